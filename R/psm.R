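#' Nearest-neighbor propensity-score matching with a caliper
#'
#' Estimates propensity scores by logistic regression of the outcome group
#' on the balancing covariates, then greedily matches each case to up to
#' `ratio` unused controls: cases are processed in descending propensity
#' order and each receives its nearest controls on the propensity scale
#' within the caliper. Controls are never reused; cases with no in-caliper
#' control are dropped and reported. Balance is summarized as standardized
#' mean differences before and after matching.
#'
#' @param data data.frame with covariates and outcome.
#' @param covariates character vector of covariate names to balance on.
#' @param outcome name of the 0/1 outcome column (default `"ivc"`); 1 marks
#'   a case.
#' @param ratio controls per case (default 2).
#' @param caliper maximal allowed propensity distance (default 0.10).
#' @param caliper_scale `"ps"` applies the caliper on the probability scale;
#'   `"logit_sd"` multiplies it by the SD of the logit propensity.
#' @param ps optional precomputed propensity scores (bypasses the logistic
#'   fit; useful for toy examples and cross-checks).
#' @return list of class `"psm_match"`: `matches` (data.frame `case`,
#'   `control`, `distance`), `dropped` (case row indices left unmatched),
#'   `ps`, `caliper` (the effective caliper used), `balance` (SMD per
#'   covariate before/after), `matched_rows` (row indices of the matched
#'   sample).
#' @export
propensity_match <- function(data, covariates, outcome = "ivc", ratio = 2,
                             caliper = 0.10,
                             caliper_scale = c("ps", "logit_sd"),
                             ps = NULL) {
  caliper_scale <- match.arg(caliper_scale)
  y <- as_binary(data[[outcome]])
  if (!any(y == 1) || !any(y == 0))
    stop("both outcome groups must be nonempty", call. = FALSE)
  if (is.null(ps)) {
    fit <- logistic_fit(data[, covariates, drop = FALSE], y)
    ps <- as.numeric(fit$glm$fitted.values)
  } else {
    ps <- as.numeric(ps)
    stopifnot(length(ps) == nrow(data))
  }
  eff_caliper <- if (caliper_scale == "logit_sd")
    caliper * sd(qlogis(pmin(pmax(ps, 1e-12), 1 - 1e-12))) else caliper

  cases <- which(y == 1)
  cases <- cases[order(ps[cases], decreasing = TRUE)]
  controls <- which(y == 0)
  used <- rep(FALSE, nrow(data))
  matches <- list()
  dropped <- integer(0)
  for (cs in cases) {
    avail <- controls[!used[controls]]
    if (!length(avail)) { dropped <- c(dropped, cs); next }
    d <- abs(ps[avail] - ps[cs])
    ok <- avail[d <= eff_caliper + 1e-12]
    if (!length(ok)) { dropped <- c(dropped, cs); next }
    dk <- abs(ps[ok] - ps[cs])
    take <- ok[order(dk, ok)][seq_len(min(ratio, length(ok)))]
    used[take] <- TRUE
    matches[[length(matches) + 1L]] <-
      data.frame(case = cs, control = take,
                 distance = abs(ps[take] - ps[cs]))
  }
  matches <- if (length(matches)) do.call(rbind, matches)
             else data.frame(case = integer(0), control = integer(0),
                             distance = numeric(0))
  matched_rows <- c(setdiff(cases, dropped), matches$control)
  balance <- smd_table(data, covariates, y, matched_rows)
  out <- list(matches = matches, dropped = dropped, ps = ps,
              caliper = eff_caliper, ratio = ratio, balance = balance,
              matched_rows = sort(matched_rows))
  class(out) <- "psm_match"
  out
}

## standardized mean differences, before vs after matching
smd_table <- function(data, covariates, y, matched_rows) {
  smd <- function(rows) {
    vapply(covariates, function(cv) {
      v <- as.numeric(data[[cv]][rows])
      g <- y[rows]
      m1 <- mean(v[g == 1]); m0 <- mean(v[g == 0])
      s <- sqrt((var(v[g == 1]) + var(v[g == 0])) / 2)
      if (!is.finite(s) || s == 0) return(0)
      (m1 - m0) / s
    }, numeric(1))
  }
  data.frame(covariate = covariates,
             smd_before = smd(seq_len(nrow(data))),
             smd_after = if (length(matched_rows)) smd(matched_rows)
                         else NA_real_,
             row.names = NULL)
}

#' @export
print.psm_match <- function(x, ...) {
  cat(sprintf("Propensity match: %d cases matched (%d dropped), caliper %.3g, up to %d controls each\n",
              length(unique(x$matches$case)), length(x$dropped), x$caliper,
              x$ratio))
  print(transform(x$balance, smd_before = round(smd_before, 3),
                  smd_after = round(smd_after, 3)))
  invisible(x)
}
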