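#' Derive an IVC risk model from a cohort
#'
#' Reproduces the full derivation pipeline on a cohort table:
#' \enumerate{
#'   \item 2:1 nearest-neighbor propensity matching (caliper 0.10) of cases
#'     to controls on the balancing covariates, so the anatomical predictors
#'     are compared on a demographically comparable sample;
#'   \item univariate screening of the CT features at p < 0.05;
#'   \item minimum-AIC greedy forward logistic selection among the
#'     candidates;
#'   \item Gini recursive partitioning (depth 2) on SFAR and CSI to find the
#'     operating thresholds, emitted as an ordered two-step rule model.
#' }
#'
#' @param data a cohort data.frame (e.g. from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param outcome 0/1 outcome column name (default `"ivc"`).
#' @param match_covariates covariates to balance on; defaults to age, sex,
#'   peripheral artery disease, sheath size class and valve type when
#'   present.
#' @param ct_features CT-derived candidate predictors for screening.
#' @param tree_features features handed to the threshold tree (default
#'   `c("sfar", "csi")`).
#' @param match run the propensity-matching step (default `TRUE`; `FALSE`
#'   derives on the full cohort).
#' @param ratio,caliper matching parameters, see [propensity_match()].
#' @return an [ivc_model()] whose `rules` come from the fitted tree, with
#'   the derivation artifacts attached: `tree`, `screening`, `selection`,
#'   `match`, `n_derivation`.
#' @export
derive_ivc_model <- function(data, outcome = "ivc",
                             match_covariates = NULL,
                             ct_features = c("soa", "noc", "mld",
                                             "min_area", "min_perimeter",
                                             "mean_diameter", "ift",
                                             "sfar", "cag_ge_III"),
                             tree_features = c("sfar", "csi"),
                             match = TRUE, ratio = 2, caliper = 0.10) {
  data <- as.data.frame(data)
  if ("valve_type" %in% names(data) && !"valve_balloon" %in% names(data))
    data$valve_balloon <- as.integer(data$valve_type == "balloon_expandable")
  if (is.null(match_covariates))
    match_covariates <- intersect(c("age", "sex_female", "pad",
                                    "sheath_size_gt14F", "valve_balloon"),
                                  names(data))
  psm <- NULL
  work <- data
  if (match && length(match_covariates)) {
    psm <- propensity_match(data, match_covariates, outcome = outcome,
                            ratio = ratio, caliper = caliper)
    work <- data[psm$matched_rows, , drop = FALSE]
  }
  ct_features <- intersect(ct_features, names(work))
  screening <- univariate_screen(work, ct_features, outcome = outcome)
  candidates <- screening$feature[screening$candidate]
  selection <- aic_forward_selection(work, candidates, outcome = outcome)
  tree <- fit_threshold_tree(work[, tree_features, drop = FALSE],
                             work[[outcome]], max_depth = 2)
  model <- as_ivc_model(tree)
  ## the published model evaluates SFAR before CSI; with ">"-rules the
  ## prediction is order-free, only the step attribution changes
  if (all(c("sfar", "csi") %in% model$rules$feature) &&
      all(model$rules$direction == ">"))
    model$rules <- model$rules[order(match(model$rules$feature,
                                           c("sfar", "csi"))), ]
  model$screening <- screening
  model$selection <- selection
  model$match <- psm
  model$n_derivation <- nrow(work)
  model$outcome <- outcome
  model
}

#' Evaluate a threshold model on a cohort
#'
#' Applies the model, tabulates the confusion matrix and its operating
#' characteristics, the (SFAR, CSI) quadrant distribution, and the
#' C-statistics of the continuous CSI and SFAR scores.
#'
#' @param model an [ivc_model()].
#' @param data cohort data.frame holding the model's features and the
#'   outcome.
#' @param outcome 0/1 outcome column (default `"ivc"`).
#' @return list of class `"ivc_evaluation"`: `metrics`
#'   ([confusion_metrics()]), `quadrants` (count table), `auc_csi`,
#'   `auc_sfar` ([roc_auc()] results, when the columns exist), `n`.
#' @export
evaluate_model <- function(model, data, outcome = "ivc") {
  data <- as.data.frame(data)
  cls <- classify_risk(data, model)
  cm <- confusion_matrix(cls$predicted, data[[outcome]])
  quad <- table(quadrant = cls$quadrant, outcome = data[[outcome]])
  out <- list(metrics = confusion_metrics(cm),
              quadrants = quad,
              auc_csi = if ("csi" %in% names(data))
                roc_auc(data$csi, data[[outcome]]) else NULL,
              auc_sfar = if ("sfar" %in% names(data))
                roc_auc(data$sfar, data[[outcome]]) else NULL,
              n = nrow(data))
  class(out) <- "ivc_evaluation"
  out
}

#' @export
print.ivc_evaluation <- function(x, ...) {
  cat("Model evaluation on", x$n, "patients\n")
  print(x$metrics)
  if (!is.null(x$auc_csi))
    cat(sprintf("  CSI  C-stat %.3f (95%% CI %.3f-%.3f)\n",
                x$auc_csi$auc, x$auc_csi$ci95[1], x$auc_csi$ci95[2]))
  if (!is.null(x$auc_sfar))
    cat(sprintf("  SFAR C-stat %.3f (95%% CI %.3f-%.3f)\n",
                x$auc_sfar$auc, x$auc_sfar$ci95[1], x$auc_sfar$ci95[2]))
  cat("  quadrant x outcome counts:\n")
  print(x$quadrants)
  invisible(x)
}

#' @param object an `"ivc_model"`.
#' @param data optional cohort to evaluate on; defaults to nothing (rules
#'   summary only).
#' @param ... unused.
#' @rdname derive_ivc_model
#' @export
summary.ivc_model <- function(object, data = NULL, ...) {
  print(object)
  if (!is.null(object$selection)) {
    cat("\nMinimum-AIC forward selection kept:",
        if (length(object$selection$selected))
          paste(object$selection$selected, collapse = ", ")
        else "(intercept only)", "\n")
  }
  if (!is.null(object$match))
    cat("Derivation sample:", object$n_derivation,
        "patients after 2:1 propensity matching\n")
  if (!is.null(data)) {
    cat("\n")
    print(evaluate_model(object, data,
                         outcome = object$outcome %||% "ivc"))
  }
  invisible(object)
}

#' @export
coef.ivc_model <- function(object, ...) {
  if (is.null(object$selection)) {
    stats::setNames(object$rules$threshold, object$rules$feature)
  } else {
    object$selection$fit$coefficients
  }
}

#' Quadrant scatter of a cohort under a threshold model
#'
#' Plots CSI against SFAR with the model's thresholds as reference lines;
#' cases are drawn as filled red points, controls as open grey ones.
#'
#' @param x an [ivc_model()].
#' @param data cohort with `sfar`, `csi` and the outcome column.
#' @param outcome outcome column (default `"ivc"`).
#' @param ... passed to [graphics::plot()].
#' @export
plot.ivc_model <- function(x, data, outcome = "ivc", ...) {
  data <- as.data.frame(data)
  y <- as_binary(data[[outcome]])
  graphics::plot(data$sfar, data$csi, xlab = "SFAR", ylab = "CSI",
                 col = ifelse(y == 1, "firebrick", "grey50"),
                 pch = ifelse(y == 1, 19, 1), ...)
  thr <- setNames(x$rules$threshold, x$rules$feature)
  if ("sfar" %in% names(thr)) graphics::abline(v = thr[["sfar"]], lty = 2)
  if ("csi" %in% names(thr)) graphics::abline(h = thr[["csi"]], lty = 2)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
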