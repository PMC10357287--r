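#' Confusion matrix from predictions and outcomes
#'
#' @param predicted 0/1 (or logical, or "high_risk"/"low_risk") predictions.
#' @param observed 0/1 (or logical) outcomes.
#' @return list of class `"confusion_matrix"` with counts `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion_matrix <- function(predicted, observed) {
  p <- as_binary(predicted)
  o <- as_binary(observed)
  if (length(p) != length(o))
    stop("`predicted` and `observed` differ in length", call. = FALSE)
  out <- list(tp = sum(p == 1 & o == 1), fp = sum(p == 1 & o == 0),
              tn = sum(p == 0 & o == 0), fn = sum(p == 0 & o == 1))
  class(out) <- "confusion_matrix"
  out
}

as_binary <- function(x) {
  if (is.logical(x)) return(as.integer(x))
  if (is.factor(x) || is.character(x)) {
    x <- as.character(x)
    if (all(x %in% c("high_risk", "low_risk")))
      return(as.integer(x == "high_risk"))
  }
  x <- as.numeric(x)
  if (!all(x %in% c(0, 1)))
    stop("binary vector must contain only 0/1 values", call. = FALSE)
  as.integer(x)
}

#' Operating characteristics of a confusion matrix
#'
#' Sensitivity, specificity, accuracy, positive and negative predictive
#' value and F1 score, computed as exact fractions. Any metric with a zero
#' denominator is reported as `NA` (undefined), never as 0. Percentages
#' rounded to one decimal accompany each proportion, matching the usual
#' reporting precision.
#'
#' @param cm a [confusion_matrix()]; alternatively give the four counts.
#' @param tp,fp,tn,fn counts when not passing a confusion matrix.
#' @return list of class `"confusion_metrics"`: each metric holds `value`
#'   (proportion or NA) and `percent` (rounded to 0.1); counts are attached.
#' @export
#' @examples
#' m <- confusion_metrics(tp = 168, fn = 4, fp = 9, tn = 335)
#' m$sensitivity$percent  # 97.7
confusion_metrics <- function(cm = NULL, tp = NULL, fp = NULL, tn = NULL,
                              fn = NULL) {
  if (!inherits(cm, "confusion_matrix")) {
    cm <- list(tp = tp %||% cm, fp = fp, tn = tn, fn = fn)
    if (any(vapply(cm, is.null, logical(1))))
      stop("supply a confusion_matrix or all four counts", call. = FALSE)
    class(cm) <- "confusion_matrix"
  }
  with(cm, {
    if (any(c(tp, fp, tn, fn) < 0))
      stop("counts must be nonnegative", call. = FALSE)
    frac <- function(num, den) {
      v <- if (den > 0) num / den else NA_real_
      list(value = v, percent = if (is.na(v)) NA_real_ else round(100 * v, 1))
    }
    sens <- frac(tp, tp + fn)
    spec <- frac(tn, tn + fp)
    ppv <- frac(tp, tp + fp)
    npv <- frac(tn, tn + fn)
    acc <- frac(tp + tn, tp + fp + tn + fn)
    f1 <- if (!is.na(ppv$value) && !is.na(sens$value) &&
              (ppv$value + sens$value) > 0)
      list(value = 2 * ppv$value * sens$value / (ppv$value + sens$value),
           percent = round(200 * ppv$value * sens$value /
                             (ppv$value + sens$value), 1))
    else list(value = NA_real_, percent = NA_real_)
    out <- list(sensitivity = sens, specificity = spec, accuracy = acc,
                ppv = ppv, npv = npv, f1 = f1, counts = unclass(cm))
    class(out) <- "confusion_metrics"
    out
  })
}

#' @export
print.confusion_metrics <- function(x, ...) {
  fmt <- function(m) if (is.na(m$value)) "undefined"
                     else sprintf("%.1f%%", m$percent)
  with(x$counts, cat(sprintf(
    "Confusion: TP %d FP %d TN %d FN %d (n = %d)\n", tp, fp, tn, fn,
    tp + fp + tn + fn)))
  cat("  sensitivity ", fmt(x$sensitivity), ", specificity ",
      fmt(x$specificity), ", accuracy ", fmt(x$accuracy), "\n", sep = "")
  cat("  PPV ", fmt(x$ppv), ", NPV ", fmt(x$npv), ", F1 ", fmt(x$f1),
      "\n", sep = "")
  invisible(x)
}

#' ROC curve, concordance statistic and DeLong interval
#'
#' Area under the ROC curve (the C-statistic: the probability that a random
#' case scores above a random control, ties counting one half) with a 95%
#' DeLong confidence interval and the full operating curve.
#'
#' @param scores numeric risk scores, higher = more likely case.
#' @param labels 0/1 outcomes.
#' @param conf.level confidence level for the interval (default 0.95).
#' @return list of class `"roc_result"` with `auc`, `ci95` (length-2), and
#'   `curve` (data.frame `fpr`, `tpr`, `threshold`, monotone nondecreasing).
#' @export
roc_auc <- function(scores, labels, conf.level = 0.95) {
  labels <- as_binary(labels)
  if (length(unique(labels)) < 2L)
    stop("both outcome classes must be present", call. = FALSE)
  if (length(scores) != length(labels))
    stop("`scores` and `labels` differ in length", call. = FALSE)
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- as.numeric(suppressWarnings(
    pROC::ci.auc(r, conf.level = conf.level, method = "delong")))
  curve <- data.frame(fpr = rev(1 - r$specificities),
                      tpr = rev(r$sensitivities),
                      threshold = rev(r$thresholds))
  out <- list(auc = as.numeric(pROC::auc(r)), ci95 = ci[c(1L, 3L)],
              curve = curve)
  class(out) <- "roc_result"
  out
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: C-statistic %.3f (95%% CI %.3f-%.3f), %d operating points\n",
              x$auc, x$ci95[1], x$ci95[2], nrow(x$curve)))
  invisible(x)
}

#' Threshold maximizing classification accuracy
#'
#' Scans every midpoint between adjacent distinct scores plus the two
#' infinite cut points, classifying `score > threshold` as positive, and
#' returns the threshold with maximal accuracy. Ties are broken towards
#' higher sensitivity, then towards the lower threshold.
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 outcomes.
#' @return list with `threshold`, `sensitivity`, `specificity`, `accuracy`.
#' @export
max_accuracy_threshold <- function(scores, labels) {
  labels <- as_binary(labels)
  if (length(unique(labels)) < 2L)
    stop("both outcome classes must be present", call. = FALSE)
  u <- sort(unique(as.numeric(scores)))
  cand <- c(-Inf, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2, Inf)
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  best <- NULL
  for (thr in cand) {
    pred <- as.integer(scores > thr)
    tp <- sum(pred == 1 & labels == 1)
    tn <- sum(pred == 0 & labels == 0)
    acc <- (tp + tn) / (npos + nneg)
    sens <- tp / npos
    cur <- list(threshold = thr, sensitivity = sens,
                specificity = tn / nneg, accuracy = acc)
    if (is.null(best) || acc > best$accuracy + 1e-12 ||
        (abs(acc - best$accuracy) <= 1e-12 &&
         (sens > best$sensitivity + 1e-12 ||
          (abs(sens - best$sensitivity) <= 1e-12 &&
           thr < best$threshold))))
      best <- cur
  }
  best
}

#' Logistic regression fit with collinearity and separation diagnostics
#'
#' Maximum-likelihood logistic regression (IRLS via [stats::glm()]) of a
#' binary outcome on a feature matrix. Exactly collinear columns raise an
#' error naming the culprit rather than being silently dropped; complete or
#' quasi-complete separation raises an error naming the feature with the
#' most extreme coefficient. For Bernoulli data the reported AIC equals the
#' residual deviance plus twice the number of parameters.
#'
#' @param x data.frame or numeric matrix of features.
#' @param y 0/1 outcome vector.
#' @param tol IRLS convergence tolerance (default 1e-8).
#' @return list of class `"logistic_fit"` with `coefficients`, `se`,
#'   `deviance`, `aic`, `converged`, and the underlying `glm` object.
#' @export
logistic_fit <- function(x, y, tol = 1e-8) {
  y <- as_binary(y)
  x <- as.data.frame(x)
  if (nrow(x) != length(y))
    stop("`x` and `y` differ in length", call. = FALSE)
  mm <- stats::model.matrix(~ ., data = x)
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    culprit <- colnames(mm)[qr_$pivot[(qr_$rank + 1L):ncol(mm)]]
    stop("collinear feature(s): ", paste(culprit, collapse = ", "),
         call. = FALSE)
  }
  dat <- cbind(x, .outcome = y)
  fit <- suppressWarnings(
    glm(.outcome ~ ., data = dat, family = binomial(),
        control = list(epsilon = tol, maxit = 100)))
  if (!fit$converged)
    stop("IRLS did not converge; worst feature: ",
         names(which.max(abs(coef(fit))[-1L])), call. = FALSE)
  mu <- fit$fitted.values
  if (any(mu < 1e-10) || any(mu > 1 - 1e-10)) {
    cf <- abs(coef(fit))[-1L]
    stop("(quasi-)separation detected; culprit feature: ",
         if (length(cf)) names(which.max(cf)) else "(intercept)",
         call. = FALSE)
  }
  out <- list(coefficients = coef(fit),
              se = sqrt(diag(vcov(fit))),
              deviance = fit$deviance,
              aic = fit$aic,
              converged = fit$converged,
              glm = fit)
  class(out) <- "logistic_fit"
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic fit (IRLS): deviance", sprintf("%.2f", x$deviance),
      "AIC", sprintf("%.2f", x$aic), "\n")
  print(round(cbind(estimate = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) object$coefficients

#' Univariate screening of candidate predictors
#'
#' Compares each feature between outcome groups: Welch t-test for numeric
#' features (Mann-Whitney when `nonparametric` names the feature),
#' chi-square for categorical/binary features (Fisher's exact test when any
#' expected cell count is below 5). Features with p < `alpha` become the
#' candidate set for multivariable selection.
#'
#' @param data data.frame holding features and outcome.
#' @param features character vector of feature column names.
#' @param outcome name of the 0/1 outcome column (default `"ivc"`).
#' @param alpha screening level (default 0.05).
#' @param nonparametric features to compare by Mann-Whitney instead of t.
#' @return data.frame with `feature`, `test`, `p_value`, `candidate`.
#' @export
univariate_screen <- function(data, features, outcome = "ivc", alpha = 0.05,
                              nonparametric = character(0)) {
  y <- as_binary(data[[outcome]])
  rows <- lapply(features, function(f) {
    v <- data[[f]]
    if (is.numeric(v) && length(unique(v)) > 2L) {
      if (f %in% nonparametric) {
        p <- suppressWarnings(wilcox.test(v ~ y)$p.value)
        test <- "mann-whitney"
      } else {
        p <- t.test(v ~ y)$p.value
        test <- "welch-t"
      }
    } else {
      tab <- table(v, y)
      expct <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expct < 5)) {
        p <- fisher.test(tab)$p.value
        test <- "fisher"
      } else {
        p <- chisq.test(tab, correct = FALSE)$p.value
        test <- "chi-square"
      }
    }
    data.frame(feature = f, test = test, p_value = p,
               candidate = p < alpha)
  })
  do.call(rbind, rows)
}

#' Greedy minimum-AIC forward selection for logistic regression
#'
#' Starting from the intercept-only model, repeatedly adds the candidate
#' whose inclusion lowers the AIC the most, stopping when no addition lowers
#' it. Deterministic: AIC ties are broken alphabetically by feature name. An
#' empty candidate set returns the intercept-only fit.
#'
#' @param data data.frame holding candidates and outcome.
#' @param candidates character vector of candidate feature names (typically
#'   the `candidate` rows of [univariate_screen()]).
#' @param outcome name of the 0/1 outcome column (default `"ivc"`).
#' @return list with `selected` (character vector, possibly empty), `fit`
#'   (a [logistic_fit()] on the selected features, or intercept-only), and
#'   `trace` (data.frame of the accepted steps).
#' @export
aic_forward_selection <- function(data, candidates, outcome = "ivc") {
  y <- as_binary(data[[outcome]])
  fit_on <- function(sel) {
    if (!length(sel)) {
      dat <- data.frame(.outcome = y)
      f <- glm(.outcome ~ 1, data = dat, family = binomial())
      list(aic = f$aic, fit = list(coefficients = coef(f), se = sqrt(diag(vcov(f))),
                                   deviance = f$deviance, aic = f$aic,
                                   converged = f$converged, glm = f))
    } else {
      f <- logistic_fit(data[, sel, drop = FALSE], y)
      list(aic = f$aic, fit = f)
    }
  }
  selected <- character(0)
  current <- fit_on(selected)
  trace <- data.frame(step = 0L, added = "(intercept)", aic = current$aic)
  remaining <- sort(unique(candidates))
  repeat {
    remaining <- setdiff(remaining, selected)
    if (!length(remaining)) break
    aics <- vapply(remaining, function(f) {
      tryCatch(fit_on(c(selected, f))$aic, error = function(e) Inf)
    }, numeric(1))
    best <- which.min(aics)  # remaining is sorted, so ties go alphabetically
    if (aics[best] >= current$aic) break
    selected <- c(selected, remaining[best])
    current <- fit_on(selected)
    trace <- rbind(trace, data.frame(step = nrow(trace),
                                     added = remaining[best],
                                     aic = current$aic))
  }
  fitc <- current$fit
  if (!inherits(fitc, "logistic_fit")) class(fitc) <- "logistic_fit"
  list(selected = selected, fit = fitc, trace = trace)
}

#' Correlation coefficient
#'
#' Pearson, Spearman or Kendall correlation with an explicit undefined flag
#' for zero-variance input (rather than `NA` with a warning).
#'
#' @param x,y numeric vectors (n >= 3).
#' @param method `"pearson"`, `"spearman"` or `"kendall"`.
#' @return the coefficient, or `NA` with attribute `undefined = TRUE` when
#'   either input has zero variance.
#' @export
correlations <- function(x, y, method = c("pearson", "spearman", "kendall")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3L)
    stop("need paired vectors of length >= 3", call. = FALSE)
  if (var(x) == 0 || var(y) == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  cor(x, y, method = method)
}

#' Calibration slope with bootstrap optimism correction
#'
#' Fits the logistic recalibration `outcome ~ logit(probability)`; the slope
#' is 1 for perfectly calibrated probabilities, below 1 for overconfident
#' (overdispersed) ones. The optimism correction subtracts the bootstrap
#' estimate of the slope's bias: for each of `B` seeded resamples the
#' apparent slope is refitted and the corrected slope is
#' `2 * apparent - mean(bootstrap slopes)`.
#'
#' @param prob predicted probabilities, strictly inside (0, 1) and not all
#'   equal.
#' @param labels 0/1 outcomes.
#' @param B bootstrap resamples (default 200); `B = 0` skips the correction.
#' @param seed RNG seed for the resamples (default 1).
#' @return list with `slope` (optimism-corrected when `B > 0`),
#'   `apparent_slope`, `intercept`, `B`.
#' @export
calibration_slope <- function(prob, labels, B = 200, seed = 1) {
  labels <- as_binary(labels)
  prob <- as.numeric(prob)
  if (any(prob <= 0) || any(prob >= 1))
    stop("probabilities must lie strictly inside (0, 1)", call. = FALSE)
  if (length(unique(prob)) < 2L)
    stop("constant probabilities: calibration slope undefined", call. = FALSE)
  lp <- qlogis(prob)
  fit_slope <- function(idx) {
    f <- suppressWarnings(glm(labels[idx] ~ lp[idx], family = binomial()))
    as.numeric(coef(f)[2L])
  }
  n <- length(prob)
  apparent <- fit_slope(seq_len(n))
  f0 <- suppressWarnings(glm(labels ~ lp, family = binomial()))
  slope <- apparent
  if (B > 0) {
    boot <- withr_seed(seed, {
      vapply(seq_len(B), function(b) fit_slope(sample.int(n, replace = TRUE)),
             numeric(1))
    })
    slope <- 2 * apparent - mean(boot)
  }
  list(slope = slope, apparent_slope = apparent,
       intercept = as.numeric(coef(f0)[1L]), B = B)
}

## evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
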