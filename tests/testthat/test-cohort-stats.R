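test_that("confusion metrics are exact rationals with one-decimal reporting", {
  m <- confusion_metrics(tp = 168, fn = 4, fp = 9, tn = 335)
  expect_equal(m$sensitivity$value, 168 / 172)
  expect_equal(m$sensitivity$percent, 97.7)
  expect_equal(m$accuracy$value, (168 + 335) / 516)
  expect_equal(m$npv$value, 335 / 339)

  ppv <- confusion_metrics(tp = 66, fp = 2, tn = 0, fn = 0)
  expect_equal(ppv$ppv$value, 66 / 68)
  expect_equal(ppv$ppv$percent, 97.1)

  und <- confusion_metrics(tp = 0, fn = 0, fp = 3, tn = 7)
  expect_true(is.na(und$sensitivity$value))   # undefined, not 0
  expect_false(is.na(und$specificity$value))
  expect_error(confusion_metrics(tp = -1, fp = 0, tn = 0, fn = 1),
               "nonnegative")
})

test_that("confusion identities hold on random tables", {
  set.seed(11)
  for (i in 1:25) {
    cnt <- as.list(rpois(4, 40) + 1)
    names(cnt) <- c("tp", "fp", "tn", "fn")
    m <- do.call(confusion_metrics, cnt)
    total <- cnt$tp + cnt$fp + cnt$tn + cnt$fn
    expect_equal(m$accuracy$value, (cnt$tp + cnt$tn) / total)
    P <- cnt$tp + cnt$fn; N <- cnt$tn + cnt$fp
    expect_equal(m$sensitivity$value * P + m$specificity$value * N,
                 cnt$tp + cnt$tn)
  }
})

test_that("the C-statistic equals pairwise concordance with half-ties", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(c(1, 3, 2, 4), c(0, 0, 1, 1))$auc, 0.75)
  expect_equal(roc_auc(rep(2, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both")
  set.seed(21)
  for (i in 1:40) {
    n <- sample(6:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    s <- round(rnorm(n), sample(0:1, 1))  # rounding forces ties
    expect_equal(roc_auc(s, y)$auc, auc_brute_force(s, y),
                 tolerance = 1e-12)
  }
})

test_that("the ROC curve is monotone and the DeLong interval brackets the AUC", {
  set.seed(3)
  y <- rbinom(200, 1, 0.3)
  s <- rnorm(200) + y
  r <- roc_auc(s, y)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
  expect_true(r$ci95[1] <= r$auc && r$auc <= r$ci95[2])
})

test_that("the max-accuracy threshold matches an exhaustive scan", {
  ## perfectly separated: any midpoint in the gap, reported as the midpoint
  sep <- max_accuracy_threshold(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(sep$accuracy, 1)
  expect_equal(sep$threshold, 6.5)

  scores <- 1:6; labels <- c(0, 0, 0, 1, 0, 1)
  got <- max_accuracy_threshold(scores, labels)
  ## independent brute force over all cut points
  cand <- c(-Inf, (1:5) + 0.5, Inf)
  accs <- vapply(cand, function(t) mean((scores > t) == labels), numeric(1))
  expect_equal(got$accuracy, max(accs))
  expect_equal(got$threshold, 3.5)  # highest-sensitivity tie-break

  shifted <- max_accuracy_threshold(scores + 100, labels)
  expect_equal(shifted$threshold, got$threshold + 100)
  expect_equal(shifted$accuracy, got$accuracy)
})

test_that("logistic fitting matches closed forms and flags bad designs", {
  y <- c(rep(1, 30), rep(0, 70))
  f <- aic_forward_selection(data.frame(ivc = y), character(0))
  expect_equal(unname(f$fit$coefficients[1]), log(30 / 70), tolerance = 1e-6)

  set.seed(9)
  x <- rnorm(200)
  dup <- data.frame(a = x, b = 2 * x)
  expect_error(logistic_fit(dup, rbinom(200, 1, 0.5)), "collinear")

  xs <- c(rnorm(50, -3), rnorm(50, 3))
  ys <- as.integer(xs > 0)
  expect_error(logistic_fit(data.frame(x = xs), ys), "separation")
})

test_that("logistic AIC equals deviance plus twice the parameter count", {
  set.seed(13)
  d <- data.frame(a = rnorm(300), b = rnorm(300))
  y <- rbinom(300, 1, plogis(-1 + d$a))
  f <- logistic_fit(d, y)
  expect_equal(f$aic, f$deviance + 2 * 3, tolerance = 1e-9)
})

test_that("forward AIC selection finds a planted predictor among noise", {
  set.seed(17)
  n <- 1500
  d <- data.frame(signal = rnorm(n), n1 = rnorm(n), n2 = rnorm(n),
                  n3 = rnorm(n))
  d$ivc <- rbinom(n, 1, plogis(-2 + 1.2 * d$signal))
  sel <- aic_forward_selection(d, c("signal", "n1", "n2", "n3"))
  expect_true("signal" %in% sel$selected)
  ## exhaustive-subset oracle: the best-AIC subset over all 2^4 candidates
  subsets <- unlist(lapply(0:4, function(k)
    combn(c("signal", "n1", "n2", "n3"), k, simplify = FALSE)),
    recursive = FALSE)
  aics <- vapply(subsets, function(s) {
    if (!length(s)) glm(ivc ~ 1, binomial, data = d)$aic
    else glm(reformulate(s, "ivc"), binomial, data = d)$aic
  }, numeric(1))
  expect_true("signal" %in% subsets[[which.min(aics)]])
  expect_equal(sort(sel$selected), sort(subsets[[which.min(aics)]]))
})

test_that("with pure-noise candidates the empty set is kept at the analytic rate", {
  ## one candidate enters iff its LRT deviance drop exceeds 2, so with m
  ## independent null candidates P(select none) ~ P(chi2_1 < 2)^m
  m <- 2
  p_none <- pchisq(2, df = 1)^m
  set.seed(23)
  hits <- 0L
  for (r in 1:100) {
    d <- data.frame(n1 = rnorm(400), n2 = rnorm(400),
                    ivc = rbinom(400, 1, 0.3))
    sel <- aic_forward_selection(d, c("n1", "n2"))
    if (!length(sel$selected)) hits <- hits + 1L
  }
  se <- sqrt(p_none * (1 - p_none) / 100)
  expect_lt(abs(hits / 100 - p_none), 4 * se)
})

test_that("a duplicate of a selected feature is never added", {
  set.seed(29)
  n <- 800
  d <- data.frame(x = rnorm(n))
  d$x_copy <- d$x
  d$ivc <- rbinom(n, 1, plogis(-1 + d$x))
  sel <- aic_forward_selection(d, c("x", "x_copy"))
  expect_equal(sel$selected, "x")  # alphabetical tie-break, then no gain
})

test_that("correlation coefficients match their definitions", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  expect_equal(correlations(x, 2 * x, "pearson"), 1)
  expect_equal(correlations(x, exp(x), "spearman"), 1)
  expect_equal(correlations(x, x^3, "kendall"), 1)
  ## brute-force concordant/discordant count for Kendall's tau
  y <- c(2.0, 1.0, 4.0, 3.5, 5.0)
  pairs <- combn(5, 2)
  cd <- sum(sign(x[pairs[1, ]] - x[pairs[2, ]]) *
              sign(y[pairs[1, ]] - y[pairs[2, ]]))
  expect_equal(correlations(x, y, "kendall"), cd / choose(5, 2))
  z <- correlations(rep(1, 5), 1:5)
  expect_true(is.na(z))
  expect_true(attr(z, "undefined"))
})

test_that("calibration slope recovers 1 for self-consistent probabilities", {
  set.seed(31)
  p <- plogis(rnorm(10000, -2, 1.2))
  y <- rbinom(length(p), 1, p)
  se <- sqrt(diag(vcov(glm(y ~ qlogis(p), family = binomial()))))[2]
  cal <- calibration_slope(p, y, B = 50, seed = 4)
  expect_lt(abs(cal$slope - 1), 4 * se)
  ## doubling the logits halves the slope
  over <- plogis(2 * qlogis(p))
  cal2 <- calibration_slope(over, y, B = 50, seed = 4)
  expect_lt(abs(cal2$slope - 0.5), 4 * se)
  expect_error(calibration_slope(rep(0.3, 100), rbinom(100, 1, 0.3)),
               "constant")
  expect_error(calibration_slope(c(0, 0.5), c(0, 1)), "strictly inside")
})
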