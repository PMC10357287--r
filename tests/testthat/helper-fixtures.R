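# Fixture builders shared across the suite. All geometry is constructed in
# code so the planted values are the oracle.

# straight-gap / arc-elbow vessel; returns the centerline plus planted values
elbow_vessel <- function(angles, gaps, radius = 15, diameter = 7,
                         azimuths = rep(0, length(angles))) {
  geo <- iliorisk:::build_vessel_geometry(gaps, angles, azimuths, radius)
  list(cl = centerline(geo$points, diameter),
       peak_s = geo$peak_s, angles = angles, length = geo$length)
}

# one elbow of `angle` degrees in the middle of two long straights
single_elbow <- function(angle, diameter = 6, radius = 15,
                         gaps = c(90, 90)) {
  elbow_vessel(angle, gaps, radius = radius, diameter = diameter)
}

straight_vessel <- function(length = 205, diameter = 7, spacing = 1) {
  n <- round(length / spacing)
  centerline(cbind(0, 0, seq(0, length, length.out = n + 1)), diameter)
}

# points on a planar circular arc of radius R spanning `ang` radians
arc_points <- function(R = 50, ang = pi / 2, n = 50) {
  phi <- seq(0, ang, length.out = n)
  cbind(R * sin(phi), R * (1 - cos(phi)), 0)
}

# independent O(n^2) concordance oracle for the AUC
auc_brute_force <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  gr <- outer(pos, neg, ">")
  eq <- outer(pos, neg, "==")
  (sum(gr) + 0.5 * sum(eq)) / (length(pos) * length(neg))
}

# independent implementation of the greedy caliper match used as oracle
psm_brute_force <- function(ps, y, ratio = 2, caliper = 0.10) {
  cases <- order(ps, decreasing = TRUE)
  cases <- cases[y[cases] == 1]
  used <- rep(FALSE, length(ps))
  pairs <- list()
  for (cs in cases) {
    cand <- which(y == 0 & !used & abs(ps - ps[cs]) <= caliper + 1e-12)
    if (!length(cand)) next
    cand <- cand[order(abs(ps[cand] - ps[cs]), cand)]
    take <- cand[seq_len(min(ratio, length(cand)))]
    used[take] <- TRUE
    pairs[[length(pairs) + 1L]] <- data.frame(case = cs, control = take)
  }
  if (length(pairs)) do.call(rbind, pairs)
  else data.frame(case = integer(0), control = integer(0))
}

# planted-rule cohort for threshold-tree recovery: high risk iff
# sfar > 1 or csi > 100, with a margin excluded around both thresholds.
# sfar alternates around 1 on a fixed cycle so that no run of same-label
# points sits next to the csi boundary (such a pocket would legitimately
# pull the empirical Gini optimum off the planted gap), and csi fills both
# sides of its margin evenly.
planted_rule_cohort <- function(n = 2000, margin_sfar = 0.05,
                                margin_csi = 5, seed = 99) {
  set.seed(seed)
  n_lo <- ceiling(n / 2)
  lo <- seq(1, 100 - margin_csi - 0.5, length.out = n_lo)
  hi <- seq(100 + margin_csi + 0.5, 250, length.out = n - n_lo)
  csi <- sample(c(lo, hi))
  below <- c(0.75, 0.90, 0.60, 0.85, 1 - margin_sfar - 0.01)
  above <- c(1.25, 1.40, 1 + margin_sfar + 0.01, 1.15, 1.30)
  ## in csi order, sfar alternates around 1 and the point adjacent to the
  ## csi gap from below always lies below 1 (label 0)
  is_below <- ((n_lo - seq_len(n)) %% 2) == 0
  sfar_in_order <- numeric(n)
  sfar_in_order[is_below] <- rep_len(below, sum(is_below))
  sfar_in_order[!is_below] <- rep_len(above, sum(!is_below))
  sfar <- sfar_in_order[rank(csi)]
  data.frame(sfar = sfar, csi = csi,
             ivc = as.integer(sfar > 1 | csi > 100))
}

# run the CLI without cluttering test output
cli_quiet <- function(args) {
  status <- NULL
  utils::capture.output(status <- suppressMessages(iliorisk_cli(args)))
  status
}

expect_angle_equal <- function(measured, planted, tol = 2) {
  expect_lt(max(abs(measured - planted)), tol)
}
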