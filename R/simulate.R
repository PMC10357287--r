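#' Simulation configuration for synthetic vessels and cohorts
#'
#' Defaults emulate the anatomy of iliofemoral arteries in TAVR candidates:
#' a stretched vessel length of 205 +/- 13 mm; 2 + Poisson(1.4) curves for
#' normal anatomy versus 2 + Poisson(3.6) for complication-prone
#' ("high-risk") anatomy; per-curve angles Gamma-distributed around the
#' group means of the sum-of-angles over number-of-curves (about 32 and 29
#' degrees); minimal lumen diameter truncated-normal 6.8 (SD 1.0) versus
#' 5.6 (SD 0.8) mm with a 3.0 mm floor; high-grade calcification
#' (category >= III) in 21.8% versus 33.7%; and an overall complication
#' incidence of 7.2% produced by a logistic mechanism on SOA, NOC, MLD,
#' SFAR > 1 and CAG >= III. The betas are package configuration inspired by
#' the direction and rough strength of the reported multivariable
#' associations, not estimates; the intercept is calibrated so that the
#' default cohort hits the target incidence.
#'
#' @param ... named overrides of any default listed below.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_patients = 1000L,
    seed = 1L,
    incidence_target = 0.072,
    p_highrisk_anatomy = 0.15,
    ## vessel geometry
    true_length_mean = 205, true_length_sd = 13,
    noc_base = 2L, noc_mean_control = 1.4, noc_mean_highrisk = 3.6,
    angle_mean_control = 32.4, angle_mean_highrisk = 29.5,
    angle_shape = 18, angle_range = c(20, 85),
    elbow_radius = 15,
    min_gap_interior = 25, min_gap_end = 15,
    noise_sd = 0,
    ## lumen
    mld_mean_control = 6.8, mld_sd_control = 1.0,
    mld_mean_highrisk = 5.6, mld_sd_highrisk = 0.8,
    mld_floor = 3.0, lumen_margin = c(1.0, 2.5), dip_width = 6,
    ## plaques
    plaque_prob = 0.6,
    cag3_prob_control = 0.218, cag3_prob_highrisk = 0.337,
    plaque_length = c(10, 25), plaque_thickness = c(0.3, 1.0),
    plaque_on_curve_prob = 0.5,
    ## sheath
    sheath_od_mean = 5.85, sheath_od_sd = 0.5, sheath_od_range = c(4.5, 7.5),
    ## outcome mechanism (logistic on extracted features)
    betas = c(intercept = -2.4849, soa = 0.010, noc = 0.30, mld = -0.55,
              sfar_gt_1 = 0.9, cag_ge_III = 0.7),
    ## complication-type mix among cases
    ivc_type_prob = c(dissection = 0.360, perforation = 0.250,
                      pseudoaneurysm = 0.198,
                      stenosis_thrombosis_embolism_ischemia = 0.163,
                      av_fistula = 0.029))
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown))
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(override)] <- override
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$incidence_target > 0, cfg$incidence_target < 1,
            cfg$true_length_mean > 0, cfg$true_length_sd >= 0,
            cfg$noc_mean_control > 0, cfg$noc_mean_highrisk > 0,
            cfg$angle_shape > 0, all(cfg$angle_range > 0),
            cfg$elbow_radius > 0, cfg$mld_floor > 0,
            cfg$mld_mean_control > 0, cfg$mld_mean_highrisk > 0,
            cfg$sheath_od_mean > 0,
            cfg$p_highrisk_anatomy >= 0, cfg$p_highrisk_anatomy <= 1)
  invisible(cfg)
}

## deterministic per-patient substream seed below 2^31
patient_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 65011) * 33029 + i * 7 + 13) %% 2147483647L
}

rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

rtrunc_gamma <- function(n, shape, mean, lo, hi) {
  out <- rgamma(n, shape = shape, rate = shape / mean)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- rgamma(length(bad), shape = shape, rate = shape / mean)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

## 3D polyline from straight gaps joined by planar circular-arc elbows whose
## bend planes are rotated by the given azimuths about the running axis
build_vessel_geometry <- function(gaps, angles, azimuths, radius,
                                  spacing = 1) {
  stopifnot(length(gaps) == length(angles) + 1L)
  p <- c(0, 0, 0)
  d <- c(0, 0, 1)
  pts <- list(p)
  peak_s <- numeric(length(angles))
  s_acc <- 0
  emit_straight <- function(len) {
    k <- max(1L, ceiling(len / spacing))
    step <- len / k
    for (j in seq_len(k)) {
      p <<- p + d * step
      pts[[length(pts) + 1L]] <<- p
    }
    s_acc <<- s_acc + len
  }
  for (i in seq_along(angles)) {
    emit_straight(gaps[i])
    ## orthonormal frame around d
    ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- ref - sum(ref * d) * d; u <- u / sqrt(sum(u^2))
    v <- c(d[2] * u[3] - d[3] * u[2], d[3] * u[1] - d[1] * u[3],
           d[1] * u[2] - d[2] * u[1])
    b <- cos(azimuths[i]) * u + sin(azimuths[i]) * v  # in-plane normal
    a_rad <- angles[i] * pi / 180
    arc_len <- radius * a_rad
    k <- max(2L, ceiling(arc_len / spacing))
    centre <- p + radius * b
    for (j in seq_len(k)) {
      phi <- a_rad * j / k
      pj <- centre - radius * (cos(phi) * b - sin(phi) * d)
      pts[[length(pts) + 1L]] <- pj
    }
    peak_s[i] <- s_acc + arc_len / 2
    s_acc <- s_acc + arc_len
    p <- pts[[length(pts)]]
    d <- cos(a_rad) * d + sin(a_rad) * b
  }
  emit_straight(gaps[length(gaps)])
  list(points = do.call(rbind, pts), peak_s = peak_s, length = s_acc)
}

#' Simulate one synthetic iliofemoral vessel
#'
#' Draws an anatomy stratum (normal vs high-risk tortuosity) and builds a 3D
#' centerline of straight segments joined by circular-arc elbows with the
#' drawn angles, the elbow planes rotated randomly about the vessel axis. A
#' smooth diameter profile is planted whose minimum equals the drawn MLD at
#' an exact grid point, and a calcified plaque is optionally added. The
#' planted values are returned so detection can be checked against them.
#'
#' @param config a [sim_config()].
#' @param stratum `"control"`, `"highrisk"`, or `NULL` to draw it with
#'   probability `config$p_highrisk_anatomy`.
#' @param seed optional integer; when given the vessel is regenerated
#'   bit-exactly from (config, seed).
#' @return list with `centerline`, `plaques` (possibly empty list),
#'   `sheath_od`, `stratum` and `planted` (list: `noc`, `angles`, `peak_s`,
#'   `mld`, `dip_s`, `true_length`).
#' @export
simulate_vessel <- function(config = sim_config(), stratum = NULL,
                            seed = NULL) {
  if (!is.null(seed)) return(withr_seed(seed,
    simulate_vessel(config, stratum, seed = NULL)))
  cfg <- config
  if (is.null(stratum))
    stratum <- if (runif(1) < cfg$p_highrisk_anatomy) "highrisk" else "control"
  hr <- stratum == "highrisk"

  noc <- cfg$noc_base + rpois(1, if (hr) cfg$noc_mean_highrisk
                                 else cfg$noc_mean_control)
  angles <- rtrunc_gamma(noc, cfg$angle_shape,
                         if (hr) cfg$angle_mean_highrisk
                         else cfg$angle_mean_control,
                         cfg$angle_range[1], cfg$angle_range[2])
  azimuths <- runif(noc, 0, 2 * pi)
  arc_total <- sum(cfg$elbow_radius * angles * pi / 180)
  min_len <- 2 * cfg$min_gap_end +
    max(0, noc - 1) * cfg$min_gap_interior + arc_total
  L <- max(rtrunc_norm(1, cfg$true_length_mean, cfg$true_length_sd,
                       lo = 150), min_len + 15)
  slack <- L - min_len
  w <- rgamma(noc + 1L, 1)
  gaps <- c(cfg$min_gap_end, rep(cfg$min_gap_interior, max(0, noc - 1L)),
            cfg$min_gap_end) + slack * w / sum(w)
  if (noc == 0L) gaps <- L

  geo <- build_vessel_geometry(gaps, angles, azimuths, cfg$elbow_radius)
  pts <- geo$points
  if (cfg$noise_sd > 0)
    pts <- pts + matrix(rnorm(length(pts), 0, cfg$noise_sd), ncol = 3L)

  ## lumen profile: smooth baseline with one stenotic dip to exactly MLD
  n <- nrow(pts)
  s <- c(0, cumsum(sqrt(rowSums((pts[-1L, , drop = FALSE] -
                                   pts[-n, , drop = FALSE])^2))))
  mld <- rtrunc_norm(1, if (hr) cfg$mld_mean_highrisk else cfg$mld_mean_control,
                     if (hr) cfg$mld_sd_highrisk else cfg$mld_sd_control,
                     lo = cfg$mld_floor)
  base <- mld + runif(1, cfg$lumen_margin[1], cfg$lumen_margin[2])
  dip_cand <- which(s > 20 & s < geo$length - 20)
  dip_i <- dip_cand[sample.int(length(dip_cand), 1L)]
  diam <- base - (base - mld) * exp(-((s - s[dip_i])^2) / (2 * cfg$dip_width^2))
  diam[dip_i] <- mld  # exact at the grid point

  cl <- centerline(pts, diam,
                   landmarks = c(puncture = 1L, bifurcation = n))

  plaques <- list()
  if (runif(1) < cfg$plaque_prob) {
    p_cag3 <- if (hr) cfg$cag3_prob_highrisk else cfg$cag3_prob_control
    high <- runif(1) < p_cag3
    lf <- if (high) runif(1, 0.5, 0.95) else runif(1, 0.05, 0.45)
    pf <- if (runif(1) < 0.5) runif(1, 0.05, 0.45) else runif(1, 0.5, 0.95)
    position <- if (pf >= 0.5 && runif(1) < 0.25) "circumferential"
                else sample(c("inner_wall", "outer_wall"), 1L)
    len <- runif(1, cfg$plaque_length[1], cfg$plaque_length[2])
    centre_s <- if (noc > 0 && runif(1) < cfg$plaque_on_curve_prob)
      geo$peak_s[sample.int(noc, 1L)]
    else runif(1, len / 2 + 5, geo$length - len / 2 - 5)
    span <- c(max(0, centre_s - len / 2), min(geo$length, centre_s + len / 2))
    in_span <- s >= span[1] & s <= span[2]
    thick <- min(runif(1, cfg$plaque_thickness[1], cfg$plaque_thickness[2]),
                 0.28 * min(diam[in_span]) / 2)
    plaques <- list(plaque(span[1], span[2], position, pf, lf, thick))
  }

  sheath_od <- rtrunc_norm(1, cfg$sheath_od_mean, cfg$sheath_od_sd,
                           cfg$sheath_od_range[1], cfg$sheath_od_range[2])
  list(centerline = cl, plaques = plaques, sheath_od = sheath_od,
       stratum = stratum,
       planted = list(noc = noc, angles = angles, peak_s = geo$peak_s,
                      mld = mld, dip_s = s[dip_i],
                      true_length = geo$length))
}

#' Logistic outcome mechanism
#'
#' Probability of an iliofemoral vascular complication given the extracted
#' anatomical features, under the simulator's logistic mechanism:
#' `logit(p) = b0 + b_soa*SOA + b_noc*NOC + b_mld*MLD + b_sfar*1(SFAR > 1) +
#' b_cag*1(CAG >= III)`.
#'
#' @param features data.frame (or list) with `soa`, `noc`, `mld`,
#'   `sfar_gt_1` (0/1), `cag_ge_III` (0/1).
#' @param betas named vector with `intercept`, `soa`, `noc`, `mld`,
#'   `sfar_gt_1`, `cag_ge_III` (default: [sim_config()]'s).
#' @return vector of probabilities.
#' @export
outcome_probability <- function(features, betas = sim_config()$betas) {
  f <- as.data.frame(features)
  lp <- betas[["intercept"]] +
    betas[["soa"]] * f$soa + betas[["noc"]] * f$noc +
    betas[["mld"]] * f$mld +
    betas[["sfar_gt_1"]] * as.numeric(f$sfar_gt_1) +
    betas[["cag_ge_III"]] * as.numeric(f$cag_ge_III)
  plogis(lp)
}

## fast latent feature draws (no geometry) used for intercept calibration
latent_features <- function(config, n) {
  cfg <- config
  hr <- runif(n) < cfg$p_highrisk_anatomy
  noc <- cfg$noc_base + rpois(n, ifelse(hr, cfg$noc_mean_highrisk,
                                        cfg$noc_mean_control))
  soa <- vapply(seq_len(n), function(i)
    sum(rtrunc_gamma(noc[i], cfg$angle_shape,
                     if (hr[i]) cfg$angle_mean_highrisk
                     else cfg$angle_mean_control,
                     cfg$angle_range[1], cfg$angle_range[2])), numeric(1))
  mld <- rtrunc_norm(n, ifelse(hr, cfg$mld_mean_highrisk, cfg$mld_mean_control),
                     ifelse(hr, cfg$mld_sd_highrisk, cfg$mld_sd_control),
                     lo = cfg$mld_floor)
  sheath <- rtrunc_norm(n, cfg$sheath_od_mean, cfg$sheath_od_sd,
                        cfg$sheath_od_range[1], cfg$sheath_od_range[2])
  cag3 <- runif(n) < cfg$plaque_prob *
    ifelse(hr, cfg$cag3_prob_highrisk, cfg$cag3_prob_control)
  data.frame(soa = soa, noc = noc, mld = mld,
             sfar_gt_1 = as.integer(sheath / mld > 1),
             cag_ge_III = as.integer(cag3))
}

#' Calibrate the outcome-mechanism intercept
#'
#' Root-finds the logistic intercept so that the mean outcome probability
#' over `n` latent anatomy draws equals the configured incidence target.
#' The packaged default intercept was produced by this function at
#' `n = 100000`.
#'
#' @param config a [sim_config()].
#' @param n number of latent draws (default 1e5).
#' @param seed RNG seed for the draws.
#' @return the calibrated intercept (numeric scalar).
#' @export
calibrate_intercept <- function(config = sim_config(), n = 1e5, seed = 1) {
  feats <- withr_seed(seed, latent_features(config, n))
  b <- config$betas
  lp0 <- b[["soa"]] * feats$soa + b[["noc"]] * feats$noc +
    b[["mld"]] * feats$mld + b[["sfar_gt_1"]] * feats$sfar_gt_1 +
    b[["cag_ge_III"]] * feats$cag_ge_III
  uniroot(function(b0) mean(plogis(b0 + lp0)) - config$incidence_target,
          interval = c(-20, 10), tol = 1e-8)$root
}

#' Simulate a synthetic TAVR cohort
#'
#' Generates `n` patients: a vessel and plaques per patient
#' ([simulate_vessel()]), features extracted by running the measurement
#' pipeline ([assess_patient()] — not copied from the planted values), and
#' the outcome drawn from the logistic mechanism on the extracted features.
#' Every patient is generated from an independent substream of `seed`, so
#' any row is regenerable bit-exactly from (config, seed, patient index).
#'
#' @param config a [sim_config()].
#' @param n number of patients (default `config$n_patients`).
#' @param seed integer seed (default `config$seed`).
#' @return data.frame of class `"cohort_table"`, one row per patient:
#'   demographics (`age`, `sex_female`, `pad`, `valve_type`), sheath
#'   (`sheath_od_mm`, `sheath_size_gt14F`), extracted CT features (`soa`,
#'   `noc`, `mld`, `min_area`, `min_perimeter`, `mean_diameter`, `ift`,
#'   `sfar`, `csi`, `calc_category`, `cag_ge_III`), the latent probability
#'   `p_true`, the outcome `ivc` and `ivc_type`, plus the anatomy `stratum`.
#' @export
simulate_cohort <- function(config = sim_config(), n = config$n_patients,
                            seed = config$seed) {
  cfg <- config
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- withr_seed(patient_seed(seed, i), {
      v <- simulate_vessel(cfg)
      a <- assess_patient(v$centerline, v$plaques, v$sheath_od)
      hr_anat <- v$stratum == "highrisk"
      feats <- data.frame(
        soa = a$profile$sum_of_angles, noc = a$profile$n_curves,
        mld = a$lumen$mld,
        sfar_gt_1 = as.integer(a$sfar > 1),
        cag_ge_III = as.integer(isTRUE(cag_high_risk(a$calc_category))))
      p <- outcome_probability(feats, cfg$betas)
      ivc <- rbinom(1, 1, p)
      data.frame(
        id = i,
        age = round(rtrunc_norm(1, 81 + 1.5 * hr_anat, 8, 55, 99)),
        sex_female = rbinom(1, 1, 0.52 + 0.04 * hr_anat),
        pad = rbinom(1, 1, 0.12 + 0.08 * hr_anat),
        valve_type = sample(c("balloon_expandable", "self_expanding"), 1,
                            prob = c(0.74, 0.26)),
        sheath_od_mm = v$sheath_od,
        sheath_size_gt14F = as.integer(v$sheath_od > 6.0),
        soa = feats$soa, noc = feats$noc, mld = feats$mld,
        min_area = a$lumen$min_area, min_perimeter = a$lumen$min_perimeter,
        mean_diameter = a$lumen$mean_diameter,
        ift = a$profile$ift, sfar = a$sfar, csi = a$csi,
        calc_category = ifelse(is.na(a$calc_category), "none",
                               as.character(a$calc_category)),
        cag_ge_III = feats$cag_ge_III,
        p_true = p, ivc = ivc,
        ivc_type = if (ivc == 1)
          sample(names(cfg$ivc_type_prob), 1,
                 prob = cfg$ivc_type_prob / sum(cfg$ivc_type_prob))
        else NA_character_,
        stratum = v$stratum,
        stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_table", "data.frame")
  out
}
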