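#' Cedars-Sinai Index (CSI)
#'
#' `CSI = SOA x NOC / MLD`: the sum of all curve angles (degrees) times the
#' number of curves, divided by the minimal lumen diameter (mm). Values above
#' 100 flag a high-risk iliofemoral anatomy.
#'
#' @param soa sum of curve angles, degrees (>= 0).
#' @param noc number of curves (>= 0). Integer per patient; fractional values
#'   arise only when plugging in group means.
#' @param mld minimal lumen diameter, mm (> 0).
#' @return the CSI score (vectorized).
#' @export
#' @examples
#' csi_score(110, 3.4, 6.8)  # 55, typical uncomplicated anatomy
#' csi_score(165, 5.6, 5.6)  # 165, typical complication-prone anatomy
csi_score <- function(soa, noc, mld) {
  if (any(mld <= 0, na.rm = TRUE))
    stop("`mld` must be > 0", call. = FALSE)
  if (any(soa < 0, na.rm = TRUE) || any(noc < 0, na.rm = TRUE))
    stop("`soa` and `noc` must be >= 0", call. = FALSE)
  soa * noc / mld
}

#' Sheath-to-femoral-artery ratio (SFAR)
#'
#' Ratio of the sheath outer diameter to the minimal lumen diameter of the
#' femoral artery. Values above 1.00 mean the sheath is wider than the
#' narrowest point of the vessel.
#'
#' @param sheath_od sheath outer diameter, mm (> 0).
#' @param mld minimal lumen diameter, mm (> 0).
#' @return the ratio (vectorized).
#' @export
#' @examples
#' sfar(7.2, 6.0)  # 1.2
sfar <- function(sheath_od, mld) {
  if (any(sheath_od <= 0, na.rm = TRUE) || any(mld <= 0, na.rm = TRUE))
    stop("`sheath_od` and `mld` must be > 0", call. = FALSE)
  sheath_od / mld
}

#' Approximate sheath outer diameter from a French size
#'
#' French size encodes the (inner) diameter as Fr/3 mm; the outer diameter
#' adds twice the wall thickness. This is a nominal approximation — when the
#' manufacturer's outer diameter is known, supply it directly.
#'
#' @param french French size of the sheath.
#' @param wall wall thickness, mm per side (default 0.4).
#' @return outer diameter in mm.
#' @export
sheath_od_from_french <- function(french, wall = 0.4) {
  if (any(french <= 0)) stop("`french` must be > 0", call. = FALSE)
  french / 3 + 2 * wall
}

#' Ordered-rule threshold model
#'
#' A threshold model is an ordered sequence of single-feature rules; the
#' first rule a patient satisfies classifies them as high risk, and a patient
#' satisfying none is low risk. The published model is
#' `ivc_default_model()`: SFAR > 1.00 first, CSI > 100 second. Both
#' thresholds are strict, so boundary values fall through to low risk.
#'
#' @param rules data.frame with columns `feature` (character), `threshold`
#'   (numeric) and `direction` (`">"` or `"<="`).
#' @param ... further components stored on the object (used by
#'   [derive_ivc_model()] to attach the derivation artifacts).
#' @return object of class `"ivc_model"`.
#' @export
ivc_model <- function(rules, ...) {
  stopifnot(is.data.frame(rules),
            all(c("feature", "threshold", "direction") %in% names(rules)))
  if (!all(rules$direction %in% c(">", "<=")))
    stop('rule directions must be ">" or "<="', call. = FALSE)
  rules$feature <- as.character(rules$feature)
  rules$threshold <- as.numeric(rules$threshold)
  out <- list(rules = rules, ...)
  class(out) <- "ivc_model"
  out
}

#' @rdname ivc_model
#' @export
ivc_default_model <- function() {
  ivc_model(data.frame(feature = c("sfar", "csi"),
                       threshold = c(1.00, 100),
                       direction = c(">", ">")))
}

#' @export
print.ivc_model <- function(x, ...) {
  cat("Iliofemoral vascular complication risk model\n")
  for (i in seq_len(nrow(x$rules)))
    cat(sprintf("  step %d: high risk if %s %s %g\n", i,
                x$rules$feature[i], x$rules$direction[i], x$rules$threshold[i]))
  cat("  otherwise: low risk\n")
  invisible(x)
}

#' Classify patients with a threshold model
#'
#' Applies the ordered rules of an [ivc_model()] to per-patient features and
#' also reports the (SFAR, CSI) quadrant when both scores are available:
#' QI = SFAR <= 1 and CSI <= 100 (the event-free region), QII = SFAR > 1 and
#' CSI <= 100, QIII = both above, QIV = SFAR <= 1 and CSI > 100 (the most
#' common anatomy among complications).
#'
#' @param features data.frame (or coercible list) holding every feature named
#'   in the model's rules; typically columns `sfar` and `csi`.
#' @param model an [ivc_model()]; defaults to the published two-step model.
#' @return data.frame with columns `predicted` (factor `high_risk` /
#'   `low_risk`), `triggering_step` (e.g. `"sfar_step"`, `"csi_step"`, or
#'   `"none"`) and `quadrant` (factor QI-QIV, NA when sfar/csi absent).
#' @export
#' @examples
#' classify_risk(data.frame(sfar = c(1.09, 0.86, 0.86),
#'                          csi  = c(55, 165, 55)))
classify_risk <- function(features, model = ivc_default_model()) {
  features <- as.data.frame(features)
  missing <- setdiff(model$rules$feature, names(features))
  if (length(missing))
    stop("missing feature(s) for classification: ",
         paste(missing, collapse = ", "), call. = FALSE)
  n <- nrow(features)
  fired <- rep(NA_integer_, n)
  for (i in seq_len(nrow(model$rules))) {
    v <- features[[model$rules$feature[i]]]
    hit <- if (model$rules$direction[i] == ">") v > model$rules$threshold[i]
           else v <= model$rules$threshold[i]
    fired[is.na(fired) & hit %in% TRUE] <- i
  }
  predicted <- factor(ifelse(is.na(fired), "low_risk", "high_risk"),
                      levels = c("low_risk", "high_risk"))
  step <- ifelse(is.na(fired), "none",
                 paste0(model$rules$feature[fired], "_step"))
  data.frame(predicted = predicted, triggering_step = step,
             quadrant = risk_quadrant(features), row.names = NULL)
}

risk_quadrant <- function(features) {
  if (!all(c("sfar", "csi") %in% names(features)))
    return(factor(rep(NA_character_, nrow(as.data.frame(features))),
                  levels = c("QI", "QII", "QIII", "QIV")))
  sf <- features$sfar > 1
  cs <- features$csi > 100
  lab <- ifelse(sf & cs, "QIII", ifelse(sf, "QII", ifelse(cs, "QIV", "QI")))
  factor(lab, levels = c("QI", "QII", "QIII", "QIV"))
}

#' @param object an `"ivc_model"`.
#' @param newdata data.frame of per-patient features.
#' @param type `"class"` for the factor of predictions, `"response"` for a
#'   0/1 vector, `"detail"` for the full classification data.frame.
#' @param ... unused.
#' @rdname classify_risk
#' @export
predict.ivc_model <- function(object, newdata,
                              type = c("class", "response", "detail"), ...) {
  type <- match.arg(type)
  res <- classify_risk(newdata, object)
  switch(type,
         class = res$predicted,
         response = as.integer(res$predicted == "high_risk"),
         detail = res)
}

#' End-to-end risk assessment of one patient
#'
#' Runs the full pipeline on a vessel: free-lumen realignment for any
#' plaques, curve detection, tortuosity profile, lumen summary, calcification
#' category (the worst plaque's), CSI and SFAR, and the two-step
#' classification. Deterministic for fixed settings.
#'
#' @param x a [centerline()] (puncture site to aortoiliac bifurcation).
#' @param plaques list of [plaque()] objects (default none).
#' @param sheath_od sheath outer diameter, mm.
#' @param model an [ivc_model()] (default: SFAR > 1.00, then CSI > 100).
#' @param adjust_for_plaques when `TRUE` (default) tortuosity and lumen are
#'   measured on the free-lumen line; set `FALSE` to measure on the
#'   wall-aligned line as supplied.
#' @param offset,min_angle,spacing,window curve-detection settings, see
#'   [detect_curves()].
#' @return list of class `"risk_assessment"` with `csi`, `sfar`, `predicted`,
#'   `triggering_step`, `quadrant`, `calc_category`, `profile`, `lumen`,
#'   `curves`, `sheath_od`.
#' @export
assess_patient <- function(x, plaques = list(), sheath_od,
                           model = ivc_default_model(),
                           adjust_for_plaques = TRUE,
                           offset = 10, min_angle = 15,
                           spacing = 1, window = 5) {
  stopifnot(inherits(x, "centerline"))
  plaques <- as_plaque_list(plaques)
  work <- if (adjust_for_plaques && length(plaques))
    free_lumen_centerline(x, plaques) else x
  curves <- detect_curves(work, offset = offset, min_angle = min_angle,
                          spacing = spacing, window = window)
  prof <- tortuosity_profile(work, curves)
  lum <- lumen_summary(work)
  lvl <- c("I", "II", "III", "IV")
  cat_chr <- if (length(plaques)) {
    lvl[max(match(vapply(plaques, function(p) as.character(p$category),
                         character(1)), lvl))]
  } else NA_character_
  cat_all <- factor(cat_chr, levels = lvl, ordered = TRUE)
  feats <- data.frame(
    sfar = sfar(sheath_od, lum$mld),
    csi = csi_score(prof$sum_of_angles, prof$n_curves, lum$mld))
  cls <- classify_risk(feats, model)
  out <- list(csi = feats$csi, sfar = feats$sfar,
              predicted = as.character(cls$predicted),
              triggering_step = cls$triggering_step,
              quadrant = as.character(cls$quadrant),
              calc_category = cat_all,
              profile = prof, lumen = lum,
              curves = as.data.frame(curves), sheath_od = sheath_od)
  class(out) <- "risk_assessment"
  out
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat("IVC risk assessment\n")
  cat(sprintf("  CSI %.1f | SFAR %.2f | quadrant %s\n",
              x$csi, x$sfar, x$quadrant))
  cat(sprintf("  calcification category: %s\n",
              ifelse(is.na(x$calc_category), "none",
                     as.character(x$calc_category))))
  cat(sprintf("  prediction: %s (%s)\n", x$predicted, x$triggering_step))
  invisible(x)
}
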