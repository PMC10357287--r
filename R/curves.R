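#' Detect curves along a vessel centerline
#'
#' Computes a deviation-angle profile on a resampled, smoothed centerline and
#' segments it into curves. A curve is a maximal contiguous run of the
#' profile above a small noise floor containing one local maximum (its
#' peak); local maxima closer than `merge_dist` mm of arc length are merged
#' into one curve, keeping the larger peak. Each curve's `turn_angle` is the
#' total tangent rotation across its span — for a planar bend this equals
#' the bend's deviation-from-straight angle (0 = straight) regardless of how
#' gradually the vessel turns, where a probe-chord angle at the peak would
#' underestimate gradual bends. Curves whose angle is below `min_angle` are
#' discarded. Fully deterministic.
#'
#' @param x a [centerline()].
#' @param offset probe distance for the turning angle, mm (default 10).
#' @param min_angle smallest peak angle counted as a curve, degrees
#'   (default 15).
#' @param floor noise floor for the profile, degrees (default 5).
#' @param merge_dist peaks closer than this arc length merge, mm (default 20).
#' @param prepare if `TRUE` (default) the centerline is passed through
#'   [resample_smooth()] with `spacing`/`window` first; set to `FALSE` when
#'   `x` is already processed.
#' @param spacing,window forwarded to [resample_smooth()] when
#'   `prepare = TRUE`.
#' @return data.frame of class `"curves"` with one row per curve:
#'   `peak_index` (index into the processed centerline), `peak_s` (arc length
#'   of the peak, mm), `turn_angle` (degrees), `span_start`, `span_end`
#'   (arc-length interval, mm). The processed centerline is attached as
#'   attribute `"centerline"`.
#' @export
#' @examples
#' v <- centerline(cbind(seq(0, 200, 2), 0, 0), 7)
#' nrow(detect_curves(v))  # 0: a straight vessel has no curves
detect_curves <- function(x, offset = 10, min_angle = 15, floor = 5,
                          merge_dist = 20, prepare = TRUE,
                          spacing = 1, window = 5) {
  stopifnot(inherits(x, "centerline"))
  if (offset <= 0) stop("`offset` must be > 0", call. = FALSE)
  if (min_angle <= 0 || min_angle >= 180)
    stop("`min_angle` must be in (0, 180)", call. = FALSE)
  cl <- if (prepare) resample_smooth(x, spacing = spacing, window = window)
        else x
  s <- arc_length(cl)
  theta <- turning_profile(cl, offset = offset)
  vturn <- vertex_turns(cl)  # tangent rotation at every interior vertex

  above <- theta > floor
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  curves <- list()
  for (r in which(runs$values)) {
    i0 <- starts[r]; i1 <- ends[r]
    seg <- theta[i0:i1]
    peaks <- local_maxima(seg) + i0 - 1L
    peaks <- merge_peaks(peaks, theta, s, merge_dist)
    if (length(peaks) == 0L) next
    ## split the run between consecutive surviving peaks at the profile minimum
    bounds <- i0
    if (length(peaks) > 1L) {
      for (j in seq_len(length(peaks) - 1L)) {
        between <- (peaks[j] + 1L):(peaks[j + 1L] - 1L)
        cut <- if (length(between)) between[which.min(theta[between])]
               else peaks[j]
        bounds <- c(bounds, cut)
      }
    }
    bounds <- c(bounds, i1)
    for (j in seq_along(peaks)) {
      lo <- if (j == 1L) bounds[1L] else bounds[j] + 1L
      hi <- bounds[j + 1L]
      curves[[length(curves) + 1L]] <-
        data.frame(peak_index = peaks[j], peak_s = s[peaks[j]],
                   turn_angle = sum(vturn[lo:hi]),
                   span_start = s[lo], span_end = s[hi])
    }
  }
  out <- if (length(curves)) do.call(rbind, curves)
         else data.frame(peak_index = integer(0), peak_s = numeric(0),
                         turn_angle = numeric(0), span_start = numeric(0),
                         span_end = numeric(0))
  out <- out[out$turn_angle >= min_angle, , drop = FALSE]
  out <- out[order(out$peak_s), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "centerline") <- cl
  class(out) <- c("curves", "data.frame")
  out
}

## tangent rotation (degrees) at each vertex: angle between the incoming and
## outgoing segment directions; 0 at the two endpoints
vertex_turns <- function(cl) {
  p <- cl$points
  n <- nrow(p)
  out <- numeric(n)
  if (n < 3L) return(out)
  d <- p[-1L, , drop = FALSE] - p[-n, , drop = FALSE]
  dot <- rowSums(d[-1L, , drop = FALSE] * d[-(n - 1L), , drop = FALSE])
  nr <- sqrt(rowSums(d^2))
  cosang <- dot / (nr[-1L] * nr[-(n - 1L)])
  out[2L:(n - 1L)] <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  out
}

## indices of strict-or-plateau local maxima within a vector
local_maxima <- function(v) {
  n <- length(v)
  if (n == 1L) return(1L)
  left <- c(TRUE, v[-1L] >= v[-n])
  right <- c(v[-n] > v[-1L], TRUE)
  which(left & right)
}

## iteratively merge peaks closer than merge_dist, dropping the smaller
merge_peaks <- function(peaks, theta, s, merge_dist) {
  while (length(peaks) > 1L) {
    gaps <- diff(s[peaks])
    j <- which(gaps < merge_dist)
    if (!length(j)) break
    j <- j[1L]
    drop <- if (theta[peaks[j]] >= theta[peaks[j + 1L]]) j + 1L else j
    peaks <- peaks[-drop]
  }
  peaks
}

#' Tortuosity profile of a vessel
#'
#' Summarizes detected curves into the standard CT tortuosity measurements:
#' number of curves (NOC), sum of all curve peak angles (SOA), single maximum
#' angle, mean arc-length distance between consecutive curve peaks, true
#' (arc) length, ideal (chord) length, and the iliofemoral tortuosity index
#' `IFT = (true_length / ideal_length - 1) * 100`. The chord runs between the
#' puncture-site and bifurcation landmarks when present, otherwise between
#' the first and last points.
#'
#' @param x a [centerline()] (the one the curves were detected on).
#' @param curves result of [detect_curves()]; defaults to detecting them on
#'   `x` with default settings.
#' @return list of class `"tortuosity_profile"` with fields `n_curves`,
#'   `sum_of_angles`, `max_angle`, `mean_inter_curve_distance` (NA when fewer
#'   than 2 curves), `true_length`, `ideal_length`, `ift`.
#' @export
tortuosity_profile <- function(x, curves = detect_curves(x)) {
  stopifnot(inherits(x, "centerline"))
  ## lengths come from the centerline as supplied; the (resampled,
  ## smoothed) processing copy attached to `curves` is only a detection aid
  s <- arc_length(x)
  true_length <- s[length(s)]
  if (nrow(curves) &&
      (any(curves$peak_s < -1e-9) ||
         any(curves$peak_s > true_length * (1 + 1e-6) + 1e-6)))
    stop("curve peaks lie outside the vessel", call. = FALSE)
  lm <- x$landmarks
  ends <- if (!is.null(lm) && length(lm) >= 2L) range(lm)
          else c(1L, nrow(x$points))
  ideal_length <- sqrt(sum((x$points[ends[2L], ] - x$points[ends[1L], ])^2))
  noc <- nrow(curves)
  out <- list(
    n_curves = noc,
    sum_of_angles = if (noc) sum(curves$turn_angle) else 0,
    max_angle = if (noc) max(curves$turn_angle) else 0,
    mean_inter_curve_distance = if (noc >= 2L) mean(diff(curves$peak_s))
                                else NA_real_,
    true_length = true_length,
    ideal_length = ideal_length,
    ift = ift_index(true_length, ideal_length))
  class(out) <- "tortuosity_profile"
  out
}

#' @export
print.tortuosity_profile <- function(x, ...) {
  cat("Tortuosity profile\n")
  cat(sprintf("  curves (NOC):        %d\n", x$n_curves))
  cat(sprintf("  sum of angles (SOA): %.1f deg\n", x$sum_of_angles))
  cat(sprintf("  max angle:           %.1f deg\n", x$max_angle))
  cat(sprintf("  mean curve spacing:  %s mm\n",
              if (is.na(x$mean_inter_curve_distance)) "-"
              else sprintf("%.1f", x$mean_inter_curve_distance)))
  cat(sprintf("  true / ideal length: %.1f / %.1f mm (IFT %.1f%%)\n",
              x$true_length, x$ideal_length, x$ift))
  invisible(x)
}

#' Iliofemoral tortuosity index
#'
#' `IFT = (true_length / ideal_length - 1) * 100`, in percent.
#'
#' @param true_length vessel arc length, mm.
#' @param ideal_length straight (chord) length, mm.
#' @return IFT in percent.
#' @export
#' @examples
#' ift_index(225.5, 205)  # 10
ift_index <- function(true_length, ideal_length) {
  if (any(ideal_length <= 0)) stop("`ideal_length` must be > 0", call. = FALSE)
  (true_length / ideal_length - 1) * 100
}

#' Lumen summary of a centerline
#'
#' Minimal lumen diameter (MLD), minimal area, minimal perimeter and mean
#' diameter over all cross-sections, with the arc-length positions of the
#' minima retained for reporting.
#'
#' @param x a [centerline()].
#' @return list of class `"lumen_summary"` with `mld`, `min_area`,
#'   `min_perimeter`, `mean_diameter` and `positions` (arc lengths, mm, of
#'   the three minima).
#' @export
lumen_summary <- function(x) {
  stopifnot(inherits(x, "centerline"))
  sec <- x$sections
  if (any(sec$diameter <= 0) || any(sec$area <= 0) || any(sec$perimeter <= 0))
    stop("cross-section measurements must be positive", call. = FALSE)
  s <- arc_length(x)
  i_d <- which.min(sec$diameter)
  i_a <- which.min(sec$area)
  i_p <- which.min(sec$perimeter)
  out <- list(mld = sec$diameter[i_d],
              min_area = sec$area[i_a],
              min_perimeter = sec$perimeter[i_p],
              mean_diameter = mean(sec$diameter),
              positions = c(mld = s[i_d], min_area = s[i_a],
                            min_perimeter = s[i_p]))
  class(out) <- "lumen_summary"
  out
}

#' @export
print.lumen_summary <- function(x, ...) {
  cat(sprintf("Lumen: MLD %.2f mm (at %.0f mm), min area %.1f mm^2, min perimeter %.1f mm, mean diameter %.2f mm\n",
              x$mld, x$positions[["mld"]], x$min_area, x$min_perimeter,
              x$mean_diameter))
  invisible(x)
}
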