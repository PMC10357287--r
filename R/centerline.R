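#' Construct a vessel centerline
#'
#' A centerline is an ordered 3D polyline (one row per point, millimetres)
#' with a lumen cross-section attached to every point. Point order must run
#' from the femoral puncture site towards the aortoiliac bifurcation; readers
#' and constructors never reorder points.
#'
#' @param points numeric matrix with 3 columns (x, y, z in mm) or a
#'   data.frame coercible to one; at least 2 rows, consecutive rows distinct.
#' @param diameter numeric vector of lumen diameters (mm), one per point.
#' @param area optional lumen areas (mm^2). Imputed as `pi * (d/2)^2` when
#'   missing (circular idealization); imputation is recorded.
#' @param perimeter optional lumen perimeters (mm). Imputed as `pi * d` when
#'   missing.
#' @param landmarks optional named integer vector of point indices, e.g.
#'   `c(puncture = 1L, bifurcation = nrow(points))`. Used as the endpoints of
#'   the ideal (chord) length when present.
#'
#' @return An object of class `"centerline"`: a list with elements `points`
#'   (n x 3 matrix), `sections` (data.frame with `diameter`, `area`,
#'   `perimeter`), `landmarks`, and attribute `"imputed"` naming any
#'   cross-section fields filled in under the circular idealization.
#' @seealso [read_centerline()], [resample_smooth()], [detect_curves()]
#' @export
#' @examples
#' cl <- centerline(cbind(x = 0:10 * 20, y = 0, z = 0), diameter = 7)
#' lumen_summary(cl)
centerline <- function(points, diameter, area = NULL, perimeter = NULL,
                       landmarks = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L)
    stop("`points` must have exactly 3 columns (x, y, z in mm)", call. = FALSE)
  n <- nrow(points)
  if (n < 2L)
    stop("a centerline needs at least 2 points", call. = FALSE)
  if (anyNA(points) || any(!is.finite(points)))
    stop("centerline coordinates must be finite", call. = FALSE)
  step <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                          points[-n, , drop = FALSE])^2))
  if (any(step <= 0))
    stop("consecutive centerline points must be distinct (zero-length step at row ",
         which(step <= 0)[1L] + 1L, ")", call. = FALSE)
  diameter <- rep_len(as.numeric(diameter), n)
  if (length(diameter) != n || anyNA(diameter) || any(diameter <= 0))
    stop("`diameter` must be positive and finite for every point", call. = FALSE)
  imputed <- character(0)
  if (is.null(area)) {
    area <- pi * (diameter / 2)^2
    imputed <- c(imputed, "area")
  }
  if (is.null(perimeter)) {
    perimeter <- pi * diameter
    imputed <- c(imputed, "perimeter")
  }
  area <- rep_len(as.numeric(area), n)
  perimeter <- rep_len(as.numeric(perimeter), n)
  if (any(area <= 0) || any(perimeter <= 0) || anyNA(area) || anyNA(perimeter))
    stop("cross-section area/perimeter must be positive", call. = FALSE)
  if (!is.null(landmarks)) {
    landmarks <- vapply(landmarks, as.integer, integer(1))
    if (any(landmarks < 1L | landmarks > n))
      stop("landmark indices outside the centerline", call. = FALSE)
  }
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  out <- list(points = points,
              sections = data.frame(diameter = diameter, area = area,
                                    perimeter = perimeter),
              landmarks = landmarks)
  attr(out, "imputed") <- imputed
  class(out) <- "centerline"
  out
}

#' @export
print.centerline <- function(x, ...) {
  s <- arc_length(x)
  cat("<centerline> ", nrow(x$points), " points, ",
      sprintf("%.1f", s[length(s)]), " mm arc length\n", sep = "")
  cat("  lumen diameter: min ", sprintf("%.2f", min(x$sections$diameter)),
      " / mean ", sprintf("%.2f", mean(x$sections$diameter)), " mm\n", sep = "")
  if (!is.null(x$landmarks))
    cat("  landmarks:", paste(names(x$landmarks), x$landmarks, sep = "=",
                              collapse = ", "), "\n")
  if (length(attr(x, "imputed")))
    cat("  imputed (circular idealization):",
        paste(attr(x, "imputed"), collapse = ", "), "\n")
  invisible(x)
}

#' Cumulative arc length of a centerline
#'
#' @param x a [centerline()].
#' @return numeric vector of cumulative arc length (mm), starting at 0.
#' @export
arc_length <- function(x) {
  p <- x$points
  n <- nrow(p)
  c(0, cumsum(sqrt(rowSums((p[-1L, , drop = FALSE] -
                              p[-n, , drop = FALSE])^2))))
}

## linear interpolation of each coordinate / section column at arc lengths s0
interp_centerline <- function(x, s0) {
  s <- arc_length(x)
  pts <- vapply(1:3, function(j) approx(s, x$points[, j], xout = s0,
                                        rule = 2)$y, numeric(length(s0)))
  if (length(s0) == 1L) pts <- matrix(pts, nrow = 1L)
  sec <- lapply(x$sections, function(col) approx(s, col, xout = s0,
                                                 rule = 2)$y)
  list(points = pts, sections = as.data.frame(sec))
}

#' Resample and smooth a centerline
#'
#' Resamples the polyline at uniform arc-length spacing (linear interpolation
#' along the original segments) and then applies a moving-average smoother to
#' the coordinates. Smoothing stabilizes the turning-angle profile on noisy
#' extracted centerlines; the window shrinks symmetrically near the ends so
#' both endpoints are preserved exactly. Cross-sections are linearly
#' interpolated at the new arc lengths and are not smoothed. With
#' `window = 0` the returned points lie exactly on the original polyline.
#'
#' @param x a [centerline()].
#' @param spacing target arc-length spacing in mm (default 1).
#' @param window moving-average window in mm (default 5); 0 disables
#'   smoothing.
#' @return a `"centerline"` with attribute `"spacing"` recording the grid.
#' @export
resample_smooth <- function(x, spacing = 1, window = 5) {
  stopifnot(inherits(x, "centerline"))
  if (!is.numeric(spacing) || spacing <= 0)
    stop("`spacing` must be > 0", call. = FALSE)
  if (!is.numeric(window) || window < 0)
    stop("`window` must be >= 0", call. = FALSE)
  s <- arc_length(x)
  L <- s[length(s)]
  n_out <- max(2L, as.integer(round(L / spacing)) + 1L)
  grid <- seq(0, L, length.out = n_out)
  res <- interp_centerline(x, grid)
  pts <- res$points
  if (window > 0) {
    k <- max(1L, as.integer(floor(window / (2 * (L / (n_out - 1L))))))
    pts <- apply(pts, 2L, smooth_ma, k = k)
  }
  out <- centerline(pts, res$sections$diameter, res$sections$area,
                    res$sections$perimeter,
                    landmarks = remap_landmarks(x, s, grid))
  attr(out, "imputed") <- attr(x, "imputed")
  attr(out, "spacing") <- L / (n_out - 1L)
  out
}

## centered moving average with half-width k; the half-width shrinks near the
## ends so the first/last points are untouched
smooth_ma <- function(v, k) {
  n <- length(v)
  if (k < 1L || n < 3L) return(v)
  cs <- c(0, cumsum(v))
  i <- seq_len(n)
  h <- pmin(k, i - 1L, n - i)
  (cs[i + h + 1L] - cs[i - h]) / (2 * h + 1)
}

remap_landmarks <- function(x, s_old, grid) {
  if (is.null(x$landmarks)) return(NULL)
  idx <- vapply(x$landmarks, function(i) which.min(abs(grid - s_old[i])),
                integer(1))
  setNames(idx, names(x$landmarks))
}

#' Turning angle at a centerline point
#'
#' Measures the deviation-from-straight angle at a point: two probe points
#' are taken at arc length +/- `offset` from the point and the angle between
#' the incoming vector (probe before -> point) and the outgoing vector
#' (point -> probe after) is returned in degrees. 0 means locally straight;
#' a right-angle elbow gives 90.
#'
#' @param x a [centerline()].
#' @param index point index at which to measure.
#' @param offset probe distance along the vessel in mm (default 10).
#' @return angle in degrees, in `[0, 180]`.
#' @export
#' @examples
#' elbow <- centerline(rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0)), 7)
#' turning_angle(elbow, 2)  # 90
turning_angle <- function(x, index, offset = 10) {
  stopifnot(inherits(x, "centerline"))
  if (offset <= 0) stop("`offset` must be > 0", call. = FALSE)
  s <- arc_length(x)
  index <- as.integer(index)
  if (index < 1L || index > length(s))
    stop("`index` outside the centerline", call. = FALSE)
  turning_angle_at_s(x, s[index], offset)
}

## deviation angle at arc-length position s0 (probes interpolated)
turning_angle_at_s <- function(x, s0, offset = 10) {
  s <- arc_length(x)
  L <- s[length(s)]
  if (s0 - offset < -1e-9 || s0 + offset > L + 1e-9)
    stop("probe points fall outside the vessel (boundary)", call. = FALSE)
  p <- interp_centerline(x, c(s0 - offset, s0, s0 + offset))$points
  v1 <- p[2L, ] - p[1L, ]
  v2 <- p[3L, ] - p[2L, ]
  angle_between(v1, v2)
}

angle_between <- function(v1, v2) {
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(min(1, max(-1, cosang))) * 180 / pi
}

## vectorized deviation-angle profile on a uniformly resampled centerline;
## returns 0 where probes would leave the vessel
turning_profile <- function(x, offset = 10) {
  p <- x$points
  n <- nrow(p)
  h <- attr(x, "spacing")
  if (is.null(h)) {
    s <- arc_length(x)
    h <- s[length(s)] / (n - 1L)
  }
  k <- max(1L, as.integer(round(offset / h)))
  theta <- numeric(n)
  if (n < 2L * k + 1L) return(theta)
  i <- (k + 1L):(n - k)
  v1 <- p[i, , drop = FALSE] - p[i - k, , drop = FALSE]
  v2 <- p[i + k, , drop = FALSE] - p[i, , drop = FALSE]
  dot <- rowSums(v1 * v2)
  cosang <- dot / sqrt(rowSums(v1^2) * rowSums(v2^2))
  theta[i] <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  theta
}
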