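#' Read a vessel centerline from CSV or JSON
#'
#' CSV files need a header with columns `x_mm,y_mm,z_mm,diameter_mm` and
#' optionally `area_mm2,perimeter_mm`, one row per point in puncture-site to
#' bifurcation order. The JSON mirror holds `points` (array of `[x, y, z]`),
#' `sections` (arrays `diameter`, optionally `area`, `perimeter`) and
#' optional `landmarks`. Missing areas/perimeters are imputed under the
#' circular idealization and flagged on the returned object.
#'
#' @param path file path; `.json` selects the JSON reader.
#' @return a [centerline()].
#' @export
read_centerline <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::fromJSON(path)
    pts <- as.matrix(j$points)
    sec <- j$sections
    lmk <- if (!is.null(j$landmarks)) unlist(j$landmarks) else NULL
    return(centerline(pts, sec$diameter, sec$area, sec$perimeter,
                      landmarks = lmk))
  }
  df <- read.csv(path, check.names = TRUE)
  req <- c("x_mm", "y_mm", "z_mm", "diameter_mm")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("centerline CSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!nrow(df)) stop("empty centerline file: ", path, call. = FALSE)
  bad <- which(!is.finite(df$diameter_mm) | df$diameter_mm <= 0)
  if (length(bad))
    stop("non-positive diameter at row ", bad[1L], " of ", path,
         call. = FALSE)
  pts <- as.matrix(df[, c("x_mm", "y_mm", "z_mm")])
  step <- rowSums((pts[-1L, , drop = FALSE] -
                     pts[-nrow(pts), , drop = FALSE])^2)
  if (nrow(pts) >= 2L && any(step <= 0))
    stop("arc length not strictly increasing at row ",
         which(step <= 0)[1L] + 1L, " of ", path, call. = FALSE)
  centerline(pts, df$diameter_mm,
             area = if ("area_mm2" %in% names(df)) df$area_mm2 else NULL,
             perimeter = if ("perimeter_mm" %in% names(df)) df$perimeter_mm
                         else NULL)
}

#' Write a centerline to CSV or JSON
#'
#' @param x a [centerline()].
#' @param path destination; `.json` selects the JSON mirror.
#' @return `path`, invisibly.
#' @export
write_centerline <- function(x, path) {
  stopifnot(inherits(x, "centerline"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(points = unname(apply(x$points, 1L, c, simplify = FALSE)),
           sections = as.list(x$sections),
           landmarks = as.list(x$landmarks)),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- data.frame(x_mm = x$points[, 1L], y_mm = x$points[, 2L],
                     z_mm = x$points[, 3L],
                     diameter_mm = x$sections$diameter,
                     area_mm2 = x$sections$area,
                     perimeter_mm = x$sections$perimeter)
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read plaque annotations from CSV or JSON
#'
#' Columns/fields: `span_start_mm`, `span_end_mm`, `position`,
#' `perimeter_fraction`, `lumen_fraction`, `thickness_mm`.
#'
#' @param path file path.
#' @return list of [plaque()] objects.
#' @export
read_plaques <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE))
    as.data.frame(jsonlite::fromJSON(path))
  else read.csv(path)
  if (!nrow(df)) return(list())
  req <- c("span_start_mm", "span_end_mm", "position", "perimeter_fraction",
           "lumen_fraction", "thickness_mm")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("plaque file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    plaque(df$span_start_mm[i], df$span_end_mm[i], df$position[i],
           df$perimeter_fraction[i], df$lumen_fraction[i],
           df$thickness_mm[i]))
}

#' @rdname read_plaques
#' @param plaques list of [plaque()] objects.
#' @export
write_plaques <- function(plaques, path) {
  plaques <- as_plaque_list(plaques)
  df <- do.call(rbind, lapply(plaques, function(p)
    data.frame(span_start_mm = p$span[1], span_end_mm = p$span[2],
               position = p$position,
               perimeter_fraction = p$perimeter_fraction,
               lumen_fraction = p$lumen_fraction,
               thickness_mm = p$thickness)))
  if (is.null(df))
    df <- data.frame(span_start_mm = numeric(0), span_end_mm = numeric(0),
                     position = character(0), perimeter_fraction = numeric(0),
                     lumen_fraction = numeric(0), thickness_mm = numeric(0))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
  else write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table
#'
#' One row per patient. An outcome column (0/1) is required when the table
#' is used for evaluation or derivation; unknown columns are preserved.
#'
#' @param path CSV file path.
#' @param outcome outcome column name to validate (default `"ivc"`); set to
#'   `NULL` to skip the outcome check (scoring-only tables).
#' @return data.frame of class `"cohort_table"`.
#' @export
read_cohort <- function(path, outcome = "ivc") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse cohort file: ",
                                          conditionMessage(e), call. = FALSE))
  if (!nrow(df)) stop("empty cohort file: ", path, call. = FALSE)
  if (!is.null(outcome)) {
    if (!outcome %in% names(df))
      stop("cohort file lacks outcome column '", outcome, "'", call. = FALSE)
    if (!all(df[[outcome]] %in% c(0, 1)))
      stop("outcome column '", outcome, "' must contain only 0/1",
           call. = FALSE)
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' @rdname read_cohort
#' @param cohort a cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Read or write a threshold model as JSON
#'
#' The JSON carries the ordered rules, e.g.
#' `{"rules":[{"feature":"sfar","threshold":1,"direction":">"}, ...]}`.
#'
#' @param path file path.
#' @return an [ivc_model()].
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  j <- jsonlite::fromJSON(path)
  ivc_model(as.data.frame(j$rules))
}

#' @rdname read_model
#' @param model an [ivc_model()].
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "ivc_model"))
  jsonlite::write_json(list(rules = model$rules), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}

## provenance block attached to every JSON report
provenance <- function(inputs = character(0), seed = NULL,
                       config = NULL) {
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else NULL
  list(package = "iliorisk",
       version = as.character(utils::packageVersion("iliorisk")),
       seed = seed, config = config, input_md5 = sums,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

write_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}

## flat key = value configuration text file
read_flat_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1L]]))
    out[[key]] <- if (!anyNA(num)) num else val
  }
  out
}
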