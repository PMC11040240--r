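#' Normalize nightly call rates to proportions
#'
#' Converts per-detector average calls per night \eqn{c_i} into the
#' proportion of all calls recorded at each detector,
#' \eqn{C_i = c_i / \sum_j c_j}. The proportions are what the dispersal
#' model predicts, so the absolute colony size never enters the analysis.
#'
#' @param daily_rates Numeric vector of non-negative calls-per-night values,
#'   at least one of them positive.
#' @return Numeric vector of the same length summing to 1; order preserved.
#' @examples
#' normalize_calls(c(2, 7))   # 2/9, 7/9
#' @export
normalize_calls <- function(daily_rates) {
  if (!is.numeric(daily_rates) || length(daily_rates) == 0L) {
    stop("'daily_rates' must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(daily_rates)) || any(daily_rates < 0)) {
    stop("'daily_rates' must be finite and non-negative", call. = FALSE)
  }
  total <- sum(daily_rates)
  if (total <= 0) {
    stop("no calls recorded: all daily rates are zero", call. = FALSE)
  }
  daily_rates / total
}

#' Construct a survey set
#'
#' Validates a detector table and computes per-detector nightly call rates
#' and call proportions. Detectors that were never active
#' (`nights_active == 0`) carry no information about the average night and
#' are dropped with a warning; detectors that were active but recorded no
#' calls are retained with proportion 0, because the *absence* of calls at
#' a detector is informative for the error surface.
#'
#' @param detectors Data frame with columns `id`, `easting`, `northing`,
#'   `nights_active`, `total_calls`.
#' @param roost Optional known roost coordinates, numeric
#'   `c(easting, northing)` in metres (used for evaluation only).
#'
#' @return An object of class `survey_set`: a list with the validated
#'   `detectors` table (augmented with `daily_rate` = calls/night and
#'   `proportion` = share of all calls) and the optional `roost`.
#' @seealso [load_survey()], [save_survey()], [centre_of_calls()]
#' @export
survey_set <- function(detectors, roost = NULL) {
  req <- c("id", "easting", "northing", "nights_active", "total_calls")
  if (!is.data.frame(detectors) || !all(req %in% names(detectors))) {
    stop("'detectors' must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  det <- detectors[req]
  det$id <- as.character(det$id)
  for (col in c("easting", "northing")) {
    if (!is.numeric(det[[col]]) || any(!is.finite(det[[col]]))) {
      stop("column '", col, "' must be finite numeric", call. = FALSE)
    }
  }
  for (col in c("nights_active", "total_calls")) {
    v <- det[[col]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0) ||
        any(v != round(v))) {
      stop("column '", col, "' must contain non-negative integers",
           call. = FALSE)
    }
    det[[col]] <- as.integer(round(v))
  }
  if (anyDuplicated(det$id)) {
    stop("duplicate detector ids: ",
         paste(unique(det$id[duplicated(det$id)]), collapse = ", "),
         call. = FALSE)
  }
  idle <- det$nights_active == 0L
  if (any(idle)) {
    warning("dropping ", sum(idle), " detector(s) with no active nights: ",
            paste(det$id[idle], collapse = ", "), call. = FALSE)
    det <- det[!idle, , drop = FALSE]
  }
  if (nrow(det) == 0L) stop("no active detectors in survey", call. = FALSE)
  det$daily_rate <- det$total_calls / det$nights_active
  det$proportion <- normalize_calls(det$daily_rate)
  rownames(det) <- NULL
  if (!is.null(roost)) {
    roost <- as.numeric(roost)
    stopifnot(length(roost) == 2L, all(is.finite(roost)))
    names(roost) <- c("easting", "northing")
  }
  structure(list(detectors = det, roost = roost), class = "survey_set")
}

#' Read a detector survey from CSV
#'
#' Reads a comma-separated table with header columns
#' `id,easting,northing,nights_active,total_calls` (UTF-8, `.` decimal
#' separator) and builds a [survey_set()]. Coordinates are planar metric
#' eastings/northings; geographic coordinates must be projected before use.
#'
#' @param path Path to the CSV file.
#' @param roost Optional known roost `c(easting, northing)`.
#' @return A `survey_set`.
#' @export
load_survey <- function(path, roost = NULL) {
  if (!file.exists(path)) stop("survey file not found: ", path,
                               call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  req <- c("id", "easting", "northing", "nights_active", "total_calls")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    stop("survey CSV ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in req[-1]) {
    bad <- which(is.na(suppressWarnings(as.numeric(raw[[col]]))))
    if (length(bad)) {
      stop("malformed value in column '", col, "' at data row ",
           bad[1L], " of ", path, call. = FALSE)
    }
    raw[[col]] <- as.numeric(raw[[col]])
  }
  survey_set(raw, roost = roost)
}

#' Write a detector survey to CSV
#'
#' Writes the detector table of a `survey_set` (or a raw detector data
#' frame) in the same schema accepted by [load_survey()], so that
#' `load_survey(save_survey(x, f))` round-trips.
#'
#' @param survey A `survey_set` or detector data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_survey <- function(survey, path) {
  det <- if (inherits(survey, "survey_set")) survey$detectors else survey
  out <- det[c("id", "easting", "northing", "nights_active", "total_calls")]
  # %.17g keeps every bit of the coordinates, so reloads are exact
  out$easting <- sprintf("%.17g", out$easting)
  out$northing <- sprintf("%.17g", out$northing)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Detector coordinates as a matrix
#'
#' @param x A `survey_set`, a data frame with `easting`/`northing` columns,
#'   or a two-column matrix.
#' @return Numeric matrix with columns `easting`, `northing`.
#' @export
detector_coords <- function(x) {
  if (inherits(x, "survey_set")) x <- x$detectors
  if (is.data.frame(x)) {
    stopifnot(all(c("easting", "northing") %in% names(x)))
    x <- cbind(x$easting, x$northing)
  }
  x <- as.matrix(x)
  stopifnot(ncol(x) == 2L, is.numeric(x))
  colnames(x) <- c("easting", "northing")
  x
}

#' @export
print.survey_set <- function(x, ...) {
  det <- x$detectors
  cat(sprintf("Acoustic survey: %d active detectors, %d calls total\n",
              nrow(det), sum(det$total_calls)))
  cat(sprintf("  extent: %.0f x %.0f m; nights active: %d-%d\n",
              diff(range(det$easting)), diff(range(det$northing)),
              min(det$nights_active), max(det$nights_active)))
  if (!is.null(x$roost)) {
    cat(sprintf("  known roost at (%.1f, %.1f)\n",
                x$roost[1L], x$roost[2L]))
  }
  invisible(x)
}
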