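#' Diffusion model parameters
#'
#' Bundles the parameters of the dispersal model: the diffusion coefficient
#' of the foraging population, the post-sunset time horizon over which call
#' data are used, the radius of a detector's acoustic footprint, and the
#' sizes of the numerical quadrature rules.
#'
#' Defaults follow the greater horseshoe bat case: `D = 80` m\eqn{^2}/s was
#' fitted from radio-tracking mean-squared-displacement curves, the horizon
#' is the first 90 minutes after sunset (the window in which movement is
#' well described by diffusion), and the acoustic footprint is a disk of
#' radius 15 m.
#'
#' @param D Diffusion coefficient, m\eqn{^2}/s. Must be positive.
#' @param horizon Integration horizon \eqn{T} in seconds (default 5400 s
#'   = 90 min).
#' @param detector_radius Radius of the circular detection footprint, m.
#' @param time_steps Number of Simpson nodes for the time integral of the
#'   detection probability. Must be odd and at least 3 so that the node
#'   count closes an even number of intervals.
#' @param quad_radial,quad_angular Size of the tensor polar rule
#'   (Gauss-Legendre in radius x uniform in angle) used for the exact disk
#'   integral.
#'
#' @return An object of class `diffusion_params`: a named list with the
#'   validated fields above.
#' @examples
#' p <- diffusion_params()
#' p$D
#' @export
diffusion_params <- function(D = 80, horizon = 5400, detector_radius = 15,
                             time_steps = 501, quad_radial = 16,
                             quad_angular = 32) {
  stopifnot(is.numeric(D), length(D) == 1L, is.finite(D), D > 0)
  stopifnot(is.numeric(horizon), length(horizon) == 1L, horizon > 0)
  stopifnot(is.numeric(detector_radius), length(detector_radius) == 1L,
            detector_radius > 0)
  time_steps <- as.integer(time_steps)
  if (time_steps < 3L || time_steps %% 2L == 0L) {
    stop("'time_steps' must be an odd integer >= 3 (Simpson's rule needs ",
         "an even number of intervals)", call. = FALSE)
  }
  stopifnot(quad_radial >= 2, quad_angular >= 4)
  structure(
    list(D = D, horizon = horizon, detector_radius = detector_radius,
         time_steps = time_steps, quad_radial = as.integer(quad_radial),
         quad_angular = as.integer(quad_angular)),
    class = "diffusion_params"
  )
}

#' @export
print.diffusion_params <- function(x, ...) {
  cat("Diffusion parameters\n")
  cat(sprintf("  D               : %g m^2/s\n", x$D))
  cat(sprintf("  horizon T       : %g s (%.1f min)\n", x$horizon,
              x$horizon / 60))
  cat(sprintf("  detector radius : %g m\n", x$detector_radius))
  cat(sprintf("  time quadrature : Simpson, %d nodes\n", x$time_steps))
  cat(sprintf("  disk quadrature : %d x %d polar nodes\n",
              x$quad_radial, x$quad_angular))
  invisible(x)
}

#' Landscape grid specification
#'
#' Describes the rectangular grid of candidate roost positions over which
#' the error surface is evaluated. Cell centres are the evaluation points;
#' the grid extent is usually the bounding box of the detector positions
#' (see [grid_from_survey()]), following the convention that the mapped
#' area is defined by the detectors' coordinate extremes.
#'
#' @param x_min,x_max,y_min,y_max Grid extent in metres (eastings and
#'   northings).
#' @param n_x,n_y Number of cells along each axis (default 500 x 500).
#'
#' @return An object of class `grid_spec`.
#' @seealso [grid_from_survey()], [build_rho_surface()]
#' @export
grid_spec <- function(x_min, x_max, y_min, y_max, n_x = 500, n_y = 500) {
  stopifnot(is.finite(x_min), is.finite(x_max), is.finite(y_min),
            is.finite(y_max))
  if (x_max <= x_min || y_max <= y_min) {
    stop("grid extent must satisfy x_max > x_min and y_max > y_min",
         call. = FALSE)
  }
  n_x <- as.integer(n_x); n_y <- as.integer(n_y)
  if (n_x < 2L || n_y < 2L) stop("need at least 2 cells per axis",
                                 call. = FALSE)
  structure(
    list(x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max,
         n_x = n_x, n_y = n_y),
    class = "grid_spec"
  )
}

#' Grid covering a survey's detector extent
#'
#' Builds a [grid_spec()] whose extent is the bounding box of the survey's
#' detectors, optionally padded outward. Padding is how a search can be
#' extended beyond the detector array when the roost is suspected to lie
#' outside it (e.g. extending the mapped area 3 km to the east).
#'
#' @param survey A `survey_set` (or a data frame / matrix of detector
#'   coordinates with columns easting, northing).
#' @param n_x,n_y Number of grid cells per axis.
#' @param padding Either a single non-negative number (metres, applied on
#'   all four sides) or a length-4 vector `c(west, east, south, north)`.
#'
#' @return A `grid_spec`.
#' @export
grid_from_survey <- function(survey, n_x = 500, n_y = n_x, padding = 0) {
  xy <- detector_coords(survey)
  if (length(padding) == 1L) padding <- rep(padding, 4L)
  if (length(padding) != 4L || any(padding < 0)) {
    stop("'padding' must be one value or c(west, east, south, north), all >= 0",
         call. = FALSE)
  }
  grid_spec(min(xy[, 1L]) - padding[1L], max(xy[, 1L]) + padding[2L],
            min(xy[, 2L]) - padding[3L], max(xy[, 2L]) + padding[4L],
            n_x = n_x, n_y = n_y)
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("Grid: %d x %d cells over [%g, %g] x [%g, %g] m\n",
              x$n_x, x$n_y, x$x_min, x$x_max, x$y_min, x$y_max))
  cat(sprintf("  cell size: %.2f x %.2f m\n",
              (x$x_max - x$x_min) / x$n_x, (x$y_max - x$y_min) / x$n_y))
  invisible(x)
}

# Cell-centre coordinates of a grid_spec. Row 1 of the surface matrix is the
# NORTHERNMOST row (map convention); columns run west to east.
grid_centres <- function(grid) {
  dx <- (grid$x_max - grid$x_min) / grid$n_x
  dy <- (grid$y_max - grid$y_min) / grid$n_y
  list(
    x = grid$x_min + dx * (seq_len(grid$n_x) - 0.5),
    y = grid$y_max - dy * (seq_len(grid$n_y) - 0.5),  # north to south
    dx = dx, dy = dy
  )
}
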