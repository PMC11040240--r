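#' Error metric between observed and expected call proportions
#'
#' The raw (unnormalized) discrepancy \eqn{\sum_i |F_i - C_i|^p} between
#' the model-expected proportion vector `F` and the observed proportion
#' vector `C`. The default exponent \eqn{p = 2} (squared Euclidean
#' distance) weights detectors with large call shares most heavily —
#' detectors recording many passes are the ones likely to be near the
#' roost. Normalization by the grid-wide maximum happens in
#' [build_rho_surface()].
#'
#' @param C Observed proportions (from the survey).
#' @param F Expected proportions (from the forward model).
#' @param exponent Power applied to the componentwise absolute difference
#'   (2 by default; 1 and 3 are supported alternatives).
#' @return Non-negative scalar; zero iff `F == C`.
#' @export
rho_metric <- function(C, F, exponent = 2) {
  if (length(C) != length(F)) {
    stop("'C' and 'F' must have the same length (", length(C), " vs ",
         length(F), ")", call. = FALSE)
  }
  sum(abs(F - C)^exponent)
}

#' Build the normalized error surface over a landscape grid
#'
#' Evaluates the forward model at the centre of every grid cell: for each
#' candidate roost position \eqn{z}, the expected call proportions
#' \eqn{F(z)} are compared with the observed proportions \eqn{C} via
#' [rho_metric()], and the resulting raw errors are divided by their
#' maximum over the whole grid, so \eqn{\rho \in [0, 1]} with the maximum
#' exactly 1. Low values flag likely roost positions; the argmin cell
#' centre is the best point prediction \eqn{z_p}.
#'
#' Because the normalization constant is the maximum over the evaluated
#' grid only, \eqn{\rho} values are grid-dependent: enlarging or refining
#' the mapped area rescales the surface. Cells are independent, so the
#' surface is identical under any evaluation order.
#'
#' @param survey A `survey_set`.
#' @param grid A [grid_spec()]; defaults to the detectors' bounding box at
#'   500 x 500 cells.
#' @param params A [diffusion_params()] object.
#' @param mode `"approx"` (default) or `"exact"` detection integral.
#' @param exponent Exponent of the error metric (default 2).
#' @param chunk_cells Number of grid cells processed per block in the fast
#'   path (bounds peak memory; no effect on values).
#' @return An object of class `rho_surface`: a list with the `grid`, the
#'   `rho` matrix (`n_y` x `n_x`, row 1 = northernmost row), `raw_sse`,
#'   `max_sse`, `argmin_cell` (row, col), `zp` (argmin cell centre), and
#'   the inputs used.
#' @seealso [search_statistics()], [centre_of_calls()]
#' @export
build_rho_surface <- function(survey, grid = grid_from_survey(survey),
                              params = diffusion_params(),
                              mode = c("approx", "exact"), exponent = 2,
                              chunk_cells = 20000L) {
  mode <- match.arg(mode)
  stopifnot(inherits(survey, "survey_set"), inherits(grid, "grid_spec"))
  det_xy <- detector_coords(survey)
  C <- survey$detectors$proportion
  g <- grid_centres(grid)
  n_cells <- grid$n_x * grid$n_y
  # column-major cell list matching an n_y x n_x matrix, row 1 = north
  cx <- rep(g$x, each = grid$n_y)
  cy <- rep(g$y, times = grid$n_x)

  E <- expected_grid(cx, cy, det_xy, params, mode, chunk_cells)
  tot <- rowSums(E)
  raw <- rep(NA_real_, n_cells)
  ok <- tot > 0
  if (!all(ok)) {
    n_bad <- sum(!ok)
    warning(n_bad, " grid cell(s) beyond numerical support of the ",
            "forward model; set to NA", call. = FALSE)
    if (n_bad > 0.01 * n_cells) {
      stop("more than 1% of grid cells are beyond numerical support; ",
           "shrink the grid or increase the horizon T", call. = FALSE)
    }
  }
  Fmat <- E[ok, , drop = FALSE] / tot[ok]
  raw[ok] <- rowSums(abs(Fmat - rep(C, each = sum(ok)))^exponent)

  max_sse <- max(raw, na.rm = TRUE)
  rho <- matrix(raw / max_sse, nrow = grid$n_y, ncol = grid$n_x)

  # argmin with row-major (north-to-south, west-to-east) tie-break
  rmin <- min(rho, na.rm = TRUE)
  idx_rm <- which.min(t(rho))  # first minimum in row-major order
  row <- (idx_rm - 1L) %/% grid$n_x + 1L
  col <- (idx_rm - 1L) %% grid$n_x + 1L
  n_ties <- sum(rho == rmin, na.rm = TRUE)
  if (n_ties > 1L) {
    message("rho surface: ", n_ties, " cells tie at the minimum; ",
            "keeping the first in row-major order")
  }
  structure(
    list(grid = grid,
         rho = rho,
         raw_sse = matrix(raw, nrow = grid$n_y, ncol = grid$n_x),
         max_sse = max_sse,
         argmin_cell = c(row = row, col = col),
         zp = c(easting = g$x[col], northing = g$y[row]),
         survey = survey, params = params, mode = mode,
         exponent = exponent),
    class = "rho_surface"
  )
}

# Expected passes for every (cell, detector) pair; cells given as coordinate
# vectors. Returns an n_cells x n_detectors matrix. The approx path is
# chunked over cells so that the transient (cells x time-nodes) matrix per
# detector stays small.
expected_grid <- function(cx, cy, det_xy, params, mode, chunk_cells) {
  n_cells <- length(cx)
  n_det <- nrow(det_xy)
  time_steps <- params$time_steps
  tk <- seq(0, params$horizon, length.out = time_steps)
  w <- simpson_weights(time_steps, params$horizon)
  inv <- 1 / (4 * params$D * tk[-1L])
  E <- matrix(0, n_cells, n_det)
  if (mode == "approx") {
    scale <- params$detector_radius^2 * inv
    starts <- seq.int(1L, n_cells, by = chunk_cells)
    for (s in starts) {
      ix <- s:min(s + chunk_cells - 1L, n_cells)
      for (j in seq_len(n_det)) {
        d2 <- (cx[ix] - det_xy[j, 1L])^2 + (cy[ix] - det_xy[j, 2L])^2
        m <- exp(outer(-d2, inv))
        m <- sweep(m, 2L, scale, `*`)
        m[m > 1] <- 1
        E[ix, j] <- cbind(integrand_at_zero(d2), m) %*% w
      }
    }
  } else {
    q <- disk_quadrature(params$detector_radius, params$quad_radial,
                         params$quad_angular)
    wt <- w[-1L] * inv / pi
    for (j in seq_len(n_det)) {
      d2c <- (cx - det_xy[j, 1L])^2 + (cy - det_xy[j, 2L])^2
      acc <- w[1L] * integrand_at_zero(d2c)
      for (k in seq_along(q$w)) {
        d2 <- (cx - det_xy[j, 1L] - q$x[k])^2 +
              (cy - det_xy[j, 2L] - q$y[k])^2
        acc <- acc + q$w[k] * (exp(outer(-d2, inv)) %*% wt)
      }
      E[, j] <- acc
    }
  }
  E
}

#' Centre of calls
#'
#' The detector positions averaged with weights equal to each detector's
#' share of total calls: \eqn{CC = \sum_i C_i X_i}. A fast baseline
#' estimator of the roost position. As a convex combination of detector
#' positions it always lies inside the detectors' convex hull, so it
#' cannot point at a roost outside the array — the main reason the error
#' surface is worth the extra computation.
#'
#' @param survey A `survey_set`.
#' @return Named numeric `c(easting, northing)`.
#' @export
centre_of_calls <- function(survey) {
  stopifnot(inherits(survey, "survey_set"))
  xy <- detector_coords(survey)
  cc <- colSums(survey$detectors$proportion * xy)
  names(cc) <- c("easting", "northing")
  cc
}

# TRUE if point pt lies inside (or on) the convex hull of the rows of xy.
point_in_hull <- function(pt, xy, tol = 1e-9) {
  h <- grDevices::chull(xy)
  hx <- xy[h, 1L]; hy <- xy[h, 2L]
  n <- length(h)
  nxt <- c(seq_len(n)[-1L], 1L)
  # chull returns vertices clockwise; inside means all cross products <= 0
  cr <- (hx[nxt] - hx) * (pt[2L] - hy) - (hy[nxt] - hy) * (pt[1L] - hx)
  scale <- max(abs(c(hx, hy, pt)), 1)
  all(cr <= tol * scale) || all(cr >= -tol * scale)
}

#' Point estimates and search-effort statistics
#'
#' Summarizes a [build_rho_surface()] result into the quantities used to
#' judge a survey: the best point prediction `zp` (argmin of the surface),
#' the centre of calls `cc`, the pairwise distances between them and the
#' known roost (when given), and — the practical payoff — how much of the
#' mapped area has to be searched when cells are visited in order of
#' increasing \eqn{\rho}. `rho_c` is the surface value at the cell
#' containing the known roost (no interpolation), and
#' `percent_below[\"rho_c\"]` is the share of the map searched before the
#' roost is reached.
#'
#' @param surface A `rho_surface`.
#' @param roost Known roost `c(easting, northing)`, or `NULL`; defaults to
#'   the roost stored in the surface's survey, if any.
#' @param thresholds Surface levels at which to report cumulative search
#'   areas (default 0.1, 0.2, 0.3; `rho_c` is appended when available).
#' @return An object of class `roost_estimate`: `zp`, `cc`, `rho_c`,
#'   `dist_zp_cc`, `dist_zp_roost`, `dist_cc_roost` (metres; `NA` without
#'   a known roost), `area_below` (km\eqn{^2}) and `percent_below` (% of
#'   mapped area), both named by threshold.
#' @export
search_statistics <- function(surface, roost = surface$survey$roost,
                              thresholds = c(0.1, 0.2, 0.3)) {
  stopifnot(inherits(surface, "rho_surface"))
  if (length(thresholds) && (any(thresholds < 0) || any(thresholds > 1))) {
    stop("'thresholds' must lie in [0, 1]", call. = FALSE)
  }
  grid <- surface$grid
  g <- grid_centres(grid)
  zp <- surface$zp
  cc <- centre_of_calls(surface$survey)

  rho_c <- NA_real_
  dist_zp_roost <- dist_cc_roost <- NA_real_
  if (!is.null(roost)) {
    roost <- as.numeric(roost)
    dist_zp_roost <- sqrt(sum((zp - roost)^2))
    dist_cc_roost <- sqrt(sum((cc - roost)^2))
    inside <- roost[1L] >= grid$x_min && roost[1L] <= grid$x_max &&
              roost[2L] >= grid$y_min && roost[2L] <= grid$y_max
    if (!inside) {
      warning("known roost lies outside the mapped grid; rho_c undefined",
              call. = FALSE)
    } else {
      col <- min(max(1L, ceiling((roost[1L] - grid$x_min) / g$dx)), grid$n_x)
      row <- min(max(1L, ceiling((grid$y_max - roost[2L]) / g$dy)), grid$n_y)
      rho_c <- surface$rho[row, col]
    }
  }

  thr <- thresholds
  labels <- as.character(thr)
  if (!is.na(rho_c)) {
    thr <- c(thr, rho_c)
    labels <- c(labels, "rho_c")
  }
  cell_km2 <- g$dx * g$dy / 1e6
  n_eval <- sum(!is.na(surface$rho))
  counts <- vapply(thr, function(tau) sum(surface$rho <= tau, na.rm = TRUE),
                   numeric(1))
  area_below <- counts * cell_km2
  percent_below <- 100 * counts / n_eval
  names(area_below) <- names(percent_below) <- labels

  structure(
    list(zp = zp, cc = cc, rho_c = rho_c,
         dist_zp_cc = sqrt(sum((zp - cc)^2)),
         dist_zp_roost = dist_zp_roost, dist_cc_roost = dist_cc_roost,
         roost = if (is.null(roost)) NULL else
           c(easting = roost[1L], northing = roost[2L]),
         area_below = area_below, percent_below = percent_below,
         mapped_area_km2 = n_eval * cell_km2),
    class = "roost_estimate"
  )
}

#' Qualitative confidence in the point prediction
#'
#' Empirically, the farther the argmin prediction `zp` drifts from the
#' centre of calls, the larger the true prediction error tends to be. This
#' rule of thumb turns the `zp`-`cc` separation into a coarse flag: when
#' the two estimators agree to within a few hundred metres, the roost is
#' usually within a few hundred metres of both.
#'
#' @param estimate A `roost_estimate`.
#' @param high,moderate Separation cut-offs in metres: below `high` the
#'   flag is `"high"`, below `moderate` it is `"moderate"`, else `"low"`.
#' @return One of `"high"`, `"moderate"`, `"low"`.
#' @export
confidence_heuristic <- function(estimate, high = 500, moderate = 1000) {
  stopifnot(inherits(estimate, "roost_estimate"), high <= moderate)
  d <- estimate$dist_zp_cc
  if (d < high) "high" else if (d < moderate) "moderate" else "low"
}

#' @export
print.rho_surface <- function(x, ...) {
  cat(sprintf("rho surface (%s mode, exponent %g): %d x %d cells\n",
              x$mode, x$exponent, x$grid$n_y, x$grid$n_x))
  cat(sprintf("  min rho %.4g at cell (%d, %d) -> zp = (%.1f, %.1f)\n",
              min(x$rho, na.rm = TRUE), x$argmin_cell[1L],
              x$argmin_cell[2L], x$zp[1L], x$zp[2L]))
  invisible(x)
}

#' @export
print.roost_estimate <- function(x, ...) {
  cat("Roost estimate\n")
  cat(sprintf("  zp (argmin rho) : (%.1f, %.1f)\n", x$zp[1L], x$zp[2L]))
  cat(sprintf("  centre of calls : (%.1f, %.1f)\n", x$cc[1L], x$cc[2L]))
  cat(sprintf("  |zp - CC|       : %.2f km\n", x$dist_zp_cc / 1000))
  if (!is.na(x$dist_zp_roost)) {
    cat(sprintf("  |zR - zp|       : %.2f km\n", x$dist_zp_roost / 1000))
    cat(sprintf("  |zR - CC|       : %.2f km\n", x$dist_cc_roost / 1000))
  }
  if (!is.na(x$rho_c)) {
    cat(sprintf("  rho at roost    : %.2f\n", x$rho_c))
  }
  cat("  % of mapped area below rho thresholds:\n")
  for (nm in names(x$percent_below)) {
    cat(sprintf("    rho <= %-6s: %6.2f %% (%.2f km^2)\n", nm,
                x$percent_below[[nm]], x$area_below[[nm]]))
  }
  invisible(x)
}

#' Heatmap of an error surface
#'
#' Base-graphics image of the \eqn{\rho} surface with contour lines,
#' detector positions (crosses), the argmin prediction (diamond), the
#' centre of calls (square) and, when known, the roost (circle).
#'
#' @param x A `rho_surface`.
#' @param levels Contour levels.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.rho_surface <- function(x, levels = c(0.1, 0.2, 0.3, 0.5, 0.8), ...) {
  g <- grid_centres(x$grid)
  z <- t(x$rho[rev(seq_len(x$grid$n_y)), , drop = FALSE])  # x right, y up
  ys <- rev(g$y)
  graphics::image(g$x, ys, z, col = grDevices::hcl.colors(64, "viridis",
                                                          rev = TRUE),
                  xlab = "easting (m)", ylab = "northing (m)",
                  useRaster = TRUE, ...)
  graphics::contour(g$x, ys, z, levels = levels, add = TRUE,
                    col = "white", labcex = 0.7)
  xy <- detector_coords(x$survey)
  graphics::points(xy, pch = 4, col = "black")
  graphics::points(x$zp[1L], x$zp[2L], pch = 23, bg = "white", cex = 1.3)
  cc <- centre_of_calls(x$survey)
  graphics::points(cc[1L], cc[2L], pch = 22, bg = "white", cex = 1.3)
  if (!is.null(x$survey$roost)) {
    graphics::points(x$survey$roost[1L], x$survey$roost[2L], pch = 21,
                     bg = "white", cex = 1.3)
  }
  invisible(x)
}

#' Export an error surface
#'
#' `write_rho_csv()` writes the surface as a plain CSV matrix (row 1 =
#' northernmost row, columns west to east). `write_esri_ascii()` writes an
#' ESRI ASCII grid (requires square cells) for use in GIS tools.
#'
#' @param surface A `rho_surface`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rho_csv <- function(surface, path) {
  stopifnot(inherits(surface, "rho_surface"))
  utils::write.table(surface$rho, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_rho_csv
#' @export
write_esri_ascii <- function(surface, path) {
  stopifnot(inherits(surface, "rho_surface"))
  g <- grid_centres(surface$grid)
  if (abs(g$dx - g$dy) > 1e-6 * g$dx) {
    stop("ESRI ASCII grids need square cells; use equal n_x/n_y spacing",
         call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", surface$grid$n_x),
    sprintf("nrows %d", surface$grid$n_y),
    sprintf("xllcorner %.6f", surface$grid$x_min),
    sprintf("yllcorner %.6f", surface$grid$y_min),
    sprintf("cellsize %.6f", g$dx),
    "NODATA_value -9999"), con)
  z <- surface$rho
  z[is.na(z)] <- -9999
  utils::write.table(z, con, sep = " ", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
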