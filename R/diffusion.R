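#' @title Forward model of nightly dispersal
#' @description Bats are modelled as leaving the roost at sunset and
#'   spreading as diffusive particles on the plane. The position density at
#'   time \eqn{t} of a bat from a roost at \eqn{z = (z_x, z_y)} is the heat
#'   kernel
#'   \deqn{\phi(x, y, z, t) = \frac{1}{4\pi D t}
#'     \exp\!\left(-\frac{(x-z_x)^2 + (y-z_y)^2}{4Dt}\right),}
#'   with \eqn{D} the diffusion coefficient. Integrating \eqn{\phi} over a
#'   detector's circular footprint gives the probability of a bat being
#'   detectable there at time \eqn{t}; integrating that over the post-sunset
#'   window gives the expected number of passes, and normalizing across
#'   detectors gives the expected call proportions that are compared with
#'   survey data.
#' @name diffusion-model
NULL

# Simpson weights for n nodes (n odd) on [0, upper].
simpson_weights <- function(n, upper) {
  stopifnot(n >= 3L, n %% 2L == 1L)
  h <- upper / (n - 1L)
  w <- rep(c(2, 4), length.out = n)
  w[1L] <- 1; w[n] <- 1
  w * h / 3
}

# Tensor polar quadrature over a disk of radius r centred at the origin:
# Gauss-Legendre in radius x uniform (periodic trapezoid) in angle.
# Returns offsets (x, y) and weights summing to pi * r^2.
disk_quadrature <- function(radius, n_radial, n_angular) {
  gl <- pracma::gaussLegendre(n_radial, 0, radius)
  theta <- 2 * pi * (seq_len(n_angular) - 1L) / n_angular
  list(
    x = as.vector(outer(gl$x, cos(theta))),
    y = as.vector(outer(gl$x, sin(theta))),
    w = rep(gl$w * gl$x, times = n_angular) * (2 * pi / n_angular)
  )
}

#' Dispersal probability density
#'
#' Evaluates the free-space heat kernel: the probability density per
#' m\eqn{^2} of a diffusing bat's position at time `t` after leaving a
#' roost at `roost`.
#'
#' @param x,y Evaluation coordinates, metres. Vectorized.
#' @param roost Roost coordinates `c(easting, northing)`.
#' @param t Time since sunset, seconds (> 0).
#' @param params A [diffusion_params()] object.
#' @return Density values (per m\eqn{^2}), strictly positive and radially
#'   symmetric about the roost.
#' @examples
#' p <- diffusion_params()
#' dispersal_density(0, 0, c(0, 0), t = 1, p)  # 1 / (320 * pi)
#' @export
dispersal_density <- function(x, y, roost, t, params = diffusion_params()) {
  if (any(t <= 0)) stop("'t' must be positive", call. = FALSE)
  d2 <- (x - roost[1L])^2 + (y - roost[2L])^2
  exp(-d2 / (4 * params$D * t)) / (4 * pi * params$D * t)
}

#' Probability of dispersing beyond a radius
#'
#' Closed-form tail probability that a diffusing bat is farther than `R`
#' from the roost at time `t`: integrating the dispersal density over the
#' disk of radius `R` leaves \eqn{\exp(-R^2 / 4Dt)} outside it. At the
#' default parameters (D = 80 m\eqn{^2}/s, t = 90 min) the probability of
#' being beyond 3 km — roughly the species' core sustenance zone — is about
#' 0.55\%, which justifies mapping only a few kilometres around the
#' detector array.
#'
#' @param R Radius in metres (> 0). Vectorized.
#' @param params A [diffusion_params()] object.
#' @param t Time in seconds (default the horizon `T`).
#' @return Tail probability in (0, 1].
#' @examples
#' prob_beyond_radius(3000, diffusion_params())  # < 0.01
#' @export
prob_beyond_radius <- function(R, params = diffusion_params(),
                               t = params$horizon) {
  stopifnot(all(R >= 0), all(t > 0))
  exp(-R^2 / (4 * params$D * t))
}

#' Detection probability: exact disk integral
#'
#' Probability that a bat from a roost at `roost` lies inside the circular
#' footprint of a detector at time `t`, computed by integrating the
#' dispersal density over the disk with a tensor polar quadrature
#' (Gauss-Legendre in radius, uniform in angle). When the detector sits on
#' the roost the disk integral has the closed form
#' \eqn{1 - \exp(-r^2/4Dt)}, which the quadrature reproduces to near
#' machine precision.
#'
#' @param detector Detector centre `c(easting, northing)`, metres.
#' @param roost Candidate roost `c(easting, northing)`, metres.
#' @param t Time(s) since sunset, seconds (> 0). Vectorized.
#' @param params A [diffusion_params()] object.
#' @return Probabilities in `[0, 1]`, one per element of `t`.
#' @seealso [detection_prob_approx()] for the fast algebraic approximation.
#' @export
detection_prob_exact <- function(detector, roost, t,
                                 params = diffusion_params()) {
  if (any(t <= 0)) stop("'t' must be positive", call. = FALSE)
  q <- disk_quadrature(params$detector_radius, params$quad_radial,
                       params$quad_angular)
  dq2 <- (detector[1L] + q$x - roost[1L])^2 +
         (detector[2L] + q$y - roost[2L])^2
  inv <- 1 / (4 * params$D * t)
  # rows: quadrature points, cols: times
  p <- as.vector(crossprod(q$w, exp(outer(-dq2, inv))) * (inv / pi))
  if (any(!is.finite(p)) || any(p < -1e-10) || any(p > 1 + 1e-10)) {
    stop("disk quadrature failed: value outside [0, 1] (min ",
         min(p), ", max ", max(p), ")", call. = FALSE)
  }
  pmin(pmax(p, 0), 1)
}

#' Detection probability: algebraic approximation
#'
#' Away from the roost the dispersal density is nearly constant across a
#' 15 m footprint, so the disk integral is well approximated by the density
#' at the detector centre times the disk area:
#' \deqn{\tilde P(t) = \frac{r^2}{4Dt}
#'   \exp\!\left(-\frac{d^2}{4Dt}\right),}
#' where \eqn{d} is the detector-roost distance. The expression diverges as
#' \eqn{t \to 0} when \eqn{d = 0}, so the value is clamped to `[0, 1]`
#' (it is a probability); the approximation is intended for detectors away
#' from the roost, where the clamp never engages.
#'
#' @inheritParams detection_prob_exact
#' @return Probabilities in `[0, 1]`, one per element of `t`.
#' @export
detection_prob_approx <- function(detector, roost, t,
                                  params = diffusion_params()) {
  if (any(t <= 0)) stop("'t' must be positive", call. = FALSE)
  d2 <- (detector[1L] - roost[1L])^2 + (detector[2L] - roost[2L])^2
  a <- params$detector_radius^2 / (4 * params$D * t)
  pmin(1, a * exp(-d2 / (4 * params$D * t)))
}

# Value of the time integrand at t = 0: the analytic limit is 0 whenever
# the detector centre is away from the roost, and 1 (the clamped value,
# all mass inside the disk) when it coincides with it.
integrand_at_zero <- function(d2) as.numeric(d2 <= .Machine$double.eps)

#' Expected passes per bat over the survey window
#'
#' Integrates the detection probability over \eqn{(0, T]} with Simpson's
#' rule on a uniform time grid (the integrand has no elementary
#' antiderivative). The result is the expected number of passes at the
#' detector per bat leaving the roost; absolute bat numbers cancel when
#' proportions are formed, so the per-bat scale is used throughout.
#'
#' @inheritParams detection_prob_exact
#' @param mode `"approx"` (default, the fast algebraic form) or `"exact"`
#'   (full disk quadrature at every time node).
#' @param time_steps Number of Simpson nodes (odd, >= 3); defaults to the
#'   value in `params`.
#' @return A non-negative scalar, monotone decreasing in the
#'   detector-roost distance.
#' @export
expected_calls <- function(detector, roost, params = diffusion_params(),
                           mode = c("approx", "exact"),
                           time_steps = params$time_steps) {
  mode <- match.arg(mode)
  time_steps <- as.integer(time_steps)
  if (time_steps < 3L || time_steps %% 2L == 0L) {
    stop("'time_steps' must be an odd integer >= 3", call. = FALSE)
  }
  tk <- seq(0, params$horizon, length.out = time_steps)
  w <- simpson_weights(time_steps, params$horizon)
  pfun <- if (mode == "approx") detection_prob_approx else
    detection_prob_exact
  d2 <- (detector[1L] - roost[1L])^2 + (detector[2L] - roost[2L])^2
  vals <- c(integrand_at_zero(d2), pfun(detector, roost, tk[-1L], params))
  sum(w * vals)
}

# Expected passes for every detector row of xy (N x 2 matrix) for one
# candidate roost. Vectorized over detectors and time nodes.
expected_calls_all <- function(xy, roost, params, mode = "approx",
                               time_steps = params$time_steps) {
  tk <- seq(0, params$horizon, length.out = time_steps)
  w <- simpson_weights(time_steps, params$horizon)
  inv <- 1 / (4 * params$D * tk[-1L])
  d2 <- (xy[, 1L] - roost[1L])^2 + (xy[, 2L] - roost[2L])^2
  if (mode == "approx") {
    m <- exp(outer(-d2, inv))
    m <- sweep(m, 2L, params$detector_radius^2 * inv, `*`)
    m[m > 1] <- 1
  } else {
    q <- disk_quadrature(params$detector_radius, params$quad_radial,
                         params$quad_angular)
    m <- matrix(0, nrow(xy), length(inv))
    for (i in seq_len(nrow(xy))) {
      dq2 <- (xy[i, 1L] + q$x - roost[1L])^2 +
             (xy[i, 2L] + q$y - roost[2L])^2
      m[i, ] <- crossprod(q$w, exp(outer(-dq2, inv))) * (inv / pi)
    }
    m[m > 1] <- 1
  }
  as.vector(cbind(integrand_at_zero(d2), m) %*% w)
}

#' Expected call proportions across a survey's detectors
#'
#' For a candidate roost position, computes the expected share of all
#' calls at each detector: per-detector expected passes normalized across
#' the array. The number of bats in the roost cancels in the ratio, which
#' is why the method needs no colony-size estimate.
#'
#' @param survey A `survey_set`, detector data frame, or N x 2 coordinate
#'   matrix.
#' @param roost Candidate roost `c(easting, northing)`.
#' @param params A [diffusion_params()] object.
#' @param mode `"approx"` or `"exact"` detection integral.
#' @return Numeric vector of proportions summing to 1, in detector order.
#' @examples
#' ring <- detector_ring(4, radius = 500)
#' expected_proportions(ring, roost = c(0, 0))  # symmetric: all 0.25
#' @export
expected_proportions <- function(survey, roost,
                                 params = diffusion_params(),
                                 mode = c("approx", "exact")) {
  mode <- match.arg(mode)
  xy <- detector_coords(survey)
  e <- expected_calls_all(xy, roost, params, mode = mode)
  s <- sum(e)
  if (s <= 0) {
    stop("expected calls vanish at every detector: the candidate roost is ",
         "beyond numerical support; increase the horizon T or move ",
         "candidates closer to the array", call. = FALSE)
  }
  e / s
}
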