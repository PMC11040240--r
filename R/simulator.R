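#' Detector layout helpers
#'
#' Convenience constructors for synthetic survey designs: `detector_ring()`
#' places `n` detectors evenly on a circle, `detector_line()` spaces them
#' uniformly between two points (the layout used to study the accuracy of
#' the detection-integral approximation, with detectors from the roost out
#' to 3 km).
#'
#' @param n Number of detectors.
#' @param centre Ring centre `c(easting, northing)`.
#' @param radius Ring radius, metres.
#' @param from,to Line endpoints `c(easting, northing)`.
#' @return Data frame with columns `id`, `easting`, `northing`.
#' @export
detector_ring <- function(n, centre = c(0, 0), radius = 1500) {
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  data.frame(id = sprintf("d%02d", seq_len(n)),
             easting = centre[1L] + radius * cos(theta),
             northing = centre[2L] + radius * sin(theta))
}

#' @rdname detector_ring
#' @export
detector_line <- function(n, from = c(0, 0), to = c(3000, 0)) {
  s <- seq(0, 1, length.out = n)
  data.frame(id = sprintf("d%02d", seq_len(n)),
             easting = from[1L] + s * (to[1L] - from[1L]),
             northing = from[2L] + s * (to[2L] - from[2L]))
}

#' Simulation scenario
#'
#' Describes a synthetic survey: a roost position, the nightly number of
#' dispersing bats, the detector layout, and the movement parameters. The
#' default diffusion coefficient is 81.7 m\eqn{^2}/s — the value fitted
#' from radio-tracked trajectories — deliberately distinct from the
#' rounded 80 m\eqn{^2}/s used by the search model, so that validation
#' exercises retain the mild parameter mismatch a real survey would face.
#'
#' @param roost True roost `c(easting, northing)`, metres.
#' @param detectors Data frame with `id`, `easting`, `northing` (or a
#'   two-column coordinate matrix).
#' @param n_agents Bats dispersing per night.
#' @param n_nights Number of survey nights.
#' @param params A [diffusion_params()]; `D` is the movement rate and
#'   `horizon` the simulated window.
#' @param step_dt Euler-Maruyama time step, seconds. Brownian increments
#'   are exact in distribution at any step size, so `step_dt` only sets
#'   the resolution at which footprint crossings are detected.
#' @param refractory Dead time in seconds after a counted pass during
#'   which re-entries of the same bat at the same detector are not counted
#'   again (avoids double-counting jitter crossings; 0 disables).
#' @param seed Integer seed; together with the night index it fully
#'   determines every trajectory.
#' @param record_trajectories Keep (thinned) agent tracks.
#' @param thin Keep every `thin`-th trajectory point when recording.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(roost, detectors, n_agents = 600, n_nights = 5,
                         params = diffusion_params(D = 81.7),
                         step_dt = 1, refractory = 30, seed = 1,
                         record_trajectories = FALSE, thin = 60L) {
  roost <- as.numeric(roost)
  stopifnot(length(roost) == 2L, all(is.finite(roost)))
  if (is.null(dim(detectors))) stop("'detectors' must be tabular",
                                    call. = FALSE)
  xy <- detector_coords(detectors)
  ids <- if (is.data.frame(detectors) && "id" %in% names(detectors)) {
    as.character(detectors$id)
  } else sprintf("d%02d", seq_len(nrow(xy)))
  stopifnot(n_agents >= 1, n_nights >= 1, step_dt > 0,
            step_dt <= params$horizon, refractory >= 0)
  structure(
    list(roost = c(easting = roost[1L], northing = roost[2L]),
         detector_xy = xy, detector_ids = ids,
         n_agents = as.integer(n_agents), n_nights = as.integer(n_nights),
         params = params, step_dt = step_dt, refractory = refractory,
         seed = as.integer(seed),
         record_trajectories = isTRUE(record_trajectories),
         thin = as.integer(thin)),
    class = "sim_scenario"
  )
}

# Per-night RNG streams derived once from the scenario seed, so that
# simulate_night(scenario, k) is reproducible in isolation and nights are
# mutually independent.
night_seeds <- function(scenario) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(scenario$seed)
  sample.int(2147483646L, scenario$n_nights)
}

#' Simulate one night of dispersal
#'
#' All agents start at the roost and perform planar Brownian motion:
#' per axis, \eqn{x \leftarrow x + \sqrt{2 D \Delta t}\,\xi} with
#' \eqn{\xi \sim N(0,1)}, for `horizon / step_dt` steps. A detector counts
#' one pass per entry event — an agent moving from outside to inside its
#' circular footprint — subject to the refractory window. The random
#' stream is fully determined by `(seed, night_index)`.
#'
#' @param scenario A [sim_scenario()].
#' @param night_index Night number in `1:n_nights`.
#' @return List with `counts` (integer passes per detector), `msd`
#'   (empirical mean squared displacement from the roost after each step),
#'   `final_positions` (`n_agents` x 2), and `trajectories` (thinned
#'   data frame, or `NULL`).
#' @export
simulate_night <- function(scenario, night_index) {
  stopifnot(inherits(scenario, "sim_scenario"),
            night_index >= 1L, night_index <= scenario$n_nights)
  set.seed(night_seeds(scenario)[night_index])
  n <- scenario$n_agents
  dt <- scenario$step_dt
  n_steps <- floor(scenario$params$horizon / dt)
  sd_step <- sqrt(2 * scenario$params$D * dt)
  det <- scenario$detector_xy
  n_det <- nrow(det)
  r2 <- scenario$params$detector_radius^2

  px <- rep(scenario$roost[1L], n)
  py <- rep(scenario$roost[2L], n)
  inside <- matrix(FALSE, n, n_det)
  last_pass <- matrix(-Inf, n, n_det)
  counts <- integer(n_det)
  msd <- numeric(n_steps)
  keep <- scenario$record_trajectories
  if (keep) {
    kidx <- unique(c(seq(scenario$thin, n_steps, by = scenario$thin),
                     n_steps))
    traj <- vector("list", length(kidx))
    ki <- 1L
  }

  for (s in seq_len(n_steps)) {
    px <- px + sd_step * stats::rnorm(n)
    py <- py + sd_step * stats::rnorm(n)
    now <- (outer(px, det[, 1L], `-`))^2 +
           (outer(py, det[, 2L], `-`))^2 <= r2
    t_now <- s * dt
    entries <- now & !inside & (t_now - last_pass > scenario$refractory)
    if (any(entries)) {
      counts <- counts + colSums(entries)
      last_pass[entries] <- t_now
    }
    inside <- now
    msd[s] <- mean((px - scenario$roost[1L])^2 + (py - scenario$roost[2L])^2)
    if (keep && s == kidx[ki]) {
      traj[[ki]] <- data.frame(agent = seq_len(n), t = t_now, x = px, y = py)
      ki <- ki + 1L
    }
  }
  list(counts = as.integer(counts), msd = msd,
       final_positions = cbind(x = px, y = py),
       trajectories = if (keep) do.call(rbind, traj) else NULL)
}

#' Simulate a full survey
#'
#' Runs [simulate_night()] for every night and aggregates passes into the
#' detector-table schema consumed by [load_survey()]: total calls and
#' active nights per detector, with the ground-truth roost attached for
#' evaluation.
#'
#' @param scenario A [sim_scenario()].
#' @return An object of class `sim_result`: per-detector per-night
#'   `counts` matrix, `nights_active`, the night-averaged `msd` curve, the
#'   `scenario`, and optional pooled `trajectories`. Convert with
#'   [as_survey()].
#' @export
simulate_survey <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  nights <- lapply(seq_len(scenario$n_nights),
                   function(k) simulate_night(scenario, k))
  counts <- vapply(nights, `[[`, integer(nrow(scenario$detector_xy)),
                   "counts")
  counts <- matrix(counts, nrow = nrow(scenario$detector_xy),
                   dimnames = list(scenario$detector_ids, NULL))
  msd <- rowMeans(vapply(nights, `[[`,
                         numeric(length(nights[[1L]]$msd)), "msd"))
  traj <- if (scenario$record_trajectories) {
    do.call(rbind, lapply(seq_along(nights), function(k) {
      cbind(night = k, nights[[k]]$trajectories)
    }))
  } else NULL
  structure(
    list(counts = counts,
         nights_active = rep(scenario$n_nights, nrow(counts)),
         msd = msd, trajectories = traj, scenario = scenario),
    class = "sim_result"
  )
}

#' Impose detector failures on a simulated survey
#'
#' Real detectors fail mid-survey (batteries, vandalism, weather), so not
#' all run for every night. Each detector independently survives each
#' night with probability `survival`; once it fails it stays down, so its
#' active nights follow a geometric law truncated at the survey length.
#' Counts from nights after the failure are discarded.
#'
#' @param result A `sim_result`.
#' @param survival Per-night survival probability in (0, 1].
#' @param seed Integer seed for the failure draws.
#' @return A `sim_result` with truncated `counts` and `nights_active`.
#' @export
apply_failures <- function(result, survival, seed = 1) {
  stopifnot(inherits(result, "sim_result"),
            survival > 0, survival <= 1)
  if (survival == 1) return(result)
  set.seed(as.integer(seed))
  n_det <- nrow(result$counts)
  n_nights <- ncol(result$counts)
  # nights survived before first failure, capped at the survey length
  active <- pmin(stats::rgeom(n_det, prob = 1 - survival), n_nights)
  for (i in seq_len(n_det)) {
    if (active[i] < n_nights) {
      result$counts[i, (active[i] + 1L):n_nights] <- 0L
    }
  }
  result$nights_active <- active
  result
}

#' Convert a simulation result to a survey set
#'
#' @param result A `sim_result`.
#' @param attach_roost Record the ground-truth roost in the survey (for
#'   evaluation).
#' @return A `survey_set` (detectors with zero active nights are dropped
#'   with a warning, as for field data).
#' @export
as_survey <- function(result, attach_roost = TRUE) {
  stopifnot(inherits(result, "sim_result"))
  det <- data.frame(
    id = result$scenario$detector_ids,
    easting = result$scenario$detector_xy[, 1L],
    northing = result$scenario$detector_xy[, 2L],
    nights_active = result$nights_active,
    total_calls = as.integer(rowSums(result$counts))
  )
  survey_set(det, roost = if (attach_roost) result$scenario$roost else NULL)
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("Simulation scenario: %d agents x %d nights from (%.0f, %.0f)\n",
              x$n_agents, x$n_nights, x$roost[1L], x$roost[2L]))
  cat(sprintf("  %d detectors, D = %g m^2/s, dt = %g s, refractory %g s, seed %d\n",
              nrow(x$detector_xy), x$params$D, x$step_dt, x$refractory,
              x$seed))
  invisible(x)
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Simulated survey: %d detectors x %d nights, %d passes total\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}
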