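# Shared fixtures: all synthetic, built in code.

# Survey from explicit counts/nights at given coordinates.
make_survey <- function(calls, nights, xy, roost = NULL, ids = NULL) {
  xy <- matrix(xy, ncol = 2)
  if (is.null(ids)) ids <- sprintf("d%02d", seq_len(nrow(xy)))
  survey_set(data.frame(id = ids, easting = xy[, 1], northing = xy[, 2],
                        nights_active = nights, total_calls = calls),
             roost = roost)
}

# Survey whose observed proportions equal the forward model's expectation
# at `roost_true` (counts are proportions scaled up and rounded), so the
# error surface should bottom out at the true roost.
model_consistent_survey <- function(detectors, roost_true,
                                    params = diffusion_params(),
                                    total = 1e6) {
  f <- expected_proportions(detectors, roost_true, params)
  make_survey(calls = round(f * total),
              nights = rep(1L, nrow(detectors)),
              xy = detector_coords(detectors), roost = roost_true)
}

# Small, fast scenario for simulator tests.
quick_scenario <- function(roost = c(100, 50),
                           detectors = detector_ring(8, radius = 800),
                           n_agents = 100, n_nights = 2, step_dt = 5,
                           seed = 42, ...) {
  sim_scenario(roost = roost, detectors = detectors, n_agents = n_agents,
               n_nights = n_nights, step_dt = step_dt, seed = seed, ...)
}
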