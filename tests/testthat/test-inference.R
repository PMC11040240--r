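p_default <- diffusion_params()

test_that("error metric behaves like a weighted squared distance", {
  expect_equal(rho_metric(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(rho_metric(c(1, 0), c(0, 1)), 2)
  expect_error(rho_metric(c(1, 0), c(1, 0, 0)), "length")

  # exponent 2 punishes a mismatch at a high-count detector more than the
  # same total mismatch spread over low-count detectors; exponent 1 cannot
  # tell the two apart
  C <- c(0.7, 0.1, 0.1, 0.1)
  F_conc <- c(0.5, 0.3, 0.1, 0.1)   # 0.2 misfit at the busy detector
  F_spread <- c(0.6, 0.2, 0.2, 0.0) # same total misfit, spread thinly
  expect_equal(rho_metric(C, F_conc, exponent = 1),
               rho_metric(C, F_spread, exponent = 1))
  expect_gt(rho_metric(C, F_conc, exponent = 2),
            rho_metric(C, F_spread, exponent = 2))
})

test_that("surface bottoms out at the roost for model-consistent data", {
  ring <- detector_ring(4, radius = 1000)
  sv <- model_consistent_survey(ring, roost_true = c(0, 0))
  grid <- grid_from_survey(sv, n_x = 21)  # odd: centre cell centre = (0,0)
  surf <- build_rho_surface(sv, grid, p_default)
  expect_equal(unname(surf$argmin_cell), c(11L, 11L))
  expect_equal(unname(surf$zp), c(0, 0), tolerance = 1e-9)
  expect_lt(min(surf$rho), 1e-4)
  expect_equal(max(surf$rho), 1)  # normalization attains 1 exactly
})

test_that("surface is invariant to count scaling and scene translation", {
  xy <- cbind(c(-900, 200, 1100, -300, 600), c(100, 950, -300, -1000, 400))
  calls <- c(40, 120, 15, 8, 77)
  sv <- make_survey(calls, rep(2L, 5), xy)
  grid <- grid_from_survey(sv, n_x = 15)
  surf <- build_rho_surface(sv, grid, p_default)

  expect_true(all(surf$rho >= 0 & surf$rho <= 1))
  expect_equal(max(surf$rho), 1)

  # x10 calls: identical surface (proportions unchanged)
  sv10 <- make_survey(calls * 10L, rep(2L, 5), xy)
  surf10 <- build_rho_surface(sv10, grid, p_default)
  expect_equal(surf10$rho, surf$rho)

  # rigid translation: same surface values, shifted argmin location
  shift <- c(340000, 82000)
  sv_t <- make_survey(calls, rep(2L, 5), sweep(xy, 2, shift, `+`))
  grid_t <- grid_spec(grid$x_min + shift[1], grid$x_max + shift[1],
                      grid$y_min + shift[2], grid$y_max + shift[2],
                      grid$n_x, grid$n_y)
  surf_t <- build_rho_surface(sv_t, grid_t, p_default)
  expect_equal(surf_t$rho, surf$rho, tolerance = 1e-9)
  expect_equal(unname(surf_t$zp), unname(surf$zp + shift), tolerance = 1e-6)
})

test_that("approx-mode surface matches an exact brute-force recomputation", {
  # all detectors are >= 600 m from every grid cell centre, well inside
  # the regime where the algebraic approximation holds
  ring <- detector_ring(6, radius = 1200)
  sv <- make_survey(c(30, 55, 12, 70, 41, 9), rep(1L, 6),
                    detector_coords(ring))
  grid <- grid_spec(-600, 600, -600, 600, 10, 10)
  s_approx <- build_rho_surface(sv, grid, p_default, mode = "approx")
  s_exact <- build_rho_surface(sv, grid, p_default, mode = "exact")
  rel <- abs(s_approx$raw_sse - s_exact$raw_sse) / s_exact$raw_sse
  expect_lt(max(rel), 0.02)
})

test_that("surface values do not depend on cell evaluation order", {
  xy <- cbind(c(-500, 400, 100), c(-300, -100, 450))
  sv <- make_survey(c(20, 35, 10), rep(1L, 3), xy)
  grid <- grid_from_survey(sv, n_x = 8, n_y = 8)
  surf <- build_rho_surface(sv, grid, p_default)

  # brute-force recomputation, visiting cells in reversed order
  g <- roostfinder:::grid_centres(grid)
  C <- sv$detectors$proportion
  raw <- matrix(NA_real_, 8, 8)
  for (j in 8:1) {
    for (i in 8:1) {
      f <- expected_proportions(sv, c(g$x[j], g$y[i]), p_default)
      raw[i, j] <- rho_metric(C, f)
    }
  }
  expect_equal(surf$rho, raw / max(raw), tolerance = 1e-12)
})

test_that("argmin ties break to the first cell in row-major order", {
  # two detectors symmetric about x = 0 with equal counts: the surface is
  # mirror-symmetric, so minima come in pairs
  sv <- make_survey(c(10, 10), c(1L, 1L), c(-400, 400, 0, 0))
  grid <- grid_spec(-500, 500, -200, 200, 10, 4)
  expect_message(
    surf <- build_rho_surface(sv, grid, p_default),
    "tie"
  )
  m <- t(surf$rho)
  first_rm <- which(m == min(m))[1]
  expect_equal((first_rm - 1) %/% grid$n_x + 1, unname(surf$argmin_cell["row"]))
  expect_equal((first_rm - 1) %% grid$n_x + 1, unname(surf$argmin_cell["col"]))
})

test_that("centre of calls is the call-weighted detector mean, inside the hull", {
  # all calls at one detector -> that detector's position
  sv <- make_survey(c(0, 25, 0), rep(1L, 3), c(0, 500, 900, 0, 200, -400))
  expect_equal(unname(centre_of_calls(sv)), c(500, 200))

  # equal calls at the corners of a square -> its centre
  sq <- make_survey(rep(4L, 4), rep(1L, 4),
                    c(0, 0, 1000, 1000, 0, 1000, 0, 1000))
  expect_equal(unname(centre_of_calls(sq)), c(500, 500))

  # convexity: CC lies in the detector hull for many random surveys
  set.seed(31)
  for (i in 1:200) {
    n <- sample(3:15, 1)
    xy <- cbind(runif(n, -3000, 3000), runif(n, -3000, 3000))
    calls <- rpois(n, 20)
    if (sum(calls) == 0) calls[1] <- 1
    sv <- make_survey(calls, rep(1L, n), xy)
    expect_true(roostfinder:::point_in_hull(centre_of_calls(sv), xy))
  }
})

test_that("search statistics report rho at the roost and cumulative areas", {
  ring <- detector_ring(8, radius = 1000)
  sv <- model_consistent_survey(ring, roost_true = c(200, -150))
  surf <- build_rho_surface(sv, grid_from_survey(sv, n_x = 40), p_default)
  est <- search_statistics(surf)

  expect_s3_class(est, "roost_estimate")
  # the roost cell is itself part of the rho <= rho_c region
  expect_true(est$percent_below[["rho_c"]] > 0)
  expect_true(est$percent_below[["rho_c"]] < 100)
  # thresholds are cumulative
  expect_true(all(diff(est$percent_below[c("0.1", "0.2", "0.3")]) >= 0))
  # full threshold covers everything
  est1 <- search_statistics(surf, thresholds = c(0, 1))
  expect_equal(est1$percent_below[["1"]], 100)
  expect_equal(est1$area_below[["1"]], est1$mapped_area_km2)
  # model-consistent data: prediction lands on the roost cell
  expect_lt(est$dist_zp_roost, sqrt(2) * 2000 / 40)

  # roost outside the grid: warning, rho_c undefined
  expect_warning(est2 <- search_statistics(surf, roost = c(99999, 0)),
                 "outside")
  expect_true(is.na(est2$rho_c))

  # degenerate flat surface: everything is "searched" only at rho = 1
  flat <- surf
  flat$rho[] <- 1
  est3 <- search_statistics(flat, roost = NULL,
                            thresholds = c(0.999, 1))
  expect_equal(est3$percent_below[["0.999"]], 0)
  expect_equal(est3$percent_below[["1"]], 100)
})

test_that("confidence flag follows the zp-CC separation rule of thumb", {
  fake <- function(d) {
    structure(list(zp = c(0, 0), cc = c(d, 0), dist_zp_cc = d),
              class = "roost_estimate")
  }
  expect_equal(confidence_heuristic(fake(0)), "high")
  expect_equal(confidence_heuristic(fake(280)), "high")
  expect_equal(confidence_heuristic(fake(700)), "moderate")
  expect_equal(confidence_heuristic(fake(5000)), "low")
  expect_equal(confidence_heuristic(fake(700), high = 750), "high")
})
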