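test_that("grid spec validates its fields", {
  expect_error(grid_spec(n_points = 1), "n_points")
  expect_error(grid_spec(window_sd = 0), "window_sd")
  expect_error(grid_spec(range = c(1, 0)), "range")
})

test_that("kernel interpolation reproduces constants and single cells", {
  g <- grid_spec()
  s <- tibble::tibble(time = c(0.1, 0.4, 0.9), abundance = rep(2.5, 3))
  expect_equal(interpolate_trajectory(s, g)$value, rep(2.5, 200))
  one <- tibble::tibble(time = 0.3, abundance = 2.1)
  expect_equal(interpolate_trajectory(one, g)$value, rep(2.1, 200))
  expect_error(interpolate_trajectory(one[0, ], g), "sample")
})

test_that("interpolated values match a brute-force kernel oracle", {
  g <- grid_spec(n_points = 201)  # grid containing t = 0.5 exactly
  s <- tibble::tibble(time = c(0, 0.5, 1), abundance = c(1, 1.5, 2))
  traj <- interpolate_trajectory(s, g)
  expect_equal(traj$value[traj$grid_time == 0.5], 1.5, tolerance = 1e-7)
  # every grid point agrees with the point-wise oracle
  oracle <- vapply(traj$grid_time, function(at) {
    oracle_kernel_point(s$time, s$abundance, at, g$window_sd)
  }, numeric(1))
  expect_equal(traj$value, oracle, tolerance = 1e-12)
  # bounded by the sample's abundance range
  expect_true(all(traj$value >= 1 & traj$value <= 2))
})

test_that("reference lines follow the stated anchoring algebra", {
  g <- grid_spec()
  flat <- reference_line(0, 1.37, g)
  expect_equal(flat$value, rep(1.37, 200))
  expect_identical(attr(flat, "provenance"), "reference_constant")
  lin <- reference_line(1, 1, g, "intercept_at_zero")
  expect_equal(lin$value[1], 1)
  expect_equal(lin$value[200], 2)
  cen <- reference_line(2, 1, g, "center_at_mean")
  expect_equal(cen$value[1], 0)
  expect_equal(cen$value[200], 2)
  expect_equal(cen$value[which.min(abs(cen$grid_time - 0.5))],
               1, tolerance = 0.02)
})

test_that("area_between matches hand values and the analytic integral", {
  g <- grid_spec()
  a <- reference_line(1, 1, g, "intercept_at_zero")
  expect_equal(area_between(a, a), 0)
  expect_equal(area_between(make_traj(1), make_traj(2)), 1)
  # y = t vs y = 0: discrete mean of the grid is exactly 0.5; analytic 0.5
  ramp <- reference_line(1, 0, g, "intercept_at_zero")
  zero <- reference_line(0, 0, g)
  expect_equal(area_between(ramp, zero), 0.5, tolerance = 0.003)
  expect_error(area_between(a, reference_line(1, 1, grid_spec(100))),
               "grid")
})

test_that("area_between is a pseudometric on random trajectory triples", {
  withr::with_seed(31, {
    for (i in 1:20) {
      a <- make_traj(rnorm(200))
      b <- make_traj(rnorm(200))
      c3 <- make_traj(rnorm(200))
      expect_gte(area_between(a, b), 0)
      expect_equal(area_between(a, b), area_between(b, a))
      expect_lte(area_between(a, c3),
                 area_between(a, b) + area_between(b, c3) + 1e-12)
    }
  })
})

test_that("interpolation is shift- and scale-equivariant", {
  g <- grid_spec()
  s <- withr::with_seed(8, tibble::tibble(time = runif(16),
                                          abundance = rnorm(16, 1, 0.5)))
  base <- interpolate_trajectory(s, g)$value
  shifted <- dplyr::mutate(s, abundance = abundance + 3.2)
  expect_equal(interpolate_trajectory(shifted, g)$value, base + 3.2)
  scaled <- dplyr::mutate(s, abundance = abundance * 4)
  expect_equal(interpolate_trajectory(scaled, g)$value, base * 4)
})

test_that("refining the grid barely changes the normalised area", {
  s <- withr::with_seed(9, tibble::tibble(time = runif(30),
                                          abundance = rnorm(30, 1, 0.3)))
  abc <- vapply(c(200L, 400L), function(np) {
    g <- grid_spec(n_points = np)
    area_between(interpolate_trajectory(s, g),
                 reference_line(1, 1, g, "intercept_at_zero"))
  }, numeric(1))
  expect_lt(abs(abc[2] - abc[1]) / abc[1], 0.01)
})

test_that("trajectories round-trip through CSV", {
  g <- grid_spec(50)
  tr <- reference_line(1.5, 0.2, g, "center_at_mean")
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_identical(back$value, tr$value)
})
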