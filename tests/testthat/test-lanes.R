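straight_lane <- function(x = 10, w = 3, h = 100) {
  lane_path(tibble::tibble(y = c(0, h - 1), x = x, w = w))
}

test_that("lane paths must run strictly downward (no horizontal segment)", {
  expect_silent(validate_lane_path(straight_lane(), c(100, 50)))
  expect_error(lane_path(tibble::tibble(y = c(0, 0), x = c(10, 20), w = 3)),
               "horizontal")
  expect_error(lane_path(tibble::tibble(y = c(0, 50, 40), x = c(10, 12, 14), w = 3)),
               "horizontal|increasing")
  expect_error(lane_path(tibble::tibble(y = 0, x = 10, w = 3)), "2 nodes")
  expect_error(lane_path(tibble::tibble(y = c(0, 10), x = c(5, 5), w = c(0, 2))),
               "> 0")
})

test_that("paths outside image rows are rejected; edge-clipped widths are logged", {
  p <- straight_lane(h = 120)
  expect_error(validate_lane_path(p, c(100, 50)), "outside image rows")
  edge <- lane_path(tibble::tibble(y = c(0, 99), x = 1, w = 5))
  expect_message(validate_lane_path(edge, c(100, 50)), "clipped")
})

test_that("lane_center interpolates linearly and exactly at nodes", {
  p <- lane_path(tibble::tibble(y = c(0, 10), x = c(0, 10), w = c(2, 4)))
  mid <- lane_center(p, 5)
  expect_equal(mid$x, 5)
  expect_equal(mid$w, 3)
  at0 <- lane_center(p, 0)
  expect_equal(c(at0$x, at0$w), c(0, 2))
  expect_error(lane_center(p, 11), "outside lane span")
})

test_that("lane_center matches an independent two-point interpolation oracle", {
  set.seed(31)
  for (i in 1:20) {
    p <- random_monotone_path(80, 60)
    ys <- runif(10, min(p$y), max(p$y))
    got <- lane_center(p, ys)
    for (k in seq_along(ys)) {
      j <- max(which(p$y <= ys[k] + 1e-12))
      if (j == nrow(p)) j <- j - 1L
      t <- (ys[k] - p$y[j]) / (p$y[j + 1] - p$y[j])
      expect_equal(got$x[k], (1 - t) * p$x[j] + t * p$x[j + 1], tolerance = 1e-9)
      expect_equal(got$w[k], (1 - t) * p$w[j] + t * p$w[j + 1], tolerance = 1e-9)
    }
  }
})

test_that("profile of a constant raster counts included columns exactly", {
  r <- gel_raster(matrix(2, 50, 30))
  prof <- lane_profile(r, straight_lane(x = 10, w = 3, h = 50))
  expect_true(all(prof$intensity == 14))   # 7 columns x intensity 2
  expect_equal(prof$row, 0:49)
  zero <- lane_profile(gel_raster(matrix(0, 50, 30)), straight_lane(h = 50))
  expect_true(all(zero$intensity == 0))
})

test_that("curved-lane profile equals brute-force per-row summation", {
  set.seed(32)
  sp <- synth_spec(80, 60,
                   lanes = tibble::tibble(x0 = 30, curvature = 5e-4, half_width = 8),
                   bands = tibble::tibble(lane = 1, mu = 40, sigma_y = 5,
                                          sigma_x = 3, amount = 5000),
                   noise_sd = 1, seed = 5)
  g <- synth_gel(sp)
  p <- synth_lane_paths(sp, step = 10)[[1]]
  got <- lane_profile(g$raster, p)
  want <- brute_lane_profile(unclass(g$raster), p)
  expect_equal(got$intensity, want$intensity, tolerance = 1e-9)
})

test_that("baselines are piecewise linear with constant extrapolation", {
  b <- gel_baseline(tibble::tibble(y = c(0, 10), b = c(0, 10)))
  expect_equal(baseline_at(b, 5), 5)
  expect_equal(baseline_at(b, c(-5, 15)), c(0, 10))
  expect_equal(baseline_at(gel_baseline(), c(0, 50, 1e4)), c(0, 0, 0))
  single <- gel_baseline(tibble::tibble(y = 0, b = 4))
  expect_equal(baseline_at(single, 100), 4)
  expect_error(gel_baseline(tibble::tibble(y = c(5, 5), b = 1)), "increasing")
  expect_error(gel_baseline(tibble::tibble(y = c(0, 5), b = c(-1, 0))), ">= 0")
})

test_that("measure integrates profile minus baseline over a half-open region", {
  r <- gel_raster(matrix(2, 50, 30))
  prof <- lane_profile(r, straight_lane(x = 10, w = 3, h = 50))
  v <- measure(prof, gel_baseline(), measurement_region(0, 10))
  expect_equal(v$value, 140)
  expect_true(v$success)
  flat_bl <- gel_baseline(tibble::tibble(y = 0, b = 14))
  expect_equal(measure(prof, flat_bl, measurement_region(0, 10))$value, 0)
  high_bl <- gel_baseline(tibble::tibble(y = 0, b = 20))
  expect_warning(measure(prof, high_bl, measurement_region(0, 10)), "baseline")
  expect_error(measure(prof, gel_baseline(), measurement_region(40, 60)),
               "outside profile")
  expect_error(measurement_region(5, 5), "y0 < y1")
})

test_that("a fully contained band measures within 2% of the injected amount", {
  sp <- synth_spec(100, 60,
                   lanes = tibble::tibble(x0 = 30, curvature = 0, half_width = 12),
                   bands = tibble::tibble(lane = 1, mu = 50, sigma_y = 4,
                                          sigma_x = 3, amount = 8000),
                   noise_sd = 0, seed = 1)
  g <- synth_gel(sp)
  prof <- lane_profile(g$raster, synth_lane_paths(sp)[[1]])
  v <- measure(prof, gel_baseline(), measurement_region(20, 81))
  expect_equal(v$value, 8000, tolerance = 0.02)
})

test_that("measurement is additive, linear, and width-monotone", {
  set.seed(33)
  m <- matrix(runif(60 * 40) * 20, 60, 40)
  r <- gel_raster(m)
  p <- straight_lane(x = 20, w = 5, h = 60)
  prof <- lane_profile(r, p)
  v1 <- measure(prof, gel_baseline(), measurement_region(0, 20))$value
  v2 <- measure(prof, gel_baseline(), measurement_region(20, 45))$value
  v12 <- measure(prof, gel_baseline(), measurement_region(0, 45))$value
  expect_identical(v1 + v2, v12)
  # linearity: scaling raster and baseline by k scales v by exactly k
  bl <- gel_baseline(tibble::tibble(y = c(0, 59), b = c(1, 3)))
  k <- 3
  prof_k <- lane_profile(gel_raster(k * m), p)
  bl_k <- gel_baseline(tibble::tibble(y = c(0, 59), b = k * c(1, 3)))
  expect_equal(measure(prof_k, bl_k, measurement_region(0, 40))$value,
               k * measure(prof, bl, measurement_region(0, 40))$value,
               tolerance = 1e-12)
  expect_identical(k * prof$intensity, prof_k$intensity)
  # widening the lane can only add non-negative pixels
  wide <- lane_profile(r, straight_lane(x = 20, w = 9, h = 60))
  expect_true(all(wide$intensity >= prof$intensity))
})

test_that("a straight band tolerates lateral lane misplacement", {
  sp <- synth_spec(100, 80,
                   lanes = tibble::tibble(x0 = 40, curvature = 0, half_width = 14),
                   bands = tibble::tibble(lane = 1, mu = 50, sigma_y = 4,
                                          sigma_x = 3, amount = 10000),
                   noise_sd = 0, seed = 1)
  g <- synth_gel(sp)
  region <- measurement_region(20, 81)
  v_at <- function(dx) {
    p <- lane_path(tibble::tibble(y = c(0, 99), x = 40 + dx, w = 14))
    measure(lane_profile(g$raster, p), gel_baseline(), region)$value
  }
  v0 <- v_at(0)
  for (dx in c(-4, -2, 2, 4)) {   # delta <= w - 3 sigma = 5
    expect_lt(abs(v_at(dx) - v0) / v0, 0.01)
  }
})
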