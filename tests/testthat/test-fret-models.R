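test_that("point-geometry inversion matches the Forster equation", {
  # E = 0.5 -> r = R0, the defining property of the Forster radius
  est <- distance_from_efficiency_point(0.5, 17.6)
  expect_equal(est$r, 17.6, tolerance = 1e-12)
  # round-trip identity E -> r -> E across the open interval
  for (E in c(1e-4, 0.05, 0.2, 0.5, 0.8, 0.99)) {
    r <- distance_from_efficiency_point(E, 14)$r
    expect_equal(1 / (1 + (r / 14)^6), E, tolerance = 1e-12)
  }
  # controls give a typed no-distance result, never NaN
  nd <- distance_from_efficiency_point(-0.06, 17.6)
  expect_true(is.na(nd$r))
  expect_equal(nd$reason, "non-positive efficiency")
  expect_equal(format_distance(nd), "N/A")
  expect_error(distance_from_efficiency_point(1, 17.6), "below 1")
  expect_error(distance_from_efficiency_point(0.5, -2), "positive")
})

test_that("reported distances round half away from zero", {
  expect_equal(distance_from_efficiency_point(0.43, 17.6)$r_reported, 18L)
  # 22.17 -> 22; 26.44 -> 26
  expect_equal(distance_from_efficiency_point(0.20, 17.6)$r_reported, 22L)
  expect_equal(distance_from_efficiency_point(0.08, 17.6)$r_reported, 26L)
})

test_that("planar efficiency has the right limits and monotonicities", {
  expect_equal(planar_efficiency(10, 12.4, 0), 0)
  E <- planar_efficiency(seq(2, 40, by = 2), 12.4, 0.002)
  expect_true(all(diff(E) < 0))          # decreasing in d
  expect_true(all(E >= 0 & E < 1))
  # increasing in sigma and R0
  expect_gt(planar_efficiency(10, 12.4, 0.004), planar_efficiency(10, 12.4, 0.002))
  expect_gt(planar_efficiency(10, 14, 0.002), planar_efficiency(10, 12.4, 0.002))
  expect_error(planar_efficiency(-1, 12.4, 0.002), "positive")
})

test_that("rate-sum approximation is exact algebra and bounds the average", {
  expect_equal(rate_sum_planar_efficiency(10, 12.4, 0), 0)
  # E = 0.5 exactly when d^4 = pi sigma R0^6 / 2
  sigma <- 0.002; R0 <- 12.4
  d_half <- (pi * sigma * R0^6 / 2)^(1 / 4)
  expect_equal(rate_sum_planar_efficiency(d_half, R0, sigma), 0.5,
               tolerance = 1e-12)
  # Jensen: mean-rate form >= configurational average everywhere
  for (d in c(4, 8, 12, 20, 30)) {
    expect_gte(rate_sum_planar_efficiency(d, R0, sigma),
               planar_efficiency(d, R0, sigma))
  }
})

test_that("Monte-Carlo oracle agrees with the planar integral", {
  # modest n here; the full 12-point x 1e5 grid runs in the acceptance suite
  for (case in list(c(6, 12.4, 0.002), c(10, 12.4, 0.002),
                    c(15, 12.4, 0.004))) {
    d <- case[1]; R0 <- case[2]; sig <- case[3]
    mc <- mc_planar_oracle(d, R0, sig, n_config = 2e4, seed = 101)
    expect_lt(abs(mc$E_hat - planar_efficiency(d, R0, sig)), 3 * mc$SE)
  }
  # sigma = 0 -> exactly zero with zero SE
  expect_equal(mc_planar_oracle(10, 12.4, 0, n_config = 100),
               list(E_hat = 0, SE = 0))
  # enlarging the disc beyond 5 R0 changes nothing beyond noise
  m1 <- mc_planar_oracle(10, 12.4, 0.002, n_config = 2e4, seed = 5)
  m2 <- mc_planar_oracle(10, 12.4, 0.002, n_config = 2e4,
                         disc_radius = 2 * (5 * 12.4 + 10), seed = 5)
  expect_lt(abs(m1$E_hat - m2$E_hat), 3 * sqrt(m1$SE^2 + m2$SE^2))
  expect_error(mc_planar_oracle(10, 12.4, 0.002, disc_radius = 20),
               "at least")
})

test_that("planar inversion round-trips and honours the distance floor", {
  R0 <- 12.4; sigma <- 0.002
  for (d in c(6, 10, 20)) {
    E <- planar_efficiency(d, R0, sigma)
    est <- invert_planar_efficiency(E, R0, sigma)
    expect_equal(est$r, d, tolerance = 0.01)
    expect_false(est$beyond_range)
  }
  # an efficiency above the floor value reports as beyond range (<=5)
  E_floor <- planar_efficiency(5, R0, sigma)
  est <- invert_planar_efficiency(E_floor + 0.05, R0, sigma, d_floor = 5)
  expect_true(est$beyond_range)
  expect_equal(format_distance(est), "<=5")
  # the tabulated memFRET example: E = 0.42 near d = 10 A
  est42 <- invert_planar_efficiency(0.42, R0, sigma)
  expect_lt(abs(est42$r - 10), 2)
  # no-distance result for controls
  expect_true(is.na(invert_planar_efficiency(-0.1, R0, sigma)$r))
  # rate-sum variant also round-trips
  E_rs <- rate_sum_planar_efficiency(12, R0, sigma)
  expect_equal(invert_planar_efficiency(E_rs, R0, sigma,
                                        model = "rate_sum")$r, 12,
               tolerance = 0.01)
})

test_that("surface-density calibration round-trips through the forward model", {
  R0 <- 12.4; d_probe <- 10
  E_probe <- planar_efficiency(d_probe, R0, 0.002)
  expect_equal(calibrate_surface_density(E_probe, d_probe, R0), 0.002,
               tolerance = 1e-5 / 0.002)
  expect_equal(calibrate_surface_density(0, d_probe, R0), 0)
  # +/- 0.01 in E propagates to a sigma interval that brackets the truth
  sig_lo <- calibrate_surface_density(E_probe - 0.01, d_probe, R0)
  sig_hi <- calibrate_surface_density(E_probe + 0.01, d_probe, R0)
  expect_true(sig_lo < 0.002 && 0.002 < sig_hi)
  expect_error(calibrate_surface_density(0.999, d_probe, R0,
                                         sigma_max = 1e-5), "no density")
})
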