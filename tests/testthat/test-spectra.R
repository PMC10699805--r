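test_that("spectrum CSV round-trip validates grids", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,value", "410,2", "400,1", "420,1"), path)
  s <- read_spectrum(path, kind = "emission")
  expect_s3_class(s, "fret_spectrum")
  expect_equal(nrow(s), 3L)
  # out-of-order rows sorted ascending on load
  expect_equal(s$wavelength_nm, c(400, 410, 420))
  expect_equal(s$value, c(1, 2, 1))

  writeLines(c("wavelength_nm,value", "400,1", "400,2"), path)
  expect_error(read_spectrum(path, kind = "emission"), "duplicate")
  writeLines(c("wavelength_nm,value", "400,1", "oops,2"), path)
  expect_error(read_spectrum(path, kind = "emission"), "non-numeric")

  s2 <- gen_spectrum(470, 40, "emission")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s2, p2)
  expect_equal(read_spectrum(p2, "emission")$value, s2$value)
})

test_that("extinction conversion follows Beer-Lambert and averages replicates", {
  grid <- seq(500, 700, by = 2)
  zero <- spectrum(grid, rep(0, length(grid)), kind = "absorbance")
  expect_true(all(extinction_from_absorbance(zero, 1)$value == 0))

  one <- spectrum(c(500, 600), c(1, 1), kind = "absorbance")
  expect_equal(extinction_from_absorbance(one, 1, 1)$value, c(1, 1))
  # low-extinction metal band measured at 2 mM: A = 0.004 -> 2 M^-1 cm^-1
  low <- spectrum(c(500, 600), c(0.004, 0.004), kind = "absorbance")
  expect_equal(extinction_from_absorbance(low, 2e-3, 1)$value, c(2, 2))

  # three replicates averaged pointwise before conversion
  reps <- lapply(c(0.9, 1.0, 1.1), function(k)
    spectrum(grid, k * exp(-(grid - 600)^2 / 800), kind = "absorbance"))
  avg <- extinction_from_absorbance(reps, 1e-3)
  expect_equal(avg$value, 1000 * exp(-(grid - 600)^2 / 800))

  expect_error(extinction_from_absorbance(one, 0), "positive")
  expect_error(extinction_from_absorbance(one, 1, -1), "positive")
})

test_that("overlap integral matches delta-limit and Gaussian closed forms", {
  # zero extinction -> J = 0
  donor <- gen_spectrum(470, 20, "emission", grid = seq(380, 560, 0.5))
  eps0 <- spectrum(c(380, 560), c(0, 0), kind = "extinction")
  expect_equal(overlap_integral(donor, eps0), 0)

  # narrow donor spike at 500 nm against flat extinction 100:
  # J -> 100 * 500^4 as the spike narrows
  for (w in c(2, 1, 0.5)) {
    spike <- gen_spectrum(500, w, "emission", grid = seq(480, 520, 0.02))
    flat <- spectrum(c(380, 620), c(100, 100), kind = "extinction")
    expect_equal(overlap_integral(spike, flat), 100 * 500^4,
                 tolerance = (w / 500)^2 * 50)
  }
  expect_equal(overlap_integral(gen_spectrum(500, 0.5, "emission",
                                             grid = seq(480, 520, 0.02)),
                                spectrum(c(380, 620), c(100, 100),
                                         kind = "extinction")),
               6.25e12, tolerance = 1e-4)

  # Gaussian donor x Gaussian extinction: closed-form Gaussian-product
  # moment integral (donor 470/20 nm, acceptor 500/25 nm, peak 100)
  mu_d <- 470; s_d <- 20; mu_a <- 500; s_a <- 25; e0 <- 100
  s2 <- 1 / (1 / s_d^2 + 1 / s_a^2)
  mu <- (mu_d / s_d^2 + mu_a / s_a^2) * s2
  amp <- e0 * exp(-(mu_d - mu_a)^2 / (2 * (s_d^2 + s_a^2)))
  m4 <- mu^4 + 6 * mu^2 * s2 + 3 * s2^2
  J_exact <- amp * sqrt(2 * pi * s2) * m4 / (sqrt(2 * pi) * s_d)
  grid <- seq(350, 650, by = 0.25)
  J_num <- overlap_integral(
    gen_spectrum(mu_d, s_d, "emission", grid = grid),
    gen_spectrum(mu_a, s_a, "extinction", scale = e0, grid = grid))
  expect_equal(J_num, J_exact, tolerance = 1e-3)

  # J invariant under donor rescaling (normalized spectral overlap)
  d10 <- gen_spectrum(mu_d, s_d, "emission", scale = 10, grid = grid)
  eps <- gen_spectrum(mu_a, s_a, "extinction", scale = e0, grid = grid)
  expect_equal(overlap_integral(d10, eps), J_num, tolerance = 1e-12)

  # disjoint grids rejected
  expect_error(overlap_integral(
    gen_spectrum(400, 10, "emission", grid = seq(350, 450, 1)),
    spectrum(c(500, 600), c(1, 1), kind = "extinction")), "overlap")
})

test_that("overlap quadrature converges under grid refinement", {
  J_at <- function(h) overlap_integral(
    gen_spectrum(470, 20, "emission", grid = seq(350, 650, h)),
    gen_spectrum(500, 25, "extinction", scale = 100,
                 grid = seq(350, 650, h)))
  expect_equal(J_at(1), J_at(0.5), tolerance = 1e-3)
})

test_that("Forster radius follows the sixth-root scaling law", {
  cal <- forster_radius(fret_calibration(J = 1e13))
  expect_gt(cal$R0, 0)
  # J = 0 -> R0 = 0
  expect_equal(forster_radius(fret_calibration(J = 0))$R0, 0)
  # doubling J scales R0 by 2^(1/6)
  cal2 <- forster_radius(fret_calibration(J = 2e13))
  expect_equal(cal2$R0 / cal$R0, 2^(1 / 6), tolerance = 1e-12)
  # monotone in Q and kappa2
  expect_gt(forster_radius(fret_calibration(1e13, Q = 0.5))$R0,
            forster_radius(fret_calibration(1e13, Q = 0.22))$R0)
  expect_gt(forster_radius(fret_calibration(1e13, kappa2 = 1))$R0, cal$R0)
  expect_error(fret_calibration(J = -1), "non-negative")
})

test_that("algebraically implied J reproduces the tabulated Forster radius", {
  # with Q = 0.22, kappa2 = 2/3, eta = 1.33, invert R0 = C (J Q eta^-4
  # kappa2)^(1/6) at the tabulated point-acceptor radius and check the
  # forward path returns it
  Q <- 0.22; k2 <- 2 / 3; eta <- 1.33; C <- 0.2108
  J_implied <- (17.6 / C)^6 / (Q * k2 * eta^-4)
  cal <- forster_radius(fret_calibration(J_implied, Q, k2, eta, C))
  expect_equal(cal$R0, 17.6, tolerance = 1e-12)
})
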