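test_that("stopping power decreases with energy and scales with density", {
  for (m in c("water", "glass", "hydroxyapatite")) {
    E <- seq(10, 250, by = 20)
    S <- stopping_power(E, m)
    expect_true(all(S > 0))
    expect_true(all(diff(S) < 0))
  }
  expect_lt(stopping_power(200, "water"), stopping_power(100, "water"))
  # exact density linearity at fixed composition
  w <- get_material("water")
  w2 <- w; w2$density <- 2 * w$density; w2$name <- "heavy-water-like"
  expect_equal(stopping_power(150, w2), 2 * stopping_power(150, w))
})

test_that("stopping power matches an independent transcription", {
  w <- get_material("water")
  for (E in c(20, 80, 150, 220)) {
    expect_equal(stopping_power(E, w),
                 oracle_bethe_bloch(E, w$density, w$Z / w$A, w$I),
                 tolerance = 1e-12)
  }
  expect_error(stopping_power(-5, "water"), "positive")
  expect_error(stopping_power(100, "adamantium"), "unknown material")
})

test_that("CSDA range integrates 1/S and behaves monotonically", {
  r100 <- csda_range(100, "water")
  r200 <- csda_range(200, "water")
  expect_gt(r200, r100)
  # density 2x at fixed composition halves the range
  w <- get_material("water")
  w2 <- w; w2$density <- 2; w2$name <- "dense"
  expect_equal(csda_range(150, w) / csda_range(150, w2), 2,
               tolerance = 1e-6)
  # fine-grid trapezoid oracle within 1%
  E <- 200; cutoff <- 1
  eg <- seq(cutoff, E, length.out = 20001)
  f <- 1 / stopping_power(eg, "water")
  oracle <- sum((f[-1] + f[-length(f)]) / 2 * diff(eg))
  expect_equal(csda_range(E, "water"), oracle, tolerance = 0.01)
  # ranges at the higher-energy band clearly exceed the low band
  expect_gt(min(csda_range(c(180, 200, 220), "water")),
            csda_range(120, "water"))
})

test_that("Rutherford cross-section reproduces the analytic ratios", {
  th <- c(0.2, 0.7, 1.2, 2.5)
  # E^-2: doubling the energy quarters the cross-section
  expect_equal(rutherford_dcs(100, 8, th) / rutherford_dcs(200, 8, th),
               rep(4, length(th)))
  # sin^4: 90 vs 30 degrees gives 1:16
  expect_equal(rutherford_dcs(150, 8, pi / 2) /
                 rutherford_dcs(150, 8, pi / 6), 1 / 16)
  # Z^2: doubling Z quadruples the cross-section
  expect_equal(rutherford_dcs(150, 16, th) / rutherford_dcs(150, 8, th),
               rep(4, length(th)))
  expect_error(rutherford_dcs(150, 8, 0), "singular")
  # the classical convention peaks where the printed one does not
  expect_gt(rutherford_dcs(150, 8, pi - 1e-3,
                           convention = "sin4theta"),
            rutherford_dcs(150, 8, pi / 2, convention = "sin4theta"))
})

test_that("hard-scatter sampling matches the integrated angular CDF", {
  theta_min <- 2 * pi / 180
  set.seed(11)
  ev <- sample_hard_scatter(1e5, theta_min = theta_min)
  expect_true(all(ev$theta >= theta_min))
  expect_true(all(ev$theta <= pi - theta_min))
  expect_true(all(ev$phi >= 0 & ev$phi < 2 * pi))
  # same seed twice gives the identical event sequence
  set.seed(11)
  ev2 <- sample_hard_scatter(1e5, theta_min = theta_min)
  expect_identical(ev, ev2)
  # brute-force CDF oracle: numeric integration of sin(theta) * dcs
  sup <- c(theta_min, pi - theta_min)
  th <- seq(sup[1], sup[2], length.out = 20001)
  f <- sin(th) * rutherford_dcs(150, 8, th)
  cdf <- cumsum(c(0, (f[-1] + f[-length(f)]) / 2 * diff(th)))
  cdf <- cdf / cdf[length(cdf)]
  emp <- stats::ecdf(ev$theta)
  expect_lt(max(abs(emp(th) - cdf)), 0.01)
  # chi-square goodness of fit, not rejected at 1%
  qs <- stats::approx(cdf, th, xout = seq(0, 1, length.out = 21),
                      ties = "ordered")$y
  qs[1] <- sup[1] - 1e-9; qs[21] <- sup[2] + 1e-9
  obs <- table(cut(ev$theta, qs))
  expect_gt(stats::chisq.test(obs, p = rep(1 / 20, 20))$p.value, 0.01)
})

test_that("classical-convention sampling covers (theta_min, pi]", {
  set.seed(3)
  ev <- sample_hard_scatter(2e4, theta_min = 5 * pi / 180,
                            convention = "sin4halftheta")
  expect_true(all(ev$theta >= 5 * pi / 180 & ev$theta <= pi))
  # backward hemisphere is strongly suppressed under sin^4(theta/2)
  expect_lt(mean(ev$theta > pi / 2), 0.05)
})

test_that("Highland sigma has the expected monotonicities", {
  s1 <- highland_sigma(200, 1, "water")
  expect_gt(highland_sigma(200, 2, "water"), s1)   # longer step
  expect_lt(highland_sigma(400, 1, "water"), s1)   # faster proton
  w <- get_material("water")
  x0 <- radiation_length(w)$cm
  expect_equal(s1, oracle_highland(200, 1, x0), tolerance = 1e-12)
  expect_error(highland_sigma(200, -1, "water"), "positive")
})

test_that("hard-scatter calibration hits its target probability", {
  C <- calibrate_hard_scatter(p_target = 0.005)
  expect_gt(C, 0)
  # reconstruct the expected number of scatters over the 20 cm path
  w <- get_material("water")
  rng <- csda_range(200, w)
  e_exit <- uniroot(function(e) rng - csda_range(e, w) - 20,
                    c(1, 200))$root
  n_exp <- integrate(function(e)
    hard_scatter_sigma(e, w, C) / stopping_power(e, w),
    e_exit, 200)$value
  expect_equal(1 - exp(-n_exp), 0.005, tolerance = 1e-6)
})
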