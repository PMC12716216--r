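# Rates, disorder-resolved efficiencies, overlap, Forster radius, inversion.

test_that("spectral overlap: zero absorber, rectangular closed form, refinement", {
  em <- data.frame(wavelength = seq(480, 520, by = 0.5),
                   value = exp(-((seq(480, 520, by = 0.5) - 500) / 8)^2))
  ab0 <- data.frame(wavelength = c(480, 520), value = 0)
  expect_equal(spectral_overlap(em, ab0), 0)

  # rectangular emission on [500, 501] with eps = 1: J ~ 500.5^4
  grid <- seq(499.9, 501.1, by = 1e-3)
  rect <- data.frame(wavelength = grid,
                     value = as.numeric(grid >= 500 & grid <= 501))
  flat <- data.frame(wavelength = c(480, 520), value = 1)
  expect_equal(spectral_overlap(rect, flat), 500.5^4, tolerance = 1e-5)

  # quadrature refinement on a smooth fixture
  mk <- function(h) {
    wl <- seq(480, 520, by = h)
    list(em = data.frame(wavelength = wl, value = exp(-((wl - 500) / 8)^2)),
         ab = data.frame(wavelength = wl, value = 1e4 * exp(-((wl - 505) / 10)^2)))
  }
  c1 <- mk(0.5); c2 <- mk(0.25)
  j1 <- spectral_overlap(c1$em, c1$ab); j2 <- spectral_overlap(c2$em, c2$ab)
  expect_lt(abs(j1 / j2 - 1), 1e-4)

  expect_error(spectral_overlap(
    data.frame(wavelength = c(300, 310), value = 1),
    data.frame(wavelength = c(400, 410), value = 1)), "disjoint")
})

test_that("Forster radius: closed form, sixth-root scaling, input validation", {
  k2 <- 2 / 3; phi <- 0.14; J <- 1e14; n <- sqrt(2)
  # hand-evaluated sixth root of 8.79e-5 * k2 * n^-4 * phi * J
  hand <- (8.79e-5 * k2 * n^-4 * phi * J)^(1 / 6)
  expect_equal(forster_radius(k2, phi, J, n), hand, tolerance = 1e-12)
  expect_equal(forster_radius(k2, phi, 2 * J, n) / forster_radius(k2, phi, J, n),
               2^(1 / 6), tolerance = 1e-12)
  expect_error(forster_radius(0, phi, J, n), "positive")
})

test_that("instantaneous rate: zero, quadratic scaling, Forster reduction", {
  p <- test_photophysics()
  expect_equal(instantaneous_rate(0, p), 0)
  expect_equal(instantaneous_rate(2e-6, p) / instantaneous_rate(1e-6, p), 4)
  # screened PDA with kappa^2 = 2/3 at R = R0 gives k = 1/tau_D
  v <- (1 / p$n_refr^2) * sqrt(2 / 3) * p$mu_d_mag * p$mu_a_mag /
    (p$r0_ang * 1.889726124626)^3
  expect_equal(instantaneous_rate(v, p) * p$tau_d_ns, 1, tolerance = 1e-12)
})

test_that("rate consistency: screened PDA through the rate formula equals (R0/R)^6 / tau", {
  p <- test_photophysics()
  R <- seq(10, 60, by = 2.5)
  v <- (1 / p$n_refr^2) * sqrt(2 / 3) * p$mu_d_mag * p$mu_a_mag /
    (R * 1.889726124626)^3
  k <- instantaneous_rate(v, p)
  k_forster <- (p$r0_ang / R)^6 / p$tau_d_ns
  expect_equal(k, k_forster, tolerance = 1e-8)
})

test_that("efficiency windows implement the intermediate averaging closed forms", {
  p <- test_photophysics()
  # constant k with k*tau = 1: every window at E = 0.5
  ed <- efficiency_distribution(rep(1 / 5, 200), p, fast_window_ns = 5,
                                stride_ps = 50)
  expect_equal(unique(ed$window_efficiencies), 0.5)
  expect_equal(ed$mean_e, 0.5)
  expect_equal(ed$n_windows, 2L)
  # two windows with <k>tau = 1 and 3: E = 0.5, 0.75, mean 0.625
  ed2 <- efficiency_distribution(c(rep(1 / 5, 100), rep(3 / 5, 100)), p,
                                 fast_window_ns = 5, stride_ps = 50)
  expect_equal(ed2$window_efficiencies, c(0.5, 0.75))
  expect_equal(ed2$mean_e, 0.625)
  expect_true(all(ed2$window_efficiencies >= 0 & ed2$window_efficiencies <= 1))
  # series shorter than one window is an error
  expect_error(efficiency_distribution(rep(1, 10), p, fast_window_ns = 5,
                                       stride_ps = 50), "shorter")
})

test_that("window limits recover the fully dynamic and fully static averages", {
  p <- test_photophysics()
  set.seed(8)
  k <- stats::rexp(400, rate = 5)           # fluctuating rates, ns^-1
  dyn <- efficiency_distribution(k, p, fast_window_ns = length(k) * 0.05,
                                 stride_ps = 50)
  expect_equal(dyn$mean_e, mean(k) * 5 / (1 + mean(k) * 5), tolerance = 1e-12)
  sta <- efficiency_distribution(k, p, fast_window_ns = 0.05, stride_ps = 50)
  expect_equal(sta$mean_e, mean(k * 5 / (1 + k * 5)), tolerance = 1e-12)
  # two-state fixture: intermediate window lies between the limits
  mid <- efficiency_distribution(k, p, fast_window_ns = 1, stride_ps = 50)
  expect_lte(mid$mean_e, max(dyn$mean_e, sta$mean_e) + 1e-12)
  expect_gte(mid$mean_e, min(dyn$mean_e, sta$mean_e) - 1e-12)
})

test_that("two-timescale fixture reproduces the analytic efficiency", {
  p <- test_photophysics()
  v0 <- coupling_for_unit_ktau(p)
  fx <- make_two_timescale_trajectory(c(v0, v0 * sqrt(3)),
                                      fast_sigma = 0.2 * v0,
                                      n_windows = 100, frames_per_window = 100,
                                      stride_ps = 50, seed = 3)
  truth <- two_timescale_truth(fx, p)
  ed <- efficiency_distribution(instantaneous_rate(fx$coupling, p), p,
                                fast_window_ns = 100 * 0.05, stride_ps = 50)
  # per-window deviations give the Monte-Carlo scale of the mean
  ktau <- trespfret:::rate_prefactor(p) * (fx$state_seq^2 + fx$fast_sigma^2)
  mc_se <- stats::sd(ed$window_efficiencies - ktau / (1 + ktau)) /
    sqrt(ed$n_windows)
  expect_lt(abs(ed$mean_e - truth), 3 * mc_se)
})

test_that("distance inversion is the exact inverse of the efficiency relation", {
  r0 <- 25
  expect_equal(invert_distance(0.5, r0), r0)           # 50% at R0
  expect_equal(invert_distance(1 / 65, r0), 2 * r0, tolerance = 1e-12)
  e <- seq(0.011, 0.989, by = 0.002)
  r <- invert_distance(e, r0)
  expect_equal(forster_efficiency(r, r0), e, tolerance = 1e-12)
  expect_true(all(diff(forster_efficiency(seq(5, 80, by = 1), r0)) < 0))
  expect_error(invert_distance(1, r0), "strictly")
  expect_error(invert_distance(0, r0), "strictly")
})

test_that("distance-bias analysis: self-consistency, orientation broadening", {
  r0 <- 25
  rmd <- seq(15, 40, length.out = 200)
  # efficiencies generated exactly by the Forster relation: MUE = 0
  bias <- distance_bias_analysis(forster_efficiency(rmd, r0), r0, rmd)
  expect_equal(bias$summary$mue, 0, tolerance = 1e-12)
  expect_equal(bias$summary$max_deviation, 0, tolerance = 1e-12)

  # fixed R, fluctuating orientation: inverted spread exceeds the true one
  p <- test_photophysics()
  set.seed(12)
  k2 <- (rowSums((m1 <- {m <- matrix(rnorm(600), 200); m / sqrt(rowSums(m^2))}) *
                   (m2 <- {m <- matrix(rnorm(600), 200); m / sqrt(rowSums(m^2))})) -
           3 * m1[, 3] * m2[, 3])^2
  R_fix <- 25
  v <- sqrt(k2) * p$mu_d_mag * p$mu_a_mag / (R_fix * 1.889726124626)^3 / p$n_refr^2
  e <- instantaneous_rate(v, p) * p$tau_d_ns
  e <- e / (1 + e)
  b2 <- distance_bias_analysis(e[e > 0 & e < 1], r0,
                               rep(R_fix, sum(e > 0 & e < 1)))
  expect_gt(stats::sd(b2$r_inverted), 1)        # broad apparent distances
  expect_equal(stats::sd(b2$r_md), 0)           # degenerate true distances

  expect_error(distance_bias_analysis(numeric(0), r0, rmd), "empty")
  expect_error(distance_bias_analysis(c(0, 1), r0, rmd), "degenerate")
})
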