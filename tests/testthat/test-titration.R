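# Titration processing: IFE, efficiencies, Hill fit, fraction-bound
# correction, site ranking.

test_that("inner-filter correction: identity, hand value, monotonicity, errors", {
  expect_equal(ife_correct(123, 0, 0), 123)
  expect_equal(ife_correct(100, 0.3, 0.1), 100 * 10^0.2, tolerance = 1e-12)
  a <- seq(0, 0.5, by = 0.1)
  expect_true(all(diff(ife_correct(100, a, 0.2)) > 0))
  expect_true(all(diff(ife_correct(100, 0.2, a)) > 0))
  expect_error(ife_correct(100, -0.01, 0), "negative absorbance")
})

test_that("efficiency from intensities covers the limiting cases", {
  expect_equal(efficiency_from_intensities(100, 100), 0)
  expect_equal(efficiency_from_intensities(50, 100), 0.5)
  expect_equal(efficiency_from_intensities(0, 100), 1)
  expect_warning(e <- efficiency_from_intensities(120, 100), "enhancement")
  expect_lt(e, 0)
  expect_error(efficiency_from_intensities(50, 0), "positive")
})

test_that("hill fit inverts noiseless log-linear titrations exactly", {
  for (kd in c(0.5, 10, 300)) for (n in c(0.4, 0.7, 1, 1.3)) {
    s <- make_titration(kd, n, 1, model = "loglinear")
    fit <- hill_fit(s)
    expect_equal(fit$kd_uM, kd, tolerance = 1e-10)
    expect_equal(fit$n_hill, n, tolerance = 1e-10)
    expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  }
  # half-saturation identity: n = 1, [L] = Kd gives a quenching ratio of 1
  s <- make_titration(50, 1, 1, model = "loglinear", concs_uM = c(10, 50, 100))
  i_cor <- ife_correct(s$intensity, s$abs_ex, s$abs_em)
  expect_equal((s$i_d - i_cor[2]) / i_cor[2], 1, tolerance = 1e-10)
})

test_that("hill fit excludes non-quenched points and needs two usable ones", {
  s <- titration_series("x", c(0, 10, 50, 100), c(100, 90, 100, 60))
  expect_warning(fit <- hill_fit(s), "excluded")
  expect_false(fit$per_conc$usable[2])
  s2 <- titration_series("x", c(0, 10, 50), c(100, 100, 60))
  expect_warning(expect_error(hill_fit(s2), "fewer than 2"))
})

test_that("median Hill exponent is recovered under 1% intensity noise", {
  n_true <- 0.7
  fits <- vapply(1:200, function(seed) {
    s <- make_titration(10, n_true, 1, model = "loglinear",
                        noise_sigma = 0.01, seed = seed)
    hill_fit(s)$n_hill
  }, numeric(1))
  expect_lt(abs(stats::median(fits) - n_true), 0.05)
})

test_that("fraction-bound correction: saturation identity, arithmetic, recovery", {
  # near-saturation (f ~ 1): correction is the identity up to 1 - f, and
  # recovers the bound-complex efficiency exactly
  s <- make_titration(1e-4, 1, 0.6, model = "hill_quench")
  fit <- hill_fit(s)
  out <- corrected_efficiency(s, fit, kd_uM = 1e-4, n_hill = 1)
  expect_equal(out$per_conc$e_corrected, out$per_conc$e_raw, tolerance = 1e-4)
  expect_equal(out$per_conc$e_corrected, rep(0.6, 3), tolerance = 1e-12)
  # E_raw = 0.3 at f = 0.6 corrects to 0.5
  s2 <- titration_series("x", c(0, 10, 30), c(1000, 700, 700))
  fit2 <- suppressWarnings(hill_fit(s2))
  fit2$per_conc$e_raw <- c(0.3, 0.3)
  out2 <- corrected_efficiency(s2, fit2, kd_uM = 10 * (1 / 0.6 - 1),
                               n_hill = 1)
  expect_equal(out2$per_conc$e_corrected[1], 0.5, tolerance = 1e-12)
  # generated with known (Kd, n, E_true): correction with those parameters
  # recovers the bound-complex efficiency exactly
  s3 <- make_titration(10, 1, 0.7, model = "hill_quench")
  out3 <- corrected_efficiency(s3, hill_fit(s3), kd_uM = 10, n_hill = 1)
  expect_equal(out3$e_final, 0.7, tolerance = 1e-6)
  expect_equal(out3$n_clipped, 0L)
})

test_that("fully chained pipeline is exact on log-linear data and robust to noise", {
  # noiseless: fit + correction recover (Kd, n, E_true) end to end
  s <- make_titration(10, 1, 1, model = "loglinear")
  fit <- corrected_efficiency(s, hill_fit(s))
  expect_equal(fit$kd_uM, 10, tolerance = 1e-6)
  expect_equal(fit$n_hill, 1, tolerance = 1e-6)
  expect_equal(fit$e_final, 1, tolerance = 1e-6)
  # 2% multiplicative noise on the physical quench model: median E within 0.05
  e_hat <- vapply(1:200, function(seed) {
    ss <- make_titration(10, 1, 0.7, model = "hill_quench",
                         noise_sigma = 0.02, seed = seed)
    corrected_efficiency(ss, hill_fit(ss))$e_final
  }, numeric(1))
  expect_lt(abs(stats::median(e_hat) - 0.7), 0.05)
})

test_that("clipping of over-corrected efficiencies is visible, not silent", {
  s <- titration_series("x", c(0, 5, 10, 20), c(1000, 500, 480, 450))
  fit <- hill_fit(s)
  # tiny fraction bound forces E_raw / f far above 1
  expect_message(out <- corrected_efficiency(s, fit, kd_uM = 5000, n_hill = 1),
                 "clipped")
  expect_gt(out$n_clipped, 0)
  expect_true(all(out$per_conc$e_corrected <= 1, na.rm = TRUE))
})

test_that("site ranking reproduces the two-site decision case", {
  rank <- compare_to_simulation(0.73, c(IIA = 1.00, IB = 0.25))
  expect_equal(rank$site, c("IIA", "IB"))
  expect_equal(rank$deviation, c(0.27, 0.48), tolerance = 1e-12)
  expect_true(all(rank$ruled_out))          # both beyond the 0.25 threshold
  # exact match is never ruled out and ties break by site name
  r2 <- compare_to_simulation(0.5, c(b = 0.6, a = 0.4, exact = 0.5))
  expect_equal(r2$site[1], "exact")
  expect_false(r2$ruled_out[1])
  expect_equal(r2$site[2:3], c("a", "b"))
  expect_error(compare_to_simulation(numeric(0), c(a = 1)), "single")
  # threshold 0 rules out everything except exact matches
  r3 <- compare_to_simulation(0.5, c(a = 0.5, b = 0.51), threshold = 0)
  expect_equal(r3$ruled_out, c(FALSE, TRUE))
})

test_that("titration construction and CSV round trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ligand_conc_uM,intensity,abs_ex,abs_em",
               "0,1000,0,0", "10,650,0.02,0.01",
               "50,400,0.1,0.05", "100,330,0.2,0.1"), path)
  s <- read_titration(path, ligand_id = "demo")
  expect_equal(s$i_d, 1000)
  expect_equal(s$conc_uM, c(10, 50, 100))
  expect_error(titration_series("x", c(0, 50, 10), c(1, 2, 3)),
               "strictly increasing")
  expect_error(titration_series("x", c(10, 50), c(100, 60)),
               "donor-only")
})
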