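test_that("fit_calibration recovers an exact line and flags degenerate input", {
  conc <- c(0.03, 0.06, 0.09, 0.12, 0.15)
  cv <- fit_calibration(conc, 7.80333 * conc + 0.0301)
  expect_equal(cv$slope, 7.80333, tolerance = 1e-12)
  expect_equal(cv$intercept, 0.0301, tolerance = 1e-12)
  expect_equal(cv$r_squared, 1)
  # two points: interpolating line
  cv2 <- fit_calibration(c(0.05, 0.10), c(0.5, 0.9))
  expect_equal(cv2$slope, 8, tolerance = 1e-12)
  expect_equal(cv2$intercept, 0.1, tolerance = 1e-12)
  expect_equal(cv2$r_squared, 1)
  expect_error(fit_calibration(rep(0.05, 3), c(0.4, 0.5, 0.6)), "degenerate")
  expect_error(fit_calibration(0.05, 0.4), "two")
})

test_that("design-symmetric perturbation moves the intercept, not the slope", {
  # hand-derived: for x symmetric about its mean, adding +eps to the first and
  # last response leaves sum((x - xbar) * dA) = 0, so the OLS slope is exact
  # and the intercept shifts by 2*eps/n
  conc <- c(0.03, 0.06, 0.09, 0.12, 0.15)
  a <- 7.80333 * conc + 0.0301
  eps <- 0.01
  a[c(1, 5)] <- a[c(1, 5)] + eps
  cv <- fit_calibration(conc, a)
  expect_equal(cv$slope, 7.80333, tolerance = 1e-10)
  expect_equal(cv$intercept, 0.0301 + 2 * eps / 5, tolerance = 1e-10)
})

test_that("invert_absorbance applies blank, slope, unit scale and dilution", {
  cv <- ref_curve()
  expect_equal(signif(invert_absorbance(0.860, cv, 100) / 1e-2, 3), 0.106)
  # hand computation: (0.377 - 0.0301)/7.80333 * 1e-4 * 1000 = 4.44554e-3
  expect_equal(invert_absorbance(0.377, cv, 1000), 4.44554e-3,
               tolerance = 1e-6)
  expect_equal(invert_absorbance(cv$intercept, cv, 10), 0)
  expect_error(invert_absorbance(0.0001, cv), "below the blank")
  expect_warning(c0 <- invert_absorbance(0.0001, cv, tolerant = TRUE), "blank")
  expect_equal(c0, 0)
})

test_that("forward and inverse curve are exact round trips", {
  cv <- ref_curve()
  for (conc in c(0, 1e-6, 1.0635e-3, 4.4455e-3, 0.015))
    for (dil in c(1, 100, 1000))
      expect_equal(invert_absorbance(forward_absorbance(conc, cv, dil), cv, dil),
                   conc, tolerance = 1e-12)
})

test_that("solution_mass_mg implements c * V * M * 1000 and matches table rows", {
  cv <- ref_curve()
  expect_equal(round(solution_mass_mg(invert_absorbance(0.860, cv, 100),
                                      0.020), 3), 10.189)
  expect_equal(round(solution_mass_mg(invert_absorbance(0.377, cv, 1000),
                                      0.020), 3), 42.589)
  expect_equal(solution_mass_mg(0, 0.020), 0)
})

test_that("loading_result reproduces capacity and composite drug content", {
  cv <- ref_curve()
  e1 <- loading_experiment(0.020, 0.377, 1000, 0.1,
                           initial_conc_molL = 0.15e-1)
  r1 <- loading_result(e1, cv)
  expect_equal(round(r1$adsorbed_mass_mg, 3), 101.114)
  expect_equal(round(r1$capacity_mg_per_g, 1), 1011.1)
  # mass balance to 1e-9 relative
  expect_equal(r1$remaining_mass_mg + r1$adsorbed_mass_mg, r1$initial_mass_mg,
               tolerance = 1e-9)

  e2 <- loading_experiment(0.040, 0.291, 1000, 0.100,
                           initial_absorbance = 1.177)
  expect_equal(round(loading_result(e2, cv)$drug_content_per_10mg, 3), 6.851)

  # supernatant equal to initial concentration: nothing adsorbed
  a0 <- forward_absorbance(0.15e-1, cv, 1000)
  e3 <- loading_experiment(0.020, a0, 1000, 0.1, initial_conc_molL = 0.15e-1)
  r3 <- loading_result(e3, cv)
  expect_equal(r3$adsorbed_mass_mg, 0, tolerance = 1e-9)
  expect_equal(r3$capacity_mg_per_g, 0, tolerance = 1e-9)

  # supernatant above initial: error, or floored-at-zero when tolerant
  e4 <- loading_experiment(0.020, a0 + 0.05, 1000, 0.1,
                           initial_conc_molL = 0.15e-1)
  expect_error(loading_result(e4, cv), "exceeds initial")
  expect_warning(r4 <- loading_result(e4, cv, tolerant = TRUE), "flooring")
  expect_equal(r4$adsorbed_mass_mg, 0)
})

test_that("capacity scales as 1/particle mass at fixed adsorbed mass", {
  cv <- ref_curve()
  mk <- function(g) loading_experiment(0.020, 0.377, 1000, g,
                                       initial_conc_molL = 0.15e-1)
  r1 <- loading_result(mk(0.1), cv)
  r2 <- loading_result(mk(0.2), cv)
  expect_equal(r1$adsorbed_mass_mg, r2$adsorbed_mass_mg)
  expect_equal(r2$capacity_mg_per_g, r1$capacity_mg_per_g / 2)
})

test_that("display rounding chains mass rows from the 3-decimal concentration", {
  cv <- ref_curve()
  e_ph3 <- loading_experiment(0.020, 1.054, 1000, 0.100,
                              initial_conc_molL = 0.15e-1)
  expect_equal(round(loading_result(e_ph3, cv,
                                    rounding = "display")$remaining_mass_mg, 3),
               125.501)
  # full-precision chaining differs past the printed digits
  expect_gt(abs(loading_result(e_ph3, cv)$remaining_mass_mg - 125.501), 0.1)
})

test_that("cumulative_release converts absorbances to percent of loaded mass", {
  cv <- ref_curve()
  loaded <- 6.851; vol <- 0.1; dil <- 10
  frac_to_a <- function(f)
    forward_absorbance(f * loaded / 1000 / r6g_molar_mass / vol, cv, dil)
  tt <- c(1, 2, 4, 8, 14)

  # blank absorbances throughout -> 0%
  s0 <- release_series(tt, rep(cv$intercept, 5), vol, loaded, dil)
  expect_equal(cumulative_release(s0, cv)$table$percent, rep(0, 5))

  # series encoding exactly half the loaded mass -> 50.0%
  s_half <- release_series(tt, frac_to_a(rep(0.5, 5)), vol, loaded, dil)
  expect_equal(cumulative_release(s_half, cv)$final_percent, 50,
               tolerance = 1e-9)

  # forward/inverse round trip of a 93%-release profile
  f <- 0.93 * (1 - exp(-0.8 * tt))
  s <- release_series(tt, frac_to_a(f), vol, loaded, dil)
  out <- cumulative_release(s, cv)
  expect_equal(out$table$percent, 100 * f, tolerance = 1e-9)
  expect_equal(round(out$final_percent, 1), 93.0)
  expect_true(out$monotone)

  # monotone truth stays monotone through the noiseless round trip
  expect_true(all(diff(out$table$percent) >= 0))

  # overshoot warns, clips only on request
  s_over <- release_series(tt, frac_to_a(c(0.5, 0.8, 0.9, 1.0, 1.06)),
                           vol, loaded, dil)
  expect_warning(o1 <- cumulative_release(s_over, cv), "100")
  expect_gt(max(o1$table$percent), 100)
  expect_warning(o2 <- cumulative_release(s_over, cv, clip = TRUE), "100")
  expect_lte(max(o2$table$percent), 100)
})

test_that("coating_fraction follows organic / residue arithmetic", {
  expect_equal(signif(coating_fraction(c(25.2, 6.2, 5.5), 1), 4), 39.94)
  expect_equal(signif(coating_fraction(c(25.2, 6.2, 5.5), 1), 2), 40)
  expect_equal(coating_fraction(c(0, 6.2), 1), 0)
  x <- 30
  expect_equal(coating_fraction(x, 1), x / (100 - x) * 100)
  expect_error(coating_fraction(c(60, 41), 1), "100")
  expect_error(coating_fraction(c(10, -1), 1), "non-negative")
  expect_error(coating_fraction(c(10, 5), 3), "out of range")
})
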