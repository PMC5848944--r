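test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- synthetic_config(seed = 11)
  expect_identical(gen_calibration(cfg), gen_calibration(cfg))
  expect_identical(gen_loading(cfg, 5), gen_loading(cfg, 5))
  expect_identical(gen_release(cfg), gen_release(cfg))
  # a different seed changes the noise
  cfg2 <- synthetic_config(seed = 12)
  expect_false(identical(gen_calibration(cfg)$points$absorbance,
                         gen_calibration(cfg2)$points$absorbance))
  # generators do not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(gen_calibration(cfg)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("noiseless calibration generation lies on the true line exactly", {
  cfg <- synthetic_config(seed = 1, noise_sd_absorbance = 0)
  g <- gen_calibration(cfg)
  expect_equal(g$points$absorbance,
               7.80333 * g$points$concentration + 0.0301, tolerance = 1e-14)
  fit <- fit_calibration(g$points$concentration, g$points$absorbance)
  expect_equal(fit$slope, 7.80333, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.0301, tolerance = 1e-12)
})

test_that("noisy calibration recovery sharpens with sample size", {
  base <- function(n) synthetic_config(seed = 21, noise_sd_absorbance = 0.005,
                                       n_calibration_points = n)
  fit_of <- function(cfg) {
    g <- gen_calibration(cfg)
    fit_calibration(g$points$concentration, g$points$absorbance)
  }
  big <- fit_of(base(500))
  expect_rel(big$slope, 7.80333, 0.005)   # within 0.5% at n = 500
  small <- fit_of(base(5))
  expect_lt(abs(big$slope - 7.80333), abs(small$slope - 7.80333) + 0.05)
})

test_that("noiseless loading generation recovers the configured capacity", {
  cfg <- synthetic_config(seed = 3, noise_sd_absorbance = 0)
  g <- gen_loading(cfg)
  row <- g$experiments[1, ]
  exp_obj <- loading_experiment(row$volume_l, row$A_sup, row$dilution,
                                row$particle_g,
                                initial_conc_molL = row$c0_molL)
  r <- loading_result(exp_obj, ref_curve())
  expect_equal(r$capacity_mg_per_g, g$truth$capacity_mg_per_g,
               tolerance = 1e-9)
  # the default configuration mirrors the highest-concentration run
  expect_equal(round(r$capacity_mg_per_g, 1), 1011.1, tolerance = 0.11)

  # zero adsorbed fraction -> zero capacity
  cfg0 <- synthetic_config(seed = 3, noise_sd_absorbance = 0,
                           loading_truth = list(initial_conc_molL = 0.15e-1,
                                                adsorbed_fraction = 0,
                                                volume_l = 0.020,
                                                particle_g = 0.1,
                                                dilution = 1000))
  g0 <- gen_loading(cfg0)
  r0 <- loading_result(loading_experiment(0.020, g0$experiments$A_sup[1], 1000,
                                          0.1, initial_conc_molL = 0.15e-1),
                       ref_curve(), tolerant = TRUE)
  expect_equal(r0$adsorbed_mass_mg, 0, tolerance = 1e-9)
})

test_that("noisy loading replicates average to the true capacity", {
  cfg <- synthetic_config(seed = 31, noise_sd_absorbance = 0.005)
  g <- gen_loading(cfg, n_replicates = 200)
  caps <- vapply(seq_len(200), function(i) {
    row <- g$experiments[i, ]
    loading_result(loading_experiment(row$volume_l, row$A_sup, row$dilution,
                                      row$particle_g,
                                      initial_conc_molL = row$c0_molL),
                   ref_curve(), tolerant = TRUE)$capacity_mg_per_g
  }, numeric(1))
  expect_rel(mean(caps), g$truth$capacity_mg_per_g, 0.01)
})

test_that("noiseless release series round-trips both kinetic models", {
  # first-order truth with plateau 0.93: final cumulative release is 93.0%
  cfg_fo <- synthetic_config(seed = 5, noise_sd_absorbance = 0)
  g <- gen_release(cfg_fo)
  out <- cumulative_release(g$series, ref_curve())
  expect_equal(out$table$percent, 100 * g$truth$fractions, tolerance = 1e-9)
  expect_equal(round(out$final_percent, 1), 93.0, tolerance = 0.06)
  fit <- fit_first_order(release_curve(g$series$times_h,
                                       out$table$percent / 100,
                                       time_unit = "h"))
  expect_rel(fit$rate, 0.8, 1e-6)
  expect_rel(fit$plateau, 0.93, 1e-6)

  # Fickian truth: diffusivity recovered to machine precision via the
  # early-time law on early samples
  slab <- fickian_slab(5e-14, 1e-4)
  cfg_fk <- synthetic_config(seed = 5, noise_sd_absorbance = 0,
                             release_truth = list(model = slab,
                                                  times_h = seq(1 / 3, 14, by = 1 / 3),
                                                  release_volume_l = 0.100,
                                                  loaded_mg = 6.851,
                                                  dilution = 10))
  gf <- gen_release(cfg_fk)
  outf <- cumulative_release(gf$series, ref_curve())
  cvf <- release_curve(gf$series$times_h, outf$table$percent / 100,
                       time_unit = "h")
  fitD <- fit_diffusivity(cvf, thickness = 1e-4, cutoff = 0.4)
  expect_rel(fitD$diffusivity, 5e-14, 0.02)  # solver-vs-law discretisation only
})

test_that("noisy release series still recovers the diffusivity within 10%", {
  slab <- fickian_slab(5e-14, 1e-4)
  cfg <- synthetic_config(seed = 41, noise_sd_absorbance = 0.01,
                          release_truth = list(model = slab,
                                               times_h = seq(1 / 3, 10, length.out = 30),
                                               release_volume_l = 0.100,
                                               loaded_mg = 6.851,
                                               dilution = 10))
  g <- gen_release(cfg)
  out <- suppressWarnings(cumulative_release(g$series, ref_curve(),
                                             tolerant = TRUE))
  cv <- release_curve(g$series$times_h, pmin(out$table$percent / 100, 1),
                      time_unit = "h")
  fit <- fit_diffusivity(cv, thickness = 1e-4)
  expect_rel(fit$diffusivity, 5e-14, 0.10)
})

test_that("synthetic_config validates its fields", {
  expect_error(synthetic_config(noise_sd_absorbance = -1), "non-negative")
  expect_error(synthetic_config(loading_truth = list(initial_conc_molL = 1,
                                                     adsorbed_fraction = 1.2,
                                                     volume_l = 1,
                                                     particle_g = 1,
                                                     dilution = 1)),
               "adsorbed_fraction")
  expect_error(synthetic_config(release_truth = list(model = "nope",
                                                     times_h = 1:3,
                                                     release_volume_l = 1,
                                                     loaded_mg = 1,
                                                     dilution = 1)),
               "model")
})
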