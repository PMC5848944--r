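# Seeded synthetic-data generators. Noise enters on absorbance only (the
# measured quantity), i.i.d. Gaussian and homoscedastic; sigma defaults to
# 0.005 absorbance units, the residual scale implied by a calibration
# R^2 of ~0.9997 over the standard-solution range.

#' Default release sampling schedule
#'
#' Sampling every 20 min for the first 6 h, widening to 40 min until 10 h,
#' 1 h until 12 h and a final 2 h step to 14 h — the cadence of a typical
#' cumulative-release experiment read on a benchtop UV-Vis instrument.
#'
#' @return Times in hours (27 points).
#' @export
release_sampling_times <- function() {
  c(seq(1 / 3, 6, by = 1 / 3), seq(6 + 2 / 3, 10, by = 2 / 3), 11, 12, 14)
}

#' Configuration for the synthetic-data generators
#'
#' Bundles the ground truth for all three generators. Defaults mirror the
#' reference study conditions: the calibration line
#' \eqn{A = 7.80333 c + 0.0301} on \eqn{c} in \eqn{10^{-4}} mol/L units over
#' 0.03-0.15; a loading run of 20 mL at 0.015 mol/L on 0.1 g of particles
#' adsorbing 70.36\% of the drug (measured at 1000-fold dilution); and a
#' release run of 6.851 mg loaded drug into 100 mL, measured at 10-fold
#' dilution, following a first-order law (rate 0.8/h, plateau 0.93) on the
#' default sampling schedule.
#'
#' @param seed Integer seed; every generator is bit-reproducible given it.
#' @param curve_truth List `slope`, `intercept`, `conc_unit_scale`.
#' @param noise_sd_absorbance Gaussian noise SD on absorbance, >= 0.
#' @param n_calibration_points Number of calibration standards, >= 2.
#' @param calibration_range Concentration range (curve units) of standards.
#' @param loading_truth List `initial_conc_molL`, `adsorbed_fraction` (in
#'   `[0, 1]`), `volume_l`, `particle_g`, `dilution`.
#' @param release_truth List `model` (a [fickian_slab()] or
#'   [first_order_model()]), `times_h`, `release_volume_l`, `loaded_mg`,
#'   `dilution`.
#' @param drug_molar_mass Drug molar mass, g/mol.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1L,
    curve_truth = list(slope = 7.80333, intercept = 0.0301,
                       conc_unit_scale = 1e-4),
    noise_sd_absorbance = 0.005,
    n_calibration_points = 5L,
    calibration_range = c(0.03, 0.15),
    loading_truth = list(initial_conc_molL = 0.15e-1,
                         adsorbed_fraction = 0.7036,
                         volume_l = 0.020, particle_g = 0.1, dilution = 1000),
    release_truth = list(model = first_order_model(0.8, 0.93),
                         times_h = release_sampling_times(),
                         release_volume_l = 0.100, loaded_mg = 6.851,
                         dilution = 10),
    drug_molar_mass = r6g_molar_mass) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("`seed` must be an integer")
  if (!is.finite(noise_sd_absorbance) || noise_sd_absorbance < 0)
    stop("`noise_sd_absorbance` must be non-negative")
  if (n_calibration_points < 1) stop("`n_calibration_points` must be >= 1")
  if (loading_truth$adsorbed_fraction < 0 || loading_truth$adsorbed_fraction > 1)
    stop("`adsorbed_fraction` must lie in [0, 1]")
  if (!inherits(release_truth$model, "fickian_slab") &&
      !inherits(release_truth$model, "first_order_model"))
    stop("release model must be a fickian_slab or first_order_model")
  structure(list(seed = seed, curve_truth = curve_truth,
                 noise_sd_absorbance = noise_sd_absorbance,
                 n_calibration_points = as.integer(n_calibration_points),
                 calibration_range = calibration_range,
                 loading_truth = loading_truth,
                 release_truth = release_truth,
                 drug_molar_mass = drug_molar_mass),
            class = "synthetic_config")
}

truth_curve <- function(config) {
  calibration_curve(config$curve_truth$slope, config$curve_truth$intercept,
                    config$curve_truth$conc_unit_scale)
}

# evaluate the generators under a deterministic RNG stream without
# disturbing the caller's RNG state
with_config_seed <- function(config, offset, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(config$seed + offset)
  force(expr)
}

#' Generate synthetic calibration standards
#'
#' Evenly spaced concentrations over the configured range with absorbances
#' from the true line plus seeded Gaussian noise.
#'
#' @param config A [synthetic_config()].
#' @return A list: `points` (data frame `concentration` in curve units,
#'   `absorbance`) and `truth` (the generating [calibration_curve()]).
#' @export
gen_calibration <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_calibration_points
  conc <- if (n == 1) mean(config$calibration_range) else
    seq(config$calibration_range[1], config$calibration_range[2],
        length.out = n)
  truth <- truth_curve(config)
  a <- truth$slope * conc + truth$intercept +
    with_config_seed(config, 101L,
                     stats::rnorm(n, 0, config$noise_sd_absorbance))
  list(points = data.frame(concentration = conc, absorbance = a),
       truth = truth)
}

#' Generate synthetic loading-experiment rows
#'
#' The supernatant absorbance is computed by the forward calibration curve
#' from the un-adsorbed concentration
#' \eqn{(1 - f_{ads})\, c_0} after the configured dilution, plus seeded
#' noise. The true capacity implied by the configuration is recorded.
#'
#' @param config A [synthetic_config()].
#' @param n_replicates Number of replicate rows.
#' @return A list: `experiments` (data frame in the loading-file layout:
#'   `label`, `volume_l`, `c0_molL`, `A_sup`, `dilution`, `particle_g`) and
#'   `truth` (list `capacity_mg_per_g`, `adsorbed_mg`, `remaining_conc_molL`).
#' @export
gen_loading <- function(config, n_replicates = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  lt <- config$loading_truth
  truth <- truth_curve(config)
  c_rem <- (1 - lt$adsorbed_fraction) * lt$initial_conc_molL
  a_true <- forward_absorbance(c_rem, truth, lt$dilution)
  a <- a_true + with_config_seed(config, 202L,
                                 stats::rnorm(n_replicates, 0,
                                              config$noise_sd_absorbance))
  adsorbed_mg <- solution_mass_mg(lt$adsorbed_fraction * lt$initial_conc_molL,
                                  lt$volume_l, config$drug_molar_mass)
  list(experiments = data.frame(
         label = sprintf("synthetic-%02d", seq_len(n_replicates)),
         volume_l = lt$volume_l, c0_molL = lt$initial_conc_molL,
         A_sup = pmax(a, 0), dilution = lt$dilution,
         particle_g = lt$particle_g, stringsAsFactors = FALSE),
       truth = list(capacity_mg_per_g = adsorbed_mg / lt$particle_g,
                    adsorbed_mg = adsorbed_mg,
                    remaining_conc_molL = c_rem))
}

#' Generate a synthetic release absorbance series
#'
#' True released fractions come from the configured kinetic model (Fickian
#' slab, solved with [solve_fick_slab()]; or first-order, closed form); the
#' solution-phase drug mass is mapped to supernatant absorbance through the
#' forward calibration curve and dilution, plus seeded Gaussian noise.
#'
#' @param config A [synthetic_config()].
#' @param grid_points Spatial resolution for the Fickian solver.
#' @return A list: `series` (a [release_series()]), `data` (data frame
#'   `time_h`, `absorbance`), `truth` (list `model`, `fractions`,
#'   `final_percent`).
#' @export
gen_release <- function(config, grid_points = 400L) {
  stopifnot(inherits(config, "synthetic_config"))
  rt <- config$release_truth
  times_h <- rt$times_h
  fractions <- if (inherits(rt$model, "fickian_slab")) {
    solve_fick_slab(rt$model, times_h, grid_points = grid_points,
                    time_unit = "h")$fractions
  } else {
    rt$model$plateau_fraction * (1 - exp(-rt$model$rate * times_h))
  }
  truth <- truth_curve(config)
  released_mg <- fractions * rt$loaded_mg
  conc <- released_mg / 1000 / config$drug_molar_mass / rt$release_volume_l
  a_true <- forward_absorbance(conc, truth, rt$dilution)
  a <- a_true + with_config_seed(config, 303L,
                                 stats::rnorm(length(times_h), 0,
                                              config$noise_sd_absorbance))
  a <- pmax(a, 0)
  list(series = release_series(times_h, a, rt$release_volume_l, rt$loaded_mg,
                               rt$dilution, config$drug_molar_mass),
       data = data.frame(time_h = times_h, absorbance = a),
       truth = list(model = rt$model, fractions = fractions,
                    final_percent = 100 * fractions[length(fractions)]))
}
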