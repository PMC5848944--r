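# Beer-Lambert calibration and the loading / release mass arithmetic.
# Concentrations cross module boundaries in SI mol/L; the curve's
# conc_unit_scale records what one "concentration unit" of its fitted line
# means in mol/L (e.g. 1e-4 when the line was fitted on c in 1e-4 mol/L).

#' Linear absorbance-concentration calibration curve
#'
#' \eqn{A = slope \cdot c + intercept} with `c` in curve concentration units;
#' `conc_unit_scale` is the mol/L represented by one unit.
#'
#' @param slope Absorbance per concentration unit; non-zero.
#' @param intercept Absorbance at zero concentration (the blank).
#' @param conc_unit_scale mol/L per concentration unit (default `1e-4`).
#' @param r_squared Optional coefficient of determination in `[0, 1]`.
#' @param wavelength Optional wavelength metadata, nm.
#' @return An object of class `calibration_curve`.
#' @export
calibration_curve <- function(slope, intercept, conc_unit_scale = 1e-4,
                              r_squared = NULL, wavelength = NULL) {
  slope <- as.numeric(slope); intercept <- as.numeric(intercept)
  if (!is.finite(slope) || slope == 0)
    stop("`slope` must be finite and non-zero for an invertible curve")
  if (!is.finite(intercept)) stop("`intercept` must be finite")
  if (!is.finite(conc_unit_scale) || conc_unit_scale <= 0)
    stop("`conc_unit_scale` must be a positive mol/L value")
  if (!is.null(r_squared)) {
    r_squared <- as.numeric(r_squared)
    if (!is.finite(r_squared) || r_squared < 0 || r_squared > 1)
      stop("`r_squared` must lie in [0, 1]")
  }
  structure(list(slope = slope, intercept = intercept,
                 conc_unit_scale = conc_unit_scale,
                 r_squared = r_squared, wavelength = wavelength),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration: A = %.6g c + %.6g  (c in %g mol/L units)\n",
              x$slope, x$intercept, x$conc_unit_scale))
  if (!is.null(x$r_squared)) cat(sprintf("  R^2 = %.5f\n", x$r_squared))
  if (!is.null(x$wavelength)) cat(sprintf("  wavelength = %g nm\n", x$wavelength))
  invisible(x)
}

#' Fit a calibration curve by ordinary least squares
#'
#' Fits \eqn{A = slope \cdot c + intercept} to standard-solution points and
#' reports \eqn{R^2 = 1 - SS_{res}/SS_{tot}}.
#'
#' @param concentration Concentrations in curve units (at least two distinct
#'   values).
#' @param absorbance Matching absorbances.
#' @param conc_unit_scale mol/L per concentration unit.
#' @param wavelength Optional wavelength metadata, nm.
#' @return A [calibration_curve()].
#' @examples
#' conc <- c(0.03, 0.06, 0.09, 0.12, 0.15)     # units of 1e-4 mol/L
#' fit_calibration(conc, 7.80333 * conc + 0.0301)
#' @export
fit_calibration <- function(concentration, absorbance, conc_unit_scale = 1e-4,
                            wavelength = NULL) {
  concentration <- as.numeric(concentration)
  absorbance <- as.numeric(absorbance)
  if (length(concentration) != length(absorbance))
    stop("`concentration` and `absorbance` must have the same length")
  if (length(concentration) < 2)
    stop("at least two calibration points are required")
  if (anyNA(concentration) || anyNA(absorbance))
    stop("calibration points must not contain missing values")
  if (length(unique(concentration)) < 2)
    stop("degenerate fit: all concentrations identical")
  fit <- stats::lm(absorbance ~ concentration)
  co <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((absorbance - mean(absorbance))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  calibration_curve(slope = unname(co["concentration"]),
                    intercept = unname(co["(Intercept)"]),
                    conc_unit_scale = conc_unit_scale,
                    r_squared = min(max(r2, 0), 1),
                    wavelength = wavelength)
}

#' Convert absorbance to molar concentration
#'
#' Inverts the calibration line and undoes the measurement dilution:
#' \eqn{c = (A - intercept)/slope \times scale \times dilution} in mol/L.
#'
#' @param absorbance Measured absorbance(s), non-negative.
#' @param curve A [calibration_curve()].
#' @param dilution_factor Fold-dilution applied before measurement (>= 1).
#' @param tolerant If `TRUE`, absorbances marginally below the blank are
#'   floored to zero concentration with a warning instead of erroring.
#' @return Concentration(s), mol/L.
#' @examples
#' curve <- calibration_curve(7.80333, 0.0301, 1e-4)
#' invert_absorbance(0.860, curve, dilution_factor = 100)
#' @export
invert_absorbance <- function(absorbance, curve, dilution_factor = 1,
                              tolerant = FALSE) {
  stopifnot(inherits(curve, "calibration_curve"))
  absorbance <- as.numeric(absorbance)
  if (any(!is.finite(absorbance)) || any(absorbance < 0))
    stop("`absorbance` must be finite and non-negative")
  if (!is.finite(dilution_factor) || dilution_factor < 1)
    stop("`dilution_factor` must be >= 1")
  conc <- (absorbance - curve$intercept) / curve$slope *
    curve$conc_unit_scale * dilution_factor
  neg <- conc < 0
  if (any(neg)) {
    if (!tolerant)
      stop("absorbance below the blank: inverted concentration is negative")
    warning("absorbance below the blank; flooring concentration at zero")
    conc[neg] <- 0
  }
  conc
}

#' Predict absorbance from molar concentration (forward curve)
#'
#' The forward Beer-Lambert map, the exact inverse of [invert_absorbance()]:
#' \eqn{A = slope \cdot c/(scale \cdot dilution) + intercept}. Used by the
#' synthetic-data generators and round-trip checks.
#'
#' @inheritParams invert_absorbance
#' @param conc_molL Concentration(s) in mol/L, before dilution.
#' @return Absorbance(s).
#' @export
forward_absorbance <- function(conc_molL, curve, dilution_factor = 1) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.finite(dilution_factor) || dilution_factor < 1)
    stop("`dilution_factor` must be >= 1")
  curve$slope * conc_molL / (curve$conc_unit_scale * dilution_factor) +
    curve$intercept
}

#' Drug mass in solution
#'
#' \eqn{m\,[mg] = c \times V \times M \times 1000} for concentration `c`
#' (mol/L), volume `V` (L) and molar mass `M` (g/mol).
#'
#' @param conc_molL Concentration, mol/L.
#' @param volume_l Solution volume, L.
#' @param molar_mass Drug molar mass, g/mol; defaults to [r6g_molar_mass].
#' @return Mass in mg.
#' @export
solution_mass_mg <- function(conc_molL, volume_l, molar_mass = r6g_molar_mass) {
  if (any(conc_molL < 0) || volume_l < 0 || molar_mass < 0)
    stop("concentration, volume and molar mass must be non-negative")
  conc_molL * volume_l * molar_mass * 1000
}

#' One adsorption (drug-loading) run
#'
#' Inputs for the supernatant-depletion loading calculation. The initial
#' concentration may be given directly (`initial_conc_molL`, nominal) or as a
#' measured pre-adsorption absorbance (`initial_absorbance`, inverted through
#' the same curve and dilution as the supernatant). Exactly one of the two
#' must be supplied: the initial amount is always an explicit input, never a
#' hidden correction.
#'
#' @param solution_volume_l Solution volume, L.
#' @param supernatant_absorbance Post-adsorption supernatant absorbance.
#' @param dilution_factor Fold-dilution applied before measurement (>= 1).
#' @param particle_mass_g Carrier particle mass, g.
#' @param initial_conc_molL Initial drug concentration, mol/L (optional).
#' @param initial_absorbance Pre-adsorption absorbance (optional).
#' @param drug_molar_mass Drug molar mass, g/mol.
#' @param label Optional run label.
#' @return An object of class `loading_experiment`.
#' @export
loading_experiment <- function(solution_volume_l, supernatant_absorbance,
                               dilution_factor, particle_mass_g,
                               initial_conc_molL = NULL,
                               initial_absorbance = NULL,
                               drug_molar_mass = r6g_molar_mass,
                               label = "loading") {
  if (is.null(initial_conc_molL) == is.null(initial_absorbance))
    stop("supply exactly one of `initial_conc_molL` or `initial_absorbance`")
  for (v in c(solution_volume_l, dilution_factor, particle_mass_g, drug_molar_mass))
    if (!is.finite(v) || v <= 0)
      stop("volumes, dilution factor, particle mass and molar mass must be positive")
  if (dilution_factor < 1) stop("`dilution_factor` must be >= 1")
  if (!is.finite(supernatant_absorbance) || supernatant_absorbance < 0)
    stop("`supernatant_absorbance` must be non-negative")
  if (!is.null(initial_conc_molL) &&
      (!is.finite(initial_conc_molL) || initial_conc_molL <= 0))
    stop("`initial_conc_molL` must be positive")
  if (!is.null(initial_absorbance) &&
      (!is.finite(initial_absorbance) || initial_absorbance < 0))
    stop("`initial_absorbance` must be non-negative")
  structure(list(label = label,
                 solution_volume_l = solution_volume_l,
                 supernatant_absorbance = supernatant_absorbance,
                 dilution_factor = dilution_factor,
                 particle_mass_g = particle_mass_g,
                 initial_conc_molL = initial_conc_molL,
                 initial_absorbance = initial_absorbance,
                 drug_molar_mass = drug_molar_mass),
            class = "loading_experiment")
}

#' Loading masses and capacity from a supernatant measurement
#'
#' Chains [invert_absorbance()] and [solution_mass_mg()]:
#' remaining mass from the supernatant absorbance, adsorbed mass as
#' initial minus remaining, capacity as adsorbed mass per gram of particles,
#' and the drug content of 10 mg of drug-loaded composite,
#' \eqn{adsorbed/(adsorbed + particles\,[mg]) \times 10}.
#'
#' `rounding = "display"` rounds the inverted concentration to 3 decimal
#' places in display units (`conc_unit_scale * dilution_factor` mol/L) before
#' the mass step, mimicking report tables that chain their mass rows from the
#' displayed concentration; all analysis should use the default `"full"`.
#'
#' @param exp A [loading_experiment()].
#' @param curve A [calibration_curve()].
#' @param rounding `"full"` (default) or `"display"`.
#' @param tolerant If `TRUE`, a supernatant slightly above the initial
#'   concentration yields zero adsorbed mass with a warning instead of an
#'   error.
#' @return An object of class `loading_result` with fields
#'   `remaining_conc_molL`, `initial_mass_mg`, `remaining_mass_mg`,
#'   `adsorbed_mass_mg`, `capacity_mg_per_g`, `drug_content_per_10mg`.
#' @examples
#' curve <- calibration_curve(7.80333, 0.0301, 1e-4)
#' exp <- loading_experiment(0.020, 0.377, 1000, 0.1,
#'                           initial_conc_molL = 0.15e-1)
#' loading_result(exp, curve)
#' @export
loading_result <- function(exp, curve, rounding = c("full", "display"),
                           tolerant = FALSE) {
  stopifnot(inherits(exp, "loading_experiment"),
            inherits(curve, "calibration_curve"))
  rounding <- match.arg(rounding)
  conc <- invert_absorbance(exp$supernatant_absorbance, curve,
                            exp$dilution_factor, tolerant = tolerant)
  if (rounding == "display") {
    display_unit <- curve$conc_unit_scale * exp$dilution_factor
    conc <- round(conc / display_unit, 3) * display_unit
  }
  c0 <- if (!is.null(exp$initial_conc_molL)) exp$initial_conc_molL else
    invert_absorbance(exp$initial_absorbance, curve, exp$dilution_factor,
                      tolerant = tolerant)
  remaining <- solution_mass_mg(conc, exp$solution_volume_l, exp$drug_molar_mass)
  initial <- solution_mass_mg(c0, exp$solution_volume_l, exp$drug_molar_mass)
  adsorbed <- initial - remaining
  if (adsorbed < 0) {
    if (!tolerant)
      stop(sprintf(paste0("supernatant exceeds initial concentration in '%s' ",
                          "(remaining %.4g mg > initial %.4g mg)"),
                   exp$label, remaining, initial))
    warning("supernatant exceeds initial concentration; flooring adsorbed mass at zero")
    adsorbed <- 0
  }
  particle_mg <- exp$particle_mass_g * 1000
  structure(list(label = exp$label,
                 remaining_conc_molL = conc,
                 initial_mass_mg = initial,
                 remaining_mass_mg = remaining,
                 adsorbed_mass_mg = adsorbed,
                 capacity_mg_per_g = adsorbed / exp$particle_mass_g,
                 drug_content_per_10mg = adsorbed / (adsorbed + particle_mg) * 10),
            class = "loading_result")
}

#' @export
print.loading_result <- function(x, ...) {
  cat("Loading result:", x$label, "\n")
  cat(sprintf("  remaining concentration : %.4g mol/L\n", x$remaining_conc_molL))
  cat(sprintf("  initial / remaining mass: %.3f / %.3f mg\n",
              x$initial_mass_mg, x$remaining_mass_mg))
  cat(sprintf("  adsorbed mass           : %.3f mg\n", x$adsorbed_mass_mg))
  cat(sprintf("  capacity                : %.1f mg/g\n", x$capacity_mg_per_g))
  cat(sprintf("  drug per 10 mg composite: %.3f mg\n", x$drug_content_per_10mg))
  invisible(x)
}

#' Release time series of supernatant absorbances
#'
#' Raw inputs for [cumulative_release()]: sampling times (h, strictly
#' increasing), supernatant absorbances, the constant release volume, the
#' drug mass loaded on the dispersed carrier, and the measurement dilution.
#'
#' @param times_h Sampling times, h, strictly increasing and non-negative.
#' @param absorbances Supernatant absorbances, same length, non-negative.
#' @param release_volume_l Release-medium volume, L (assumed constant).
#' @param loaded_mg Loaded drug mass, mg (> 0).
#' @param dilution_factor Fold-dilution before measurement (>= 1).
#' @param drug_molar_mass Drug molar mass, g/mol.
#' @return An object of class `release_series`.
#' @export
release_series <- function(times_h, absorbances, release_volume_l, loaded_mg,
                           dilution_factor = 1,
                           drug_molar_mass = r6g_molar_mass) {
  times_h <- as.numeric(times_h); absorbances <- as.numeric(absorbances)
  if (length(times_h) != length(absorbances) || length(times_h) == 0)
    stop("`times_h` and `absorbances` must be non-empty and equal length")
  if (any(!is.finite(times_h)) || any(times_h < 0) || any(diff(times_h) <= 0))
    stop("`times_h` must be non-negative and strictly increasing")
  if (any(!is.finite(absorbances)) || any(absorbances < 0))
    stop("`absorbances` must be non-negative")
  if (!is.finite(release_volume_l) || release_volume_l <= 0)
    stop("`release_volume_l` must be positive")
  if (!is.finite(loaded_mg) || loaded_mg <= 0)
    stop("`loaded_mg` must be positive")
  if (!is.finite(dilution_factor) || dilution_factor < 1)
    stop("`dilution_factor` must be >= 1")
  structure(list(times_h = times_h, absorbances = absorbances,
                 release_volume_l = release_volume_l, loaded_mg = loaded_mg,
                 dilution_factor = dilution_factor,
                 drug_molar_mass = drug_molar_mass),
            class = "release_series")
}

#' Cumulative release percentages from supernatant absorbances
#'
#' At each sampling time the supernatant absorbance is inverted to a
#' concentration, converted to the drug mass present in the release volume,
#' and expressed as a percentage of the loaded mass. Percentages above
#' 100 (+`tolerance`) raise a warning (measurement noise) and are clipped
#' only when `clip = TRUE`; a non-monotone derived series is flagged, not
#' altered.
#'
#' @param series A [release_series()].
#' @param curve A [calibration_curve()].
#' @param tolerance Allowed overshoot above 100 before warning, percent.
#' @param clip If `TRUE`, clip percentages into `[0, 100]` after warning.
#' @param tolerant Passed to [invert_absorbance()] for below-blank readings.
#' @return An object of class `release_quant`: a list with `table`
#'   (data frame `time_h`, `absorbance`, `conc_molL`, `released_mg`,
#'   `percent`), `final_percent` and `monotone`.
#' @export
cumulative_release <- function(series, curve, tolerance = 2, clip = FALSE,
                               tolerant = FALSE) {
  stopifnot(inherits(series, "release_series"),
            inherits(curve, "calibration_curve"))
  conc <- invert_absorbance(series$absorbances, curve, series$dilution_factor,
                            tolerant = tolerant)
  released <- solution_mass_mg(conc, series$release_volume_l,
                               series$drug_molar_mass)
  percent <- released / series$loaded_mg * 100
  if (any(percent < 0))
    stop("negative release percentage computed")  # unreachable past inversion
  if (any(percent > 100 + tolerance)) {
    warning(sprintf("release exceeds 100%% (max %.1f%%); measurement noise?",
                    max(percent)))
    if (clip) percent <- pmin(percent, 100)
  }
  monotone <- all(diff(percent) >= -1e-9)
  if (!monotone)
    warning("derived cumulative release is not monotone non-decreasing")
  structure(list(table = data.frame(time_h = series$times_h,
                                    absorbance = series$absorbances,
                                    conc_molL = conc,
                                    released_mg = released,
                                    percent = percent),
                 final_percent = percent[length(percent)],
                 monotone = monotone),
            class = "release_quant")
}

#' @export
print.release_quant <- function(x, ...) {
  cat(sprintf("Cumulative release: %d samples, final %.1f%%%s\n",
              nrow(x$table), x$final_percent,
              if (x$monotone) "" else " (non-monotone)"))
  print(utils::head(x$table, 10))
  if (nrow(x$table) > 10) cat("  ...\n")
  invisible(x)
}

#' Polymer coating fraction from thermogravimetric step losses
#'
#' For TGA step losses (percent of initial sample weight), the coating
#' fraction is the organic (polymer) step relative to the inorganic residue:
#' \eqn{loss_{organic} / (100 - \Sigma losses) \times 100}, in w/w percent
#' of the core.
#'
#' @param step_losses Numeric vector of step weight losses, percent,
#'   all non-negative and summing to less than 100.
#' @param organic_step_index Which entry is the polymer step.
#' @return Coating fraction, w/w percent.
#' @examples
#' coating_fraction(c(25.2, 6.2, 5.5), 1)   # ~ 40% polymer on the core
#' @export
coating_fraction <- function(step_losses, organic_step_index = 1) {
  step_losses <- as.numeric(step_losses)
  if (any(!is.finite(step_losses)) || any(step_losses < 0))
    stop("step losses must be finite and non-negative")
  if (organic_step_index < 1 || organic_step_index > length(step_losses))
    stop("`organic_step_index` out of range")
  total <- sum(step_losses)
  if (total >= 100)
    stop("step losses sum to ", total, "% (>= 100%): no residue remains")
  step_losses[organic_step_index] / (100 - total) * 100
}
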