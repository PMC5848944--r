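# Reproduction harness: recompute every packaged reference quantity from the
# shipped fixtures and compare against the expected values at stated
# tolerances. Serves as an end-to-end regression check of the whole pipeline.

#' Recompute the packaged reference results
#'
#' Runs the full pipeline on the packaged fixtures — species definitions,
#' reconstructed calibration standards, loading-experiment records and the
#' thermogravimetric step losses — and compares each derived quantity with
#' its expected value at a stated absolute tolerance: the solubility
#' parameters of poly(acrylic acid) and sodium polyacrylate, the polymer
#' coating fraction, the calibration line, remaining/adsorbed masses,
#' loading capacity, and the drug content of the optimally loaded composite.
#' Two rows exercise the `"display"` rounding mode, whose mass values chain
#' from the 3-decimal displayed concentration.
#'
#' @param species_file,calibration_file,loading_file Paths; default to the
#'   packaged fixtures (override to run the harness on other inputs, e.g. to
#'   demonstrate failure reporting).
#' @param tga_step_losses TGA step weight losses, percent; the polymer step
#'   first.
#' @return A data frame of class `reproduce_report` with columns `quantity`,
#'   `computed`, `expected`, `tolerance`, `pass`; attribute `ok` is `TRUE`
#'   when every row passes.
#' @examples
#' rep <- reproduce_reference()
#' print(rep)
#' @export
reproduce_reference <- function(
    species_file = system.file("extdata", "reference_species.csv",
                               package = "solrel", mustWork = TRUE),
    calibration_file = system.file("extdata", "r6g_calibration.csv",
                                   package = "solrel", mustWork = TRUE),
    loading_file = system.file("extdata", "loading_experiments.csv",
                               package = "solrel", mustWork = TRUE),
    tga_step_losses = c(25.2, 6.2, 5.5)) {
  rows <- list()
  add <- function(quantity, computed, expected, tolerance) {
    rows[[length(rows) + 1]] <<- data.frame(
      quantity = quantity, computed = computed, expected = expected,
      tolerance = tolerance, stringsAsFactors = FALSE)
  }

  sp <- read_species_file(species_file)
  add("delta PAA (J/cm^3)^1/2",
      compute_delta(sp[["PAA"]])$delta, 23.31, 0.005)
  add("delta sodium polyacrylate (J/cm^3)^1/2",
      compute_delta(sp[["sodium polyacrylate"]])$delta, 15.67, 0.005)

  add("polymer coating fraction (w/w %)",
      coating_fraction(tga_step_losses, organic_step_index = 1), 39.94, 0.005)

  cal <- read_calibration_file(calibration_file)
  curve <- fit_calibration(cal$points$concentration, cal$points$absorbance,
                           conc_unit_scale = cal$conc_unit_scale)
  add("calibration slope (A per unit)", curve$slope, 7.80333, 1e-5)
  add("calibration intercept (A)", curve$intercept, 0.0301, 1e-5)

  exps <- read_loading_file(loading_file)
  names(exps) <- vapply(exps, `[[`, character(1), "label")
  res <- function(label, ...) loading_result(exps[[label]], curve, ...)

  add("remaining mass, 30 C run (mg)",
      res("loading-30C")$remaining_mass_mg, 10.189, 1e-3)
  r15 <- res("loading-c0.015")
  add("remaining mass, 0.015 mol/L run (mg)", r15$remaining_mass_mg,
      42.589, 1e-3)
  add("adsorbed mass, 0.015 mol/L run (mg)", r15$adsorbed_mass_mg,
      101.114, 1e-3)
  add("loading capacity (mg/g)", r15$capacity_mg_per_g, 1011.1, 0.05)
  add("drug per 10 mg loaded composite (mg)",
      res("loading-optimum")$drug_content_per_10mg, 6.851, 1e-3)
  add("remaining mass, pH 3 run, display rounding (mg)",
      res("loading-pH3", rounding = "display")$remaining_mass_mg,
      125.501, 1e-3)
  add("remaining mass, pH 7 run, display rounding (mg)",
      res("loading-pH7", rounding = "display")$remaining_mass_mg,
      66.103, 1e-3)

  out <- do.call(rbind, rows)
  out$pass <- abs(out$computed - out$expected) <= out$tolerance
  attr(out, "ok") <- all(out$pass)
  class(out) <- c("reproduce_report", class(out))
  out
}

#' @export
print.reproduce_report <- function(x, ...) {
  df <- as.data.frame(x)
  df$computed <- signif(df$computed, 7)
  df$status <- ifelse(df$pass, "PASS", "FAIL")
  print(df[, c("quantity", "computed", "expected", "tolerance", "status")],
        row.names = FALSE, right = FALSE)
  cat(if (isTRUE(attr(x, "ok"))) "\nAll quantities reproduced.\n"
      else "\nSome quantities FAILED to reproduce.\n")
  invisible(x)
}
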