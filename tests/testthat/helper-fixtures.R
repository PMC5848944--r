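# shared fixtures: the reference calibration line and species
ref_curve <- function() calibration_curve(7.80333, 0.0301, conc_unit_scale = 1e-4)

ref_species <- function() {
  list(
    paa = species("PAA", molar_mass = 72.06, density = 1.20,
                  attraction_sum = 1399.83),
    napa = species("sodium polyacrylate", molar_mass = 94.04, density = 1.32,
                   attraction_sum = 1116.23),
    water = species("water", molar_mass = 18.02, density = 1.00, delta = 23.40),
    r6g = species("R6G", molar_mass = 479.01, density = 1.26, delta = 21.77))
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
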