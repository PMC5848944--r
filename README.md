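# solrel

Solubility-parameter screening and diffusive release kinetics for
polymer-coated drug carriers.

`solrel` is for experimentalists quantifying drug loading and release on
polymer-coated nanoparticle carriers (e.g. poly(acrylic acid)-coated
magnetite loaded with Rhodamine 6G as a model drug), and for anyone who
needs the three calculations such studies chain together:

1. **Group-contribution solubility parameters** (Small's method):
   δ = ρ·ΣFᵢ/M in (J/cm³)^1/2 for a repeat unit of molar mass M and density
   ρ, with Fᵢ the molar attraction constants; compatibility of
   drug/polymer/solvent triples is ranked by |δₐ − δᵦ| ("like dissolves
   like"). The pH-dependent speciation of PAA (acid, δ ≈ 23.31, vs sodium
   polyacrylate, δ ≈ 15.67, against water at 23.40) is the worked reference
   case.
2. **UV-Vis quantification**: Beer–Lambert calibration lines
   A = m·c + b with explicit unit scales and dilution factors; supernatant
   depletion gives remaining/adsorbed mass, loading capacity (mg drug per g
   particles), drug content per 10 mg composite, and cumulative release
   percentages; plus the thermogravimetric coating fraction
   loss_org/(100 − Σlosses)·100.
3. **Fickian release kinetics**: ∂C/∂t = D·∂²C/∂Z² on a plane sheet with
   uniform initial loading and perfect-sink faces; the early-time law
   Mₜ/M∞ = (4/δ)·√(Dt/π) (valid below 0.6), an implicit finite-difference
   solver cross-checked against the eigenfunction series, and least-squares
   fitting of D and of first-order kinetics p·(1 − e^(−kt)).

Seeded synthetic-data generators (`gen_calibration()`, `gen_loading()`,
`gen_release()`) produce all three data types with recorded ground truth, so
every pipeline stage is testable without instrument data.

## Worked example

```r
library(solrel)

# 1. compatibility screening: which PAA form matches water?
sp <- read_species_file(system.file("extdata", "reference_species.csv",
                                    package = "solrel"))
rank_compatibility(compute_delta(sp$water),
                   lapply(sp[c("PAA", "sodium polyacrylate", "R6G")],
                          compute_delta))
#>               species    delta  mismatch
#> 1                 PAA 23.31107 0.0889259
#> 2                 R6G 21.77000 1.6300000
#> 3 sodium polyacrylate 15.66805 7.7319481

# 2. loading quantification from a supernatant absorbance
curve <- calibration_curve(7.80333, 0.0301, conc_unit_scale = 1e-4)
exp <- loading_experiment(solution_volume_l = 0.020,
                          supernatant_absorbance = 0.377,
                          dilution_factor = 1000, particle_mass_g = 0.1,
                          initial_conc_molL = 0.15e-1)
loading_result(exp, curve)
#> Loading result: loading
#>   remaining concentration : 0.004446 mol/L
#>   initial / remaining mass: 143.703 / 42.589 mg
#>   adsorbed mass           : 101.114 mg
#>   capacity                : 1011.1 mg/g
#>   drug per 10 mg composite: 5.028 mg

coating_fraction(c(25.2, 6.2, 5.5), organic_step_index = 1)   # TGA steps
#> [1] 39.93661

# 3. Fickian release: simulate, then recover the diffusivity
slab <- fickian_slab(diffusivity = 5e-14, thickness = 1e-4)   # cm^2/s, cm
rc <- solve_fick_slab(slab, times = c(1, 2, 4, 8, 14), time_unit = "h")
rc
#> Release curve: 5 points over [1, 14] h, final fraction 0.932
fit_diffusivity(rc, thickness = 1e-4)
#> Fickian fit: D = 4.996e-14 cm^2/s (2 early-time points, RSS 3.5e-10)
```

Reading the numbers: the acid form of PAA is nearly matched to water
(mismatch 0.09) while the salt form is far (7.73), which is why release is
fast in neutral/acidic media and slow in alkaline media. The 0.015 mol/L
loading run retains 42.589 mg in solution, so 101.114 mg of the initial
143.703 mg adsorbed onto 0.1 g of particles — a capacity of 1011.1 mg/g.
About 39.94% (w/w) of polymer sits on the core by TGA. A 1 µm film with
D = 5×10⁻¹⁴ cm²/s releases 93.2% of its load in 14 h, and the early-time
√t fit recovers the diffusivity to 0.1%.

A thin command-line front end ships in `exec/solrel` (subcommands `delta`,
`rank`, `calibrate`, `loading`, `release`, `simulate-fick`, `fit-kinetics`,
`simulate`, `reproduce`), and `reproduce_reference()` recomputes every
packaged reference quantity with pass/fail reporting.

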