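# Reference species for solubility-parameter calculation.
# molar_mass g/mol (repeat unit for polymers), density g/cm^3,
# attraction_sum (J cm^3)^(1/2)/mol, delta (J/cm^3)^(1/2).
# Water and R6G carry pinned literature delta values (no group decomposition
# is available for them); the polymer attraction sums are supplied directly.
name,molar_mass,density,attraction_sum,delta,groups
PAA,72.06,1.20,1399.83,,
sodium polyacrylate,94.04,1.32,1116.23,,
water,18.02,1.00,,23.40,
R6G,479.01,1.26,,21.77,
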