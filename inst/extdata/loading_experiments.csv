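# Drug-loading experiment records (supernatant-depletion method).
# volume_l: solution volume (L); c0_molL: nominal initial concentration
# (mol/L) OR A0: measured initial absorbance (exactly one per row);
# A_sup: supernatant absorbance after adsorption; dilution: fold-dilution
# before measurement; particle_g: carrier particle mass (g).
label,volume_l,c0_molL,A0,A_sup,dilution,particle_g
loading-30C,0.020,0.0015,,0.860,100,0.010
loading-c0.015,0.020,0.015,,0.377,1000,0.100
loading-optimum,0.040,,1.177,0.291,1000,0.100
loading-pH3,0.020,0.015,,1.054,1000,0.100
loading-pH7,0.020,0.015,,0.569,1000,0.100
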