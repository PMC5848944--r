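# Molar attraction constants F, (J cm^3)^(1/2) / mol
# Small (1953) values converted to SI (factor 2.0455 from (cal cm^3)^(1/2)/mol);
# hydroxyl and carboxyl entries after Hoy (1970). Group decompositions and
# constant sets differ between tabulations; treat derived sums as estimates.
group,F
CH3,438
CH2,272
CH,57
C,-190
CH2=,389
CH=,227
C=,39
C6H5,1503
C6H4,1346
O,143
CO,563
COO,634
OH,462
COOH,565
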