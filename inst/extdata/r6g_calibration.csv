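# Rhodamine 6G calibration standards at 526 nm.
# SYNTHETIC/reconstructed: absorbances computed from the fitted reference
# line A = 7.80333 c + 0.0301 (raw standard absorbances were not reported).
# conc_unit_scale: 1e-4
concentration,absorbance
0.03,0.2641999
0.06,0.4982998
0.09,0.7323997
0.12,0.9664996
0.15,1.2005995
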