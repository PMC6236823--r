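# material: polystyrene
# density_g_cm3: 1.06
# columns: energy_keV mass_atten_cm2_g
20 0.4363885
30 0.26400192
40 0.21829668
50 0.19858616
60 0.18696418
80 0.17246294
100 0.1624682
150 0.14479296
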