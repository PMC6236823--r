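# material: ldpe
# density_g_cm3: 0.92
# columns: energy_keV mass_atten_cm2_g
20 0.43158175
30 0.27068496
40 0.22745934
50 0.20842508
60 0.19695559
80 0.18228197
100 0.1719491
150 0.15343848
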