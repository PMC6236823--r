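# material: acrylic
# density_g_cm3: 1.19
# columns: energy_keV mass_atten_cm2_g
20 0.5714
30 0.3032
40 0.235
50 0.2074
60 0.1924
80 0.1751
100 0.1641
150 0.1456
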