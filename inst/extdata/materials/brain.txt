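# material: brain
# density_g_cm3: 1.02
# columns: energy_keV mass_atten_cm2_g
20 0.805552
30 0.373722
40 0.2669585
50 0.2257655
60 0.2048705
80 0.1827815
100 0.1698465
150 0.1497475
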