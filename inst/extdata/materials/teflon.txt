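# material: teflon
# density_g_cm3: 2.16
# columns: energy_keV mass_atten_cm2_g
20 0.98730846
30 0.40884382
40 0.26785214
50 0.21506064
60 0.1893563
80 0.1640392
100 0.15048824
150 0.13105296
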