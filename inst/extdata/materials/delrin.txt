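# material: delrin
# density_g_cm3: 1.41
# columns: energy_keV mass_atten_cm2_g
20 0.66260524
30 0.32781761
40 0.24399783
50 0.21096633
60 0.19367192
80 0.17461452
100 0.16296703
150 0.14414261
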