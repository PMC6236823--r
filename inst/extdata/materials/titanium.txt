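# material: titanium
# density_g_cm3: 4.506
# columns: energy_keV mass_atten_cm2_g
20 21.6
30 6.84
40 2.97
50 1.62
60 1.03
80 0.517
100 0.337
150 0.187
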