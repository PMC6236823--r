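# generic 90 kVp tungsten spectrum, 2.5 mm Al filtration
# columns: energy_keV relative_fluence
20 0.00356173
22 0.0194239
24 0.0629562
26 0.144954
28 0.264536
30 0.410346
32 0.537692
34 0.65848
36 0.765765
38 0.855434
40 0.925722
42 0.952606
44 0.965709
46 0.96662
48 0.956955
50 0.938267
52 0.900665
54 0.859466
56 0.815437
58 1
60 0.721399
62 0.666613
64 0.612563
66 0.55935
68 0.58311
70 0.455726
72 0.405414
74 0.356142
76 0.307929
78 0.260782
80 0.214703
82 0.169017
84 0.124767
86 0.0818867
88 0.0403169
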