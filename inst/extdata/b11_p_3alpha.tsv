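# reaction: 11B(p,aa)a
# columns: energy_MeV sigma_mb
# provenance: SYNTHETIC approximation to the published 11B(p,aa)a excitation
# provenance: function, assembled by the package authors for desk-scale runs.
# provenance: Anchor point 0.6 MeV = 1400 mb reproduces the measured value
# provenance: reported for low-energy protons; 0.6-4 MeV rows sketch the
# provenance: measured resonance structure (675 keV resonance shoulder, broad
# provenance: ~2.6 MeV resonance); 4-40 MeV rows sketch an evaluated-library
# provenance: style smoothly falling tail. Values between the anchor and the
# provenance: qualitative features are hand-drawn, NOT a published evaluation.
0.6	1400
0.7	1150
0.8	640
0.9	420
1.0	300
1.1	260
1.2	250
1.4	280
1.6	330
1.8	420
2.0	560
2.2	740
2.4	900
2.6	1000
2.8	960
3.0	850
3.2	760
3.5	650
4.0	500
5.0	400
6.0	330
7.0	285
8.0	250
10.0	200
12.0	165
15.0	130
20.0	95
25.0	75
30.0	60
35.0	50
40.0	45
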