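# ICRP-21 style neutron flux-to-dose-rate conversion factors.
# provenance: transcribed from the standard maximal dose-equivalent
# provenance: tabulation (flux density delivering 1 mrem/h, inverted to
# provenance: mrem/h per unit flux of 1 n cm^-2 s^-1); values rounded as in
# provenance: the common health-physics reproduction of the table.
# cf_mrem_h_per_flux = 1 / (flux for 1 mrem/h)
energy_MeV	cf_mrem_h_per_flux
2.5e-08	0.003731
1.0e-07	0.004348
1.0e-06	0.004348
1.0e-05	0.003690
1.0e-04	0.003571
1.0e-03	0.003571
1.0e-02	0.003534
1.0e-01	0.020833
5.0e-01	0.071429
1.0e+00	0.117647
2.5e+00	0.125000
5.0e+00	0.125000
7.0e+00	0.121951
1.0e+01	0.120482
1.4e+01	0.133333
2.0e+01	0.129870
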