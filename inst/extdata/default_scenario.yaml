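# Default scenario: the study's two-tumor setup.
name: default
calibration_mode: mcnpx-like
tumor:
  radius: 0.71          # cm -> ~1.5 cm^3
  density: 1.1          # g/cm^3
phantom:
  radius: 9.0           # cm
  density: 1.1
depth_cases:
  shallow: [1.6, 3.0]   # SOBP interval, cm (45-60 MeV window)
  deep: [10.0, 11.3]    # SOBP interval, cm (121-130 MeV window)
ppm: [100]
n_peaks: 24
range_model:
  alpha: 0.0022         # cm/MeV^p (water)
  p: 1.77
  density: 1.1
baseline:                # traditional proton-therapy chains
  edep_mev_per_g: 14.0   # (MeV/g) per proton in tumor
  proton_flux: 0.5       # p cm^-2 s^-1 per incident proton
  proton_cf: 2.5         # mrem/h per unit flux, Ep < 60 MeV
physics:
  j_per_mev: 1.6e-13
  e_dep_capture: 2.3     # MeV per 10B(n,a)7Li (1.5 alpha + 0.8 7Li)
  e_dep_fusion: 8.67     # MeV per 11B(p,aa)a (three alphas)
  sigma0_b10: 3837       # barn at 0.0253 eV
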