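# borondose

Analytic comparison of two boron-mediated dose-enhancement schemes in
proton therapy, for medical-physics researchers evaluating their magnitude
before committing to experiments:

* **P-BFT** — proton–boron fusion: ¹¹B(p,αα)α initiated by the slowing-down
  protons themselves, releasing three alphas (≈ 8.67 MeV per reaction);
* **NCEPT** — neutron-capture enhancement: ¹⁰B(n,α)⁷Li capture of the
  beam's own secondary thermal neutrons (2.3 MeV deposited per capture).

The package replaces Monte Carlo transport with calibrated deterministic
generators — a Bragg–Kleeman beam/range model with spread-out-Bragg-peak
(SOBP) construction, track-length in-tumor proton spectra, and three-group
secondary-neutron spectra anchored to reported flux levels — and runs the
entire comparison pipeline at desk scale: multigroup cross-section folding,
reaction rates, equivalent-dose conversion, the traditional proton-therapy
baseline, and the out-of-field neutron burden.

## The core statistic

Reaction rates come from the discrete multigroup folding

    Ṅ = n(B) · Σᵢ φ(Eᵢ) σ(Eᵢ) · 10⁻²⁷ cm²/mb        [s⁻¹ per incident proton]

on a 100-keV proton grid (window 0.6–40 MeV for fusion) or a log-spaced
neutron grid (all groups; the 1/v capture law makes the thermal group
dominate), with φ(Eᵢ) the bin-integrated flux. Excess equivalent dose rates
follow as

    Ḋ = Ṅ · E_dep · 1.6×10⁻¹³ J/MeV / m_tumor · Q      [EGy/s],  Q = 20.

## Worked example

```r
library(borondose)
sc  <- read_scenario()        # packaged default scenario, 100 ppm
rep <- run_comparison(sc)
rep
#> <dose_report: scenario 'default', 14 channel rows>
#>   capture-rate increase with depth: 90.9%
#>  depth_case ppm              channel   value_Sv_s   value_Gy_s W_R         Q
#>     shallow 100 proton_baseline_edep           NA 2.240000e-09  NA        NA
#>     shallow 100 proton_baseline_icrp 5.034722e-09 1.006944e-09   5  1.450000
#>     shallow 100          pbft_excess           NA 1.100243e-14  20 20.000000
#>     shallow 100         ncept_excess           NA 3.101467e-16  20 20.000000
#>     ...
```

Reading the numbers: each incident proton delivers ≈ 2.2×10⁻⁹ Gy/s to the
tumor through ordinary stopping (the two baseline rows are redundant
chains: energy deposition, and ICRP conversion factor). At 100 ppm loading
the fusion channel adds ≈ 1.1×10⁻¹⁴ EGy/s, roughly depth-independent, while
the capture channel adds 3.1×10⁻¹⁶ (shallow) rising to 3.4×10⁻¹⁵ EGy/s
(deep) — a 90.9 % increase with depth, mirroring the strong depth dependence
of the thermal-neutron field. Both enhancements sit 4+ orders of magnitude
below the proton baseline even at 1000 ppm (scan `ppm: [100, 1000]` in the
config to see the exact ×10 scaling). The `neutron_*` rows are the
out-of-field burden: the fast group exceeds the thermal group by more than
three orders of magnitude, which is why ¹⁰B loading cannot meaningfully
reduce the neutron risk (`boron_capture_fraction()` stays below 1 % at
1000 ppm).

Key single calls:

```r
boron_atom_count(tumor_spec(boron_isotope = "11B", ppm = 100))  # 9.02e18
xs_lookup(b11_fusion_xs(), 0.6)                                 # 1400 mb
percent_increase(9.5e-8, 1.09e-6)                               # 91.28 %
```

## Command line

```sh
Rscript inst/exec/borondose compare --config inst/extdata/default_scenario.yaml --outdir out/
Rscript inst/exec/borondose spectra --particle neutron --depth 11.3 --out n.tsv
Rscript inst/exec/borondose fold --spectrum p.tsv --xs inst/extdata/b11_p_3alpha.tsv
```

(after installation, resolve the script via
`system.file("exec", "borondose", package = "borondose")`).

`compare` emits a per-channel CSV (`channel`, `value_Sv_s`, `value_Gy_s`,
`W_R`, `Q`, by `depth_case` and `ppm`) and a JSON report with the underlying
reaction rates — the data behind the depth-dependence, ppm-scan and
baseline-gap comparisons.

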