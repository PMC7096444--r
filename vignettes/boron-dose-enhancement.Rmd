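---
title: "Methods: boron-mediated dose enhancement in proton therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: boron-mediated dose enhancement in proton therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(borondose)
```

## The problem

Two schemes have been proposed to boost the biological effectiveness of
proton therapy by loading the tumor with a boron isotope:

* **P-BFT** (proton-boron fusion): ¹¹B in the tumor undergoes
  ¹¹B(p,αα)α with the slowing-down protons, releasing three short-range
  alpha particles (≈ 8.67 MeV total).
* **NCEPT** (neutron-capture enhancement): ¹⁰B captures the low-energy
  *secondary* neutrons that the proton beam itself produces in tissue,
  releasing a 1.5 MeV alpha and a 0.8 MeV ⁷Li ion (2.3 MeV deposited
  locally).

`borondose` implements the full analytical comparison of the two schemes —
reaction rates, excess equivalent dose rates, the traditional proton-therapy
baseline, and the out-of-field neutron burden — with deterministic analytic
generators standing in for Monte Carlo particle transport, so that every
stage runs at desk scale and is testable.

## The stated world

The scenario is a spherical head phantom (radius 9 cm, soft tissue at
1.1 g/cm³, mass fractions C 20% / H 10% / O 65% / N 5%) containing a
spherical tumor of radius 0.71 cm (≈ 1.5 cm³). Two positions are studied:
a shallow tumor spanning depths 1.6–3 cm (beam window ≈ 45–60 MeV) and a
deep one spanning 10–11.3 cm (≈ 121–130 MeV). Boron loadings are mass ppm,
100 ppm by default, scanned up to 1000 ppm.

## Beam model

### Range–energy relation

We use the Bragg–Kleeman power law `R(E) = α E^p / ρ` with water
coefficients α = 0.0022 cm·MeV⁻ᵖ, p = 1.77, scaled by the tissue density.
This reproduces the study's printed energy-depth pairings within 10 %
(60 MeV → 2.81 cm vs 3 cm; 130 MeV → 11.03 cm vs 11.3 cm) and is exactly
invertible, which the spectra and stopping powers rely on. The original
analysis obtained these curves from full Monte Carlo transport; the power
law is this package's deterministic stand-in.

### Spread-out Bragg peak

A pristine peak with nominal range `R` is modelled as the power-law
stopping rise `(R' − z)^{1/p − 1}` smeared by Gaussian range straggling
with σ_R = 0.012·R. The endpoint singularity is integrable and is removed
analytically by substitution before quadrature, so the profile is computed
to plotting accuracy without special-casing.

The SOBP places `n_peaks` pristine ranges evenly from the proximal border
to **2σ_R beyond the distal border** and solves a non-negative least-squares
problem for the weights that flatten the summed profile over the target
interval. The distal extension is deliberate: with the deepest range exactly
at the distal border, the dose at that border is inherently ~50 % of the
plateau (it sits on the falloff of the deepest peak), and no weighting can
make the closed interval flat. Clinically the distal prescription point is a
high-dose point, not the 50 % falloff, so the extension is the physically
standard choice. Consequence: the nominal window `e_min–e_max` reported for
the beam corresponds to the target borders, while the deepest pristine peak
carries ~1–2 % more energy.

**Flatness.** The plateau is flat to ±5 % whenever the range spacing of the
peaks does not exceed ≈ 1.5 straggling widths. For the deep geometry
(σ_R = 1.4 mm) 10 peaks already give ±0.3 %. For the shallow geometry
σ_R is only 0.36 mm, so 10 peaks (spacing 1.6 mm) ripple at ±12 % — a real
physical sampling effect, not a solver artifact — and ≈ 18 peaks are needed.
The package default is 24 peaks, which meets ±1 % in both geometries; the
test suite asserts ±5 % at 10 peaks (deep) and 18 peaks (shallow).

## In-tumor proton spectrum

The per-100-keV proton fluence inside the tumor is computed as track-length
fluence in the continuous-slowing-down approximation: a proton's track
length in an energy bin equals its residual-range difference across the bin,
clipped to the energies it actually has between entering and leaving (or
stopping in) the tumor, summed over pristine peaks with their SOBP weights
and divided by the tumor volume. Summed over all bins this reproduces each
proton's geometric path length in the tumor exactly, which the tests check
bit-exactly and against a brute-force depth-marching oracle. Bins below
600 keV are generated but flagged; the fusion folding excludes them through
its energy window.

## Secondary-neutron field

Neutron spectra span more than twelve decades in energy, so they live on a
piecewise log-spaced grid whose segment boundaries coincide with the group
boundaries (thermal < 0.4 eV, epithermal 0.4 eV–100 keV, fast > 100 keV —
the cadmium-cutoff convention; the source analysis names the groups but
never defines boundaries). A uniform 100-keV grid, as used for the proton
folding, would put the entire thermal group inside its first bin and make
1/v capture folding meaningless; this is the one place the package
deliberately departs from a single shared grid type, and the grid container
supports both spacings.

Each group carries a fixed shape — Maxwellian flux (`E·e^{−E/kT}`, 293 K)
for thermal, `1/E` for epithermal, an evaporation hump (`E·e^{−E/T_f}`,
T_f = 2 MeV) plus a flat cascade tail (10 % of the group) up to the incident
proton energy for fast — normalized so the *group-integrated* flux equals a
calibration amplitude. The amplitudes at the two anchor depths (3 cm and
11.3 cm) are the flux levels reported from the two Monte Carlo codes:

| group | mcnpx-like | geant4-like |
|---|---|---|
| thermal | 1.5×10⁻⁶ → 1.8×10⁻⁵ | 8×10⁻⁷ → 9×10⁻⁶ |
| epithermal | 10⁻⁵ → 10⁻⁴ | same |
| fast | ≈10⁻³ (depth-independent) | same |

(cm⁻²s⁻¹ per incident proton). Between the anchors the amplitudes
interpolate log-linearly in depth; outside they clamp with a warning. At an
anchor the group fluxes are reproduced *exactly*, by construction, so the
thermal deep/shallow ratios 12 (mcnpx-like) and 11.25 (geant4-like) follow
identically. The generator contains no randomness.

What a green test does and does not establish: the generator reproduces the
reported group flux levels and plausible within-group shapes; it does not
model angular distributions, spatial gradients across the tumor, or the
hydrogen-content sensitivity of the thermalization — so agreement here
validates the downstream arithmetic, not neutron transport.

## Cross-sections and folding

The ¹¹B(p,αα)α table ships as a plain-TSV fixture covering 0.6–40 MeV. It
is a *synthetic, hand-drawn* approximation: the only printed number in the
source material, σ(0.6 MeV) = 1400 mb, is anchored exactly, and the rest
sketches the known features (the 675 keV resonance shoulder, the broad
≈ 2.6 MeV resonance, an evaluated-library-style falling tail above 4 MeV).
The file header carries this provenance. Interpolation is lin-lin: the
folding is a pointwise product sum on a 100-keV mesh, where the
interpolation choice is second-order.

The ¹⁰B(n,α)⁷Li capture uses the analytic 1/v law σ(E) = σ₀√(E₀/E) with
σ₀ = 3837 b at 0.0253 eV (standard thermal value; the source never states
one).

The folding engine implements the discrete multigroup sum
`Σᵢ φ(Eᵢ)·σ(Eᵢ)` with **no ΔE factor** — φ(Eᵢ) is the bin-integrated flux —
because that is the bookkeeping under which the published folded values
(70.52 and 63.35 mb·cm⁻²s⁻¹) arise. σ is collapsed by midpoint evaluation
(geometric midpoints on the log grid, which matters for 1/v), bins outside
a table's validity collapse to zero, and the fusion window is
0.6–40 MeV inclusive on bin midpoints. Above 40 MeV the tail is neglected,
matching the tabulated 400-group cap; in practice the in-tumor spectrum
barely reaches 40 MeV anyway (a proton entering the shallow tumor at its
proximal border carries ≈ 40.5 MeV).

With the package defaults the synthetic folded sums come out at ≈ 72.5
(shallow) and ≈ 58.7 (deep) mb·cm⁻²s⁻¹ — the same order as the published
70.52/63.35, with a 19 % shallow/deep spread against their 11 %. These were
not tuned; they fall out of the Bragg–Kleeman defaults plus the synthetic
cross-section fixture.

## Dosimetry

* **Excess channels** (both schemes): `Ḋ = rate × E_dep × 1.6×10⁻¹³ / m × Q`
  in EGy/s, with E_dep = 2.3 MeV (capture) or 8.67 MeV (fusion), tumor mass
  m = volume × density ≈ 1.65×10⁻³ kg (never printed in the source; derived),
  and Q = 20 for the heavy charged products. The J/MeV constant is kept at
  the rounded 1.6×10⁻¹³ so printed arithmetic reproduces exactly;
  it is a function argument.
* **Proton baseline**, two redundant chains: energy deposition
  (14 (MeV/g)/p → 2.24×10⁻⁹ Gy/s) and the conversion-factor chain
  (φ = 0.5 cm⁻²s⁻¹ × CF = 2.5 mrem/h × Q = 1.45 → 5.03×10⁻⁹ Sv/s, then
  ÷ W_R). The published value for the second chain, ~4.8×10⁻⁹ Sv/s, is ~5 %
  below the product of its own printed factors; we compute the product and
  match within 10 %, flagging rather than absorbing the discrepancy. The
  proton W_R is not printed either; 5 is the only value consistent with the
  published Sv/Gy pair and is the (configurable) default.
* **Out-of-field neutrons**: group fluxes × flux-weighted group-average
  ICRP-21-style conversion factors (packaged sparse table, log-log
  interpolated, clamped outside 2.5×10⁻⁸–20 MeV) × group quality factors
  (thermal 2.3, epithermal 2, fast 6–11 resolved by linear-in-log-E
  interpolation and flux-averaged), reported in Sv/s and, via the group W_R
  (5/10/5), in Gy/s. With the deep-tumor field the fast group exceeds the
  thermal group by ≈ 3.8 decades.
* **Capture competition**: the fraction of phantom-wide thermal absorptions
  occurring on the tumor's ¹⁰B,
  `f = N_B σ_B / (N_B σ_B + Σ N_el σ_el)` with 2200 m/s cross-sections
  (H 0.332 b, N 1.83 b, C and O negligible). At 1000 ppm f ≈ 0.5 %, and
  f = 10 % is only reached near ≈ 2–3×10⁴ ppm — which is why loading the
  tumor cannot measurably reduce the neutron burden on healthy tissue.

## Numerical choices and degenerate inputs

* Quadrature: composite Simpson with 201 points on the singularity-removed
  pristine-peak integral; NNLS by an in-package Lawson–Hanson solver (the
  problems are ≤ ~30 columns).
* The folding window is inclusive at both ends on bin midpoints; on the
  default uniform grid that selects midpoints 0.65–39.95 MeV.
* Zero-weight beams, zero calibrations, zero ppm and zero spectra all
  propagate to exact zeros rather than errors; negative energies, depths and
  masses raise domain errors; malformed cross-section files are rejected,
  not repaired.
* The pipeline is fully deterministic — repeated runs are bit-identical —
  so the CLI accepts `--seed` only for interface compatibility.

## Known limitations

No transport: no lateral spreading, no angular distributions, no spatial
dose maps, no voxelized phantom. Fixed quality factors, no microdosimetry
of the ~10 µm alpha tracks. The fusion cross-section fixture is an
approximation anchored at one published point; absolute fusion rates
inherit its uncertainty (order-of-magnitude fidelity, demonstrated ~±20 %
agreement with the published folded sums). Capture rates at depths between
the anchors rely on the log-linear interpolation assumption.

## Worked example

```{r example}
sc <- read_scenario()          # packaged default: both depths, 100 ppm
rep <- run_comparison(sc)
rep
subset(rep$channels, depth_case == "deep",
       select = c(channel, value_Sv_s, value_Gy_s, Q, W_R))
```
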