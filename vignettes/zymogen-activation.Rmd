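---
title: "Models and methods: quantifying proDer p 3 activation"
author: "zymokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: quantifying proDer p 3 activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zymokin)
```

## The system

proDer p 3 is the zymogen of the house-dust-mite trypsin-like protease
Der p 3: an 11-residue propeptide (NPILPASPQAT in the N9Q background
used throughout, plus an EF- cloning extension) ahead of the protease
domain, which begins at the canonical IVGG junction. The propeptide
carries a proline-rich PxxPxxP motif (prolines 2, 5, 8). Because the
propeptide ends in threonine rather than Lys/Arg, the zymogen cannot
auto-activate; maturation is carried out inter-molecularly by the
cysteine protease Der p 1. This package implements the quantitative
analyses by which that activation is characterised — proteoform and
mass bookkeeping, thermal-stability fits, activation progress-curve
kinetics, and time-resolved quenched-flow electrospray-MS
quantification — together with a synthetic-data generator that stands
in for the fluorimeter and the mass spectrometer, so every estimator
can be validated by parameter recovery against known ground truth.

## Proteoform bookkeeping

Masses are **average** (chemical) masses: the species masses this
system is described by (zymogen 26354 Da, mature 24987 Da, propeptide
1385 Da, leucine-enkephalin standard 556 Da) are deconvoluted-ESI
average masses, and the standard average residue-mass table reproduces
them (`average_mass("EFNPILPASPQAT")` = 1384.55; `"YGGFL"` = 555.63).
Positive-mode ions are `[M + zH]^z+` with a proton mass of 1.00728 Da;
m/z values are kept at full precision and rounded only for reporting.
Cleavage (`cleave()`) enforces the hydrolysis mass balance
`mass(N) + mass(C) = mass(whole) + 18.015` to 0.01 Da.

Each expressed construct's N-terminal sequencing catalog is expanded by
`enumerate_truncations()` into proteoforms classified *activatable*
(N-terminus at or before the IVGG junction — the activator can still
produce mature enzyme from it), *non-activatable* (N-terminus inside
the mature domain, e.g. the ALAGE- fragment of the P-A preparation), or
*unknown* (rows whose sequence was not identified). "Unknown" counts in
neither fraction; this matters only for the deletion constructs, which
carry 2–9% unidentified material. Catalog sequences are N-terminal
windows, not complete chains, so they are stored with
`sequence_partial = TRUE` and no mass is derived from them; forms must
align to the construct reference allowing N-terminal truncation or
extension only.

Motif detection reports maximal runs of prolines spaced exactly three
apart (the period of a polyproline-II helix), with `min_prolines = 2`
by default so that the degraded PxxP pairs of the single mutants are
still visible; consecutive prolines ("PPP") are not a hit.

## Two-state thermal unfolding

Melting curves (fluorescence at 320 nm during a 0.5 °C/min ramp read
every 30 s, i.e. 0.25 °C spacing, 201 points over 20–70 °C) are fitted
with the van't Hoff two-state model with ΔCp = 0 and linear baselines:

$$f_U(T) = \frac{K}{1+K},\quad K = e^{-\Delta G/RT},\quad
\Delta G = \Delta H_m\!\left(1 - T/T_m\right),$$
$$y(T) = (y_N + pT)(1-f_U) + (y_U + qT)\,f_U .$$

All six parameters are fitted by Levenberg–Marquardt; the start point
places \(T_m\) at the maximum smoothed derivative, takes baselines from
the outer 10% of points, and uses ΔHm = 300 kJ/mol, a typical unfolding
enthalpy for a ~25 kDa globular domain. Internally everything is in
kelvin (R = 8.314 J mol⁻¹ K⁻¹); I/O is in °C. These transitions are
irreversible, so the fitted midpoint is always reported as an
*apparent* Tm and no reversibility analysis is attempted. Since no
measured ΔHm values exist for this system, recovery studies fix
ΔHm = 300 kJ/mol in simulation and compare only Tm. A curve whose
baseline-corrected amplitude does not exceed five times the baseline
scatter is rejected as transition-free; a transition detected in the
outer 5% of the scan range is flagged.

## Activation progress curves

In the coupled continuous assay (12.5 nM zymogen, reporter substrate in
large excess), product release follows the classical lag equation

$$P(t) = v_s t + (v_i - v_s)\frac{1 - e^{-k_{obs}t}}{k_{obs}},$$

with initial rate \(v_i\) (basal activity of the zymogen pool),
steady-state rate \(v_s\) (fully matured enzyme) and the
pseudo-first-order maturation constant \(k_{obs}\). Substrate depletion
over the 30-min window is neglected (product ≪ 10 µM substrate),
consistent with the constant-\(v_s\) form. `progress_value()` uses
`expm1` for small `k*t` and the analytic limit \(P = v_i t\) at
\(k_{obs}=0\). Fits warn when the observation window is shorter than
~3/\(k_{obs}\) (the estimate remains unbiased in our recovery studies,
but its variance grows) and when \(v_s < v_i\) ("no activation").
`fit_kobs_linear()` regresses \(k_{obs}\) on activator concentration
with a **free intercept**, since a small basal activity is observed in
practice; the slope is the apparent specificity constant of activation,
valid because 12.5 nM zymogen is far below the µM-scale Michaelis
constant.

## Michaelis–Menten depletion and the species network

Bulk maturation of 16 µM zymogen by 0.16 µM activator is modelled by
\(dZ/dt = -k_{cat} E_1 Z/(K_m + Z)\). Two deliberately independent
implementations are provided and cross-checked to 1 × 10⁻⁶ relative on
a 2000-point grid: stiff numerical integration (`deSolve::lsoda`,
rtol 1e-10) and the closed form of the integrated Michaelis–Menten
relation \(K_m \ln(Z_0/Z) + (Z_0 - Z) = k_{cat}E_1 t\), solved
explicitly with the Lambert-W function (log-space Newton iteration
beyond the overflow range of `pracma::lambertWp`). Optional first-order
sinks represent zymogen autolysis (the inactive A18LAG-type fragment
produced by self-cleavage after the propeptide-adjacent lysine) and
slow self-degradation of accumulated mature enzyme; with sinks active
only the ODE route is allowed.

`fit_mm_depletion()` fits \((K_m, k_{cat})\) with fixed, known
\(E_1, Z_0\). Joint identifiability needs the course to traverse both
the saturated and sub-\(K_m\) regimes; when the fitted \(K_m\) exceeds
10 × \(Z_0\) or its relative standard error exceeds 1, the decay is
effectively exponential and the function falls back to a first-order
fit, reporting only \(k_{cat}/K_m\) with an explicit flag. Confidence
intervals are Wald-type (delta method for the ratio); they are honest
about width, mirroring the practice of reporting ranges rather than
point values for weakly determined constants.

Mutant preparations start as mixtures of truncated forms.
`simulate_species_network()` integrates activator-proportional
first-order processing of each form (exactly, via the closed-form
linear solution, not a numerical integrator), with non-processable
forms inert and optional autolysis/degradation sinks; with a single
species it reduces to the depletion model in the first-order limit,
and total protein is conserved to 1e-9 µM.

The choice \(k_{cat} = 0.1\) s⁻¹ (with \(K_m = 4.5\) µM) in the default
wild-type MS scenario makes 16 µM zymogen deplete essentially completely
within the 40-min run, matching the qualitative timescale of the
experiment; the resulting specificity constant is 0.022 µM⁻¹ s⁻¹. No
attempt is made to reproduce the published 22–44 µM⁻¹ s⁻¹ figure, which
is hard to reconcile with a 40-min depletion of 16 µM zymogen by
0.16 µM activator and likely reflects a units ambiguity; the package
reports in µM⁻¹ s⁻¹ throughout.

## Quenched-flow MS quantification

For each declared (species, charge state) target the pipeline builds an
extracted-ion current (`extract_xic`, summing centroids within ±0.5 Th
by default — integer-rounded charge-state m/z values motivate the
window), normalizes every scan to the internal standard
(\(I_t = I_o/I_{std}\)), sums normalized charge states per species, and
scales to concentration via \(C_t = C_0\,\Sigma I(t)/I_0\) with
\(C_0 = 16\) µM. \(I_0\) is the initial normalized intensity of the
zymogen pool; for constructs starting as mixtures it is the sum over
those forms. Charge-state sets are declared, not discovered — peak
picking and deconvolution are upstream concerns. Equal ionization
response across proteoforms is assumed by the concentration equation;
the generator nevertheless exposes per-species response factors so the
bias of that assumption can be studied (it is exactly the response
ratio relative to the zymogen pool, as the test suite asserts).

Numerical choices worth stating:

* **\(I_0\) anchor.** By default \(I_0\) is the t = 0 extrapolation of
  a local quadratic fit to the pool intensity over the first 20 scans
  (one minute). A single-scan anchor imprints that scan's noise on the
  entire concentration scale; the windowed anchor reduces this to
  ~0.1% while the quadratic absorbs the slight curvature of the early
  decay (extrapolation error ≲ 1e-6 relative on noise-free data).
  `i0_scans = 1` restores the literal pointwise definition and makes
  the noise-free round trip exact to machine precision.
* Scans in which the standard has no signal are dropped from all
  traces (missing, not zero), with a reported count.
* Declared targets closer than twice the matching tolerance are flagged
  ambiguous on both species.
* The propeptide course is reconstructed and reported but not used for
  kinetic fitting — it is a small, noisier species; kinetics are fitted
  on the protein courses (specifically the zymogen-pool decay).

## The synthetic-data generator

`simulate_qfms_series()` emits stick (centroid) spectra every 3 s
(20 scans/min): one centroid per (species, charge) at the theoretical
m/z with intensity = concentration × response × envelope weight, plus
the constant 1.8 µM internal standard. Charge envelopes default to the
observed sets (zymogen 10–12+, mature 9–12+, propeptide 1–2+) with
uniform weights — the true envelope shape is unknowable from reported
data, and uniform weights exercise the summation logic without favouring
any charge.

The noise model separates the error sources an internal standard can
and cannot correct: a per-scan multiplicative ionization fluctuation
shared by every centroid in a scan (`sigma_scan`, default 2% — the
dominant electrospray instability, cancelled exactly by normalization),
independent per-centroid detector noise (`sigma_centroid`, default
0.3%, appropriate for intense protein centroids and *not* removable by
normalization), Gaussian m/z jitter (0.05 Th) so tolerance matching is
exercised, and an optional slow global drift. Quench plumbing is
abstracted to "reaction time = scan time" with a configurable dead-time
offset (default 0).

What the generator does **not** emulate — and hence what passing
recovery tests do not demonstrate about real data: isotope envelopes
and peak shape, detector saturation, unassigned degradation fragments
stealing ion current, charge-state envelope drift during unfolding or
maturation, and unequal response factors (available as a parameter but
equal by default). The melting and progress-curve simulators likewise
apply clean relative Gaussian noise to exact forward models; real
baselines drift nonlinearly and real lag curves include mixing
transients.

## Problem sizes and determinism

Every simulator takes an explicit integer seed and is a pure function
of (truth, seed). The recovery studies shipped with the package use 50
replicates for progress-curve and melting recovery (1800 s/5 s and
201-point curves), 50 replicates of the full 801-scan MS pipeline, and
2000-point grids for the ODE/closed-form cross-check — sizes at which
the estimator means are stable to well within the tolerances asserted,
while the whole suite runs in under a minute on a laptop-class machine.

## Known limitations

* The two-state Tm is apparent; for an irreversible transition it
  depends in principle on scan rate, which the model does not capture.
* `fit_mm_depletion` treats reconstruction noise as i.i.d., though
  normalization leaves weak correlation across scans; Wald intervals
  are therefore slightly optimistic.
* The species network is first-order in each form (valid when the pool
  is far from saturating the activator, or as an effective rate); it
  does not model competition between forms for the activator.
* The activatable/non-activatable classification is operational
  (position of the N-terminus relative to IVGG), not a prediction of
  processing kinetics: an activatable form may still be processed
  slowly or not at all, as the truncated forms of the proline mutants
  show.
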