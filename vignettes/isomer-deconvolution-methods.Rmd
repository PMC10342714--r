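---
title: "Methods: isomer deconvolution, CID energetics and stability kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isomer deconvolution, CID energetics and stability kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ledams)
```

## Scope and assumptions

`ledams` targets the situation where two (or a few) isomeric analytes
co-elute completely under a deliberately simple HPLC method and must be
distinguished from their ion-trap MS/MS spectra alone. The package
assumes:

* one shared reference ion (Ri) — the unfragmented precursor acquired in
  a dedicated low-collision-energy MS/MS event — with identical response
  across the isomers;
* characteristic product-ion/reference-ion (Pi/Ri) ratios that are
  stable at fixed MS/MS conditions, so a mixture's measured ratios are a
  composition-weighted linear combination of the pure compounds' ratios;
* a two-segment acquisition: the internal standard (IS) is
  chromatographically separated from the analytes and monitored in
  segment 1, while segment 2 alternates the Ri event and the product-ion
  scan (Pis) event over the unresolved analyte peak.

Everything else — retention behaviour, matrix effects, isotope fine
structure — is out of scope.

## The deconvolution model

For ions `i = 1..m` and isomers `x = 1..n` the model is `r = M f`, with
`M[i, x]` the characteristic ratio of ion `i` in pure isomer `x`, `r`
the measured ratio vector and `f` the isomer fractions. The shipped
ELF94/ELF96 table has `m = 6`, `n = 2`: the system is overdetermined,
which buys specificity — a contributor whose fingerprint is not in `M`
cannot be fitted away and surfaces as residual error.

Two deliberate choices:

* **No sum-to-one constraint.** Writing `f_B = 1 - f_A` would force any
  unknown co-eluter's signal into the known isomers. The free fit keeps
  that information in the residual; fractions are renormalised only when
  the Ri signal is physically distributed between isomers (peak areas,
  reconstructed profiles), so assigned abundances always conserve the
  measured Ri signal.
* **Nonnegative least squares by default.** Unconstrained least squares
  is available (`solver = "unconstrained"`) and agrees with NNLS
  whenever its optimum is already nonnegative, but it can return
  negative percentages on noisy near-boundary mixtures, which have no
  physical reading. `brute_force_mixture()` provides an independent
  exhaustive-grid check of either solver (fractions up to 1.2 so
  over-unity totals remain detectable; at most 3 isomers).

Degenerate matrices (proportional isomer columns) are rejected with the
offending pair named: such isomers are spectrally indistinguishable at
the chosen conditions and no solver can help.

### Scan-by-scan mode

Because the Ri and Pis events alternate in time, a Pis scan has no
simultaneous Ri measurement. The package linearly interpolates the Ri
abundance between the two neighbouring Ri scans at each Pis scan time —
the event period (0.01 min by default) is small against a peak sigma of
0.2 min, so interpolation error is negligible relative to instrument
noise. Scans with non-positive interpolated Ri are reported as gaps, not
imputed. Summed over isomers, the reconstructed profiles reproduce the
interpolated Ri trace at every assigned scan by construction.

## ERMS energetics

Per excitation-amplitude step, SY and PiF are exact complements (the
package computes `100 * (part/total)`, ratio first, so neither can round
above 100); PiY references the summed product signal to the
pre-fragmentation precursor mean. Choices where the procedure is
underdetermined by convention:

* *Pre-activation region*: steps with PiF at or below 1% (configurable;
  a threshold of zero admits exactly-zero-PiF steps). If no step
  qualifies, the lowest-amplitude step is used with a warning.
* *SY_ExA50*: linear interpolation between the bracketing grid points of
  the first downward crossing of 50%. Practitioners read this value off
  a plotted curve; interpolation is the reproducible equivalent.
* *PiY maximum ties*: resolved to the lowest amplitude — the minimal
  energy achieving maximal yield is the operationally useful one.
* *Zero-signal steps*: dropped from curves rather than imputed.

## Quantitation and validation

Calibration is ordinary unweighted least squares of the peak-area ratio
(PAR) on nominal concentration over the five-level design (5–100 ng/mL).
LOD and LOQ use the response-SE-and-slope approach with ICH-style
multipliers 3.3 and 10 and the intercept's standard error as the
response SE; their 10/3.3 ratio is exact whenever both are defined.

The validation plot regresses estimated against expected composition on
the fraction scale (0–1), one point per mixture, each point being the
mean of that mixture's replicate determinations. This reading is forced
by arithmetic: independent noise of SD 0.01 on the six ratios propagates
to a per-replicate fraction SD of `0.01 * sqrt(diag((M'M)^-1))` ≈ 0.030
for this matrix, so per-replicate points could never produce a residual
standard error in the 0.01–0.02 range, while 6-replicate means
(0.030/√6 ≈ 0.012) land exactly there. The residual standard error
(`se_lin`, `sqrt(SSR/(n-2))`) is the precision summary; ±2·se_lin reads
as a 95% band on the recovered purity ratio.

## Stability kinetics

All replicates are pooled into one regression of `ln C` on time with a
free intercept — the rate constant uses only the slope, and pinning the
intercept to the nominal `ln C0` would let preparation bias leak into
`k`. The half-life `ln(0.5)/k` is censored to the label `">120"` when
`|k| < 0.006 ln(µM)/min` or when the computed value exceeds the 120-min
incubation horizon: extrapolating far past the last observed time point
reports noise, not chemistry. The magnitude comparison handles the decay
sign convention (`k ≤ 0`); a positive fitted slope (apparent growth) is
flagged invalid rather than silently reported. Half-life uncertainty is
delta-method propagated, `|ln(0.5)| * sd(k) / k^2`. The panel runner
checks plasma hydrolytic activity on a reference substrate and fails the
check if the reference does not itself degrade within the horizon.

## The synthetic-data generator

The generator supplies every input at the study's own design points and
emits its ground truth alongside the data, so each module has a recovery
target.

* **ERMS ramps** (`gen_erms`): 0–50 a.u. unit grid. The precursor holds
  an exactly flat plateau up to the activation onset
  (`midpoint − 2·width`) and follows `plateau · plogis((midpoint −
  ExA)/width)` above it; fragmented signal is shared among product
  channels by fixed branching fractions after removal of an ejection/
  low-mass-cut-off loss fraction. The clamped plateau is deliberate: it
  gives an exact-zero-PiF region for the precursor-max estimator and
  keeps noise-free PiY at or below 100% without ejection loss, at the
  cost of SY matching the logistic only above onset (the 50% crossing is
  unaffected; with detection loss `d` it shifts to
  `midpoint − width·log(1−d)`, which the tests verify in closed form).
  An optional exponential roll-off above a chosen amplitude reproduces
  the post-maximum decline of product-yield curves.
* **Chromatograms** (`gen_chromatogram`): Gaussian envelopes (default
  sigma 0.2 min), IS at 1.5 min in segment 1, co-eluting isomers at
  5.0 min in segment 2, alternating Ri/Pis events every 0.6 s — about 40
  event pairs across ±2 sigma, comfortably above the sampling needed to
  define the peak. Co-elution at an identical retention time is the
  default (the worst case for deconvolution); partial resolution is an
  override.
* **Noise model**: multiplicative lognormal (unit mean, given CV) on
  abundances; additive Gaussian with SD 0.01, truncated at zero, on
  ratio vectors — the replicate SD printed for every characteristic
  ratio. The truncation slightly biases near-zero ratios upward; tests
  account for it by checking ions whose clean ratios sit several SDs
  above zero.
* **Degradation panels** (`gen_degradation_panel`): triplicates at
  0/30/60/120 min, 1 µM start, 5% CV lognormal noise — the stability
  study design.

What passing tests on these data do *not* show: robustness to peak
tailing, drifting ratios across the elution profile, matrix
interferences, isotope overlap, or detector saturation. The generator
emulates an idealised instrument; real-data performance must be
established on real standards.

## Numerical notes and problem sizes

* Trapezoidal integration throughout (areas agree with the Gaussian
  closed form to <0.1% at 20 points per sigma).
* m/z values are matched to data columns with a ±0.5 Th tolerance
  (unit-resolution trap).
* Time segments are half-open `[start, end)` intervals, defaults
  `[0, 3.28)` and `[3.28, 10)` min, so the boundary belongs to exactly
  one segment.
* Monte-Carlo sizes were chosen to make the checked statistics stable at
  the asserted tolerances: 200 repeats for rate-constant recovery, 1000
  replicates for fraction-scatter calibration, 100 random instances for
  solver/grid-oracle equivalence at grid step 0.005.
* All generators are pure functions of (parameters, seed) and restore
  the caller's RNG stream.

## Known limitations

* The grid-search oracle is limited to three isomers; the least-squares
  solver itself has no such limit but has only been validated for small
  `n`.
* Ri interpolation assumes the Ri trace is locally linear between
  adjacent scans; very narrow peaks relative to the event period would
  violate this.
* No weighted or robust regression variants for calibration; no
  Michaelis–Menten kinetics (the first-order model presumes substrate
  concentrations well below K_M).
* The optional mzML ingestion path is not implemented; CSV schemas (and
  the synthetic generator) are the supported inputs.
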