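---
title: "Isotope-edited IR difference spectroscopy of DNA duplexes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotope-edited IR difference spectroscopy of DNA duplexes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoedir)
```

## The measurement this package models

The IR spectrum of a DNA duplex between 1600 and 1780 cm^-1^ is a pile-up
of carbonyl and ring stretching bands from every base. Isotope editing
isolates one of them: a duplex is synthesized twice, once with ordinary
thymine ("light") and once with ^13^C substituted at the thymine C2
carbonyl ("heavy"), and the heavy absorbance spectrum is subtracted from
the light one. Every vibration not involving the labeled atom cancels;
vibrations that do involve it survive as a characteristic pair — a
positive band at the light frequency and a negative band at the position
downshifted by the isotope mass effect (≈20 cm^-1^ for ^12^C→^13^C in a
partially localized C=O stretch).

Two observables carry the biology:

* the **major band position** (~1720 cm^-1^ free, ~1710 cm^-1^
  drug-bound), which reports on hydrogen bonding to the thymine C2
  carbonyl facing the minor groove, and can be translated into an
  effective Gutmann acceptor number through a solvatochromatic
  calibration;
* the **minor band** near 1670 cm^-1^ (~¼ of the major amplitude), whose
  splitting into two components with the lower one at ~1655 cm^-1^
  accompanies Hoogsteen A–T pairing — a candidate marker band for
  detecting Hoogsteen pairs in solution.

No measured duplex spectra are distributed with the original study, so
the package carries a first-class synthetic generator that reproduces the
band structure, replicate statistics, and noise of the experiment; every
downstream stage is developed and tested against it.

## The synthetic generator

A `duplex_template` is an additive band model: a list of bands (center,
FWHM, amplitude, sign, `labeled`, `per_label`), a label count, and an
isotope shift. `generate_spectrum()` evaluates

$$ A(\nu) \;=\; \sum_b a_b\, g(\nu;\, c_b,\, w_b) \;+\; d(\nu) \;+\; \varepsilon(\nu), $$

where \(g\) is a unit-height Gaussian (pseudo-Voigt optional),
\(d\) a low-order polynomial drift, and \(\varepsilon\) i.i.d. Gaussian
noise. In the heavy variant every `labeled` band moves down by the
template's isotope shift; `per_label` amplitudes are multiplied by the
number of labeled bases. The six presets encode the study's conditions:

| preset | major | minor region | labels | pairing |
|---|---|---|---|---|
| `TA_WC` | 1720 | single 1670 (FWHM 30) | 2 | Watson–Crick |
| `AT_WC` | 1720 | 1665 dominant + 1690 weak | 2 | Watson–Crick |
| `TA_ECHINOMYCIN_HG` | 1710 | 1690 + 1655 | 2 | Hoogsteen (drug-induced) |
| `AT_ECHINOMYCIN_WC` | 1710 | single 1665 | 2 | Watson–Crick (drug-bound) |
| `A6_WC` | 1720 | single 1670 | 1 | Watson–Crick |
| `M1A_A6_HG` | 1720 | 1680 + 1655 | 1 | Hoogsteen (m^1^A-enforced) |

Choices that the reported band positions do not pin down, fixed once
here:

* **Line shape.** Gaussian by default — the simplest shape that
  reproduces the one reported width (minor band FWHM ≈ 30 cm^-1^);
  pseudo-Voigt with a fixed Lorentzian fraction is available since
  condensed-phase carbonyl bands often carry Lorentzian character.
* **Absolute amplitudes.** Only relative statements exist ("roughly one
  quarter", "~50%"). The major band is 1.0 absorbance unit per label; the
  minor region totals 0.25 per label; the phosphate normalization band at
  1080 cm^-1^ is 2.0 (label-independent). In split presets the
  drug-induced components share the minor amplitude equally, and the
  AT-duplex shoulder takes ¼ of the minor total — free parameters of the
  model, not measured quantities, as are the weak unlabeled 1740/1605
  cm^-1^ features added to drug-bound presets so that peak detection must
  discriminate against them.
* **Major band width** 25 cm^-1^ (unreported; slightly narrower than the
  composite minor band).
* **Grid.** 1000–1800 cm^-1^ at 1 cm^-1^. The fine grid keeps
  interpolation and fit discretization error far below the 4 cm^-1^
  instrument resolution; `resample()` coarsens to 4 cm^-1^ when raw
  instrument output is to be emulated.
* **Noise defaults.** `noise_model()` uses sigma = 0.005 absorbance
  units, no drift, no jitter, and an explicit integer seed — there is no
  hidden global RNG state, and `(seed, replicate, label state)` fully
  determines a spectrum. Noisy study-condition checks in the test suite
  use sigma = 0.06 with mild polynomial drift and 0.3 cm^-1^ band-center
  jitter, which puts the carbonyl difference band near SNR 20 for a
  doubly labeled duplex — strong but realistically noisy data.

## Preprocessing

`baseline_correct()` subtracts the interpolant through the spectrum's own
values at anchor wavenumbers (piecewise-linear or natural spline — vendor
"multipoint" functions differ and the original choice is unstated, so
both are provided; with only two anchors both are the same line, and end
segments extend linearly). Default anchors 1000, 1350, 1550, 1790 cm^-1^
flank the phosphate and carbonyl analysis windows where duplex spectra
are locally flat. The operation is linear and idempotent, and exactly
zero at every anchor.

`normalize_phosphate()` divides by the maximum in 1050–1110 cm^-1^,
centered on the ~1080 cm^-1^ symmetric phosphate stretch, an internal
concentration standard present at fixed stoichiometry. The window
*maximum* (not area) is used because the band is isolated and sharp; the
choice is configurable. Normalization makes the subtraction factor 1.0
the natural choice for differencing, and the label-count linearity result
(a one-label duplex gives exactly 50% of the two-label difference
amplitude) is exact under it because every labeled band scales with the
label count while the phosphate reference does not.

## Differences, replicate statistics, and noise lines

`replicate_difference()` pairs light and heavy replicates one-to-one,
differences pair-by-pair, and averages — equivalent in expectation to
subtracting mean spectra, but yielding a per-point SD across pairs.
Noise lines (replicate minus replicate within one condition) estimate
pure measurement noise with all real signal cancelled; they are formed
from consecutive disjoint pairs (1,2), (3,4) so the lines are mutually
independent. The attached SNR is the absolute extremum of the mean
difference in 1600–1780 cm^-1^ divided by the pooled RMS of the noise
lines in the same window; note a noise line's RMS is √2 times the
single-spectrum noise SD.

## Band fitting and the identifiability problem

`fit_bands()` fits a sum of signed Gaussian (or pseudo-Voigt) components
by Levenberg–Marquardt with box bounds, seeded from detected peaks, and
selects the component count by corrected AIC with ties broken toward
fewer components, so noise is not over-fitted into spurious splits.
Widths are bounded below by twice the grid step so components cannot
collapse onto single points.

Free signed fits of isotope-edited differences have a genuine
identifiability problem: a +/− pair of strongly overlapped bands is
nearly indistinguishable from a closer, taller pair (to first order the
difference signal is amplitude × separation × the band derivative).
Profiling the residual sum of squares against an imposed shift on
noise-free data shows the surface is almost flat on the low-shift side at
realistic noise. Two design responses:

* **Assignment windows.** When initial components are supplied (band
  assignments are made a priori in this field), each center is bounded
  within ±4 cm^-1^ of its assigned value — the instrument resolution at
  which positions are read — each amplitude keeps its assigned sign
  within a factor of 3, and each width stays within a factor of 2.
* **The tied isotope-pair model** (`fit_isotope_pairs()`), used by
  `analyze_difference()` whenever a template is available. Each labeled
  band contributes a positive component and a negative partner
  constrained to *equal amplitude and width*, with one isotope shift
  shared by all pairs. This is the physics of isotope editing — the
  substitution preserves oscillator strength and bandwidth and shifts
  every labeled mode together — and it removes the shift/amplitude
  trade-off. Under the study-condition noise model (SNR ≈ 20, four
  replicate pairs) the shared-shift estimate recovers the injected 20
  cm^-1^ with a standard deviation of about 1.4 cm^-1^ and no
  pathological outliers, where the free fit's estimate was skewed and
  three times as dispersed.

`detect_splitting()` classifies the *positive* components that fall in
the minor window (1630–1700 cm^-1^): split when at least two are
separated by ≥10 cm^-1^ with the weaker at least 20% of the stronger (so
a weak shoulder still counts), and Hoogsteen-marked when additionally the
lowest split component lies at or below 1660 cm^-1^ — both
Hoogsteen-forming conditions show a ~1655 cm^-1^ component and no
Watson–Crick condition does. Considering only positive components
automatically excludes the negative heavy-side major band that overlaps
the minor window in drug-bound conditions (1710 − 20 = 1690 cm^-1^). All
thresholds are arguments.

## Solvatochromatic calibration and the harmonic shift

The carbonyl frequency falls linearly with the solvent's Gutmann
acceptor number (AN), an empirical scale of hydrogen-bond-donating
power. `fit_calibration()` fits freq = a + b·AN by ordinary least
squares; the bundled default uses only the two points printed in the
source text — d~6~-DMSO (AN 21, ~1750 cm^-1^) and water (AN 54, ~1695
cm^-1^) — because the third solvent's frequency appears only in
supplementary graphics and is never hard-coded here. With two points the
line interpolates exactly and parameter standard errors are undefined
(reported `NA`); with more points, inverse predictions carry first-order
propagated uncertainty (exact Fieller intervals are out of scope).
Inverting at the duplex frequency of 1720 cm^-1^ gives AN = 39.0 — the
published "~40", computed there from the three-point line, agrees within
the stated ±2. An AN midway between DMSO and water is the quantitative
statement that the minor-groove carbonyl feels a weak but real H-bond.

`harmonic_shift()` treats the carbonyl as a diatomic C=O oscillator:
Δν = f · ν~light~ · (1 − √(μ~12~/μ~16~)), with reduced masses from
standard isotopic masses (^12^C = 12 exactly, ^13^C = 13.00335,
^16^O = 15.9949). A fully localized stretch (f = 1) at 1720 cm^-1^
predicts a 38.3 cm^-1^ shift; the observed ~20 cm^-1^ implies a
localization fraction f ≈ 0.52, quantifying how far the real normal mode
departs from the diatomic picture.

## Interaction-energy bookkeeping

The energetics module consumes externally computed counterpoise-corrected
MP2 interaction energies and AIM bond-critical-point densities; it never
runs quantum chemistry. Energies are stored attraction-positive, matching
the published table (raw binding energies are negative).
`substitution_change()` re-derives the C–H→N control column — removing
the putative CH···O bond weakens binding by 2.2–3.8 kcal/mol across the
four A–T systems — and `summarize_controls()` reports the range plus the
maximum 90°-rotation control (1.45 → 1.5 kcal/mol), the residual
attraction attributable to the CH···O bond alone. Reporting rounds half
away from zero because base R's `round()` is half-to-even and would turn
1.45 into 1.4. `classify_hbond()` maps densities to
canonical-strength (≥0.025 au), weak, or none (≤0.002 au, a conventional
AIM existence floor the source does not state).

## Numerical and testing notes

* Fit convergence uses `minpack.lm::nls.lm` with up to 500 iterations;
  non-convergence is an error carrying the last residual RMS, never a
  silent result.
* AICc on k candidate components compares `n log(RSS/n) + 2p +
  2p(p+1)/(n−p−1)` with `p = 3k`; an RSS floor at machine precision keeps
  noise-free (exact) fits comparable.
* Test problem sizes: the 801-point default grid; four replicate pairs
  per noisy condition; 50 seeds for the isotope-shift Monte Carlo and 11
  seeds per preset (majority call) for the split/marker checks — sizes at
  which the whole suite runs in seconds while the Monte Carlo standard
  error on the shift mean is ≈0.2 cm^-1^.
* Degenerate inputs error early and specifically: mixed grids direct the
  user to `resample()`, a non-positive normalization window signals a
  missing phosphate band, noise-free SNR is reported as undefined rather
  than infinite.

## What passing tests do and do not show

The generator reproduces the band structure, replicate noise, drift, and
small center jitter of the experiment, so the pipeline's recovery
results demonstrate correctness of the analysis logic under the stated
noise model. Real ATR-FTIR data additionally contain water-vapor and
CO~2~ lines, detector nonlinearity, imperfect background subtraction,
and mode-coupling effects (the minor-band composite is modeled as one or
two independent Gaussians, not as coupled oscillators). Passing tests
therefore validate the method's arithmetic and statistics, not the
spectroscopic assignments themselves; the split-marker logic in
particular inherits the assumption that the preset band positions are
the true ones. The calibration's two-point default reproduces the
published inversion to within the stated tolerance but carries no
uncertainty estimate; users with the third solvent point (or their own)
should supply it.
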