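---
title: "Detecting cryptic UV-white polymorphism: models and methods"
author: "uvmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cryptic UV-white polymorphism: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvmorph)
```

## The problem

Ventrally white lizards can carry two spectrally distinct whites: a
UV-reflecting white whose reflectance extends across 300–700 nm, and a
UV-absorbing white that reflects only above roughly 400 nm. Human vision
(400–700 nm) cannot tell them apart, but a lizard retina with an
ultraviolet-sensitive cone can, so "white" may hide a cryptic colour
polymorphism. The package chains the three analyses this question needs:
an objective spectral classification, a receptor-noise-limited model of
what the lizard eye can discriminate, and group statistics that separate
*statistical* from *perceptual* difference.

## Spectral representation and cleaning

Spectra live in a `SpectrumSet` (a `SummarizedExperiment`): a
wavelengths-by-spectra matrix of percent reflectance with specimen
metadata per column. The canonical working grid is 300–700 nm inclusive
at 1 nm (401 samples), and all spectral summaries are **plain sums over
grid samples** — no trapezoid weighting — so that, e.g., a flat spectrum
has UV chroma 101/401, a convention that keeps the quantities exactly
countable. Instrument-native grids are preserved on input;
`resampleSpectra()` interpolates linearly and refuses to extrapolate,
because reflectance outside the measured range is simply unknown.
Negative reflectance (an instrument artefact near the white standard) is
floored at zero by default with the raw values kept in the cleaning
provenance; loess smoothing is available but **off** by default, since
the summaries below are robust to mild noise and smoothing alters
half-height positions slightly.

## Classification by R_mid

`rMid()` finds where reflectance crosses the midpoint between its
minimum and maximum inside the 300–450 nm window. Numerical choices:

* min and max are taken **within the window** by default; a
  `scope = "global"` switch takes them over the whole spectrum (the
  crossing is still sought in the window), because either reading of the
  construct is defensible and the two differ for strongly sloped
  long-wavelength spectra;
* the crossing is the **first upward** crossing, located by linear
  interpolation between the bracketing 1 nm samples (sub-grid
  precision); a spectrum already above half-height at the window start
  reports the window start;
* spectra whose in-window range is below `tol = 1e-6` percent are flat:
  R_mid is undefined (`NA`) rather than arbitrary.

`classifyWhite()` applies the boundary-inclusive thresholds: R_mid ≤ 345
nm is UV⁺white, ≥ 365 nm is UV⁻white, anything strictly between (or
undefined) is *ambiguous*. Ambiguous spectra are retained and labelled,
but excluded from the two-class statistics by default — they are rare in
well-measured material and have no principled home in a two-class
comparison.

## The visual model

Cone spectral sensitivities are Govardovskii-style A1 alpha-band
templates parameterized by peak wavelength. The shipped defaults (UVS
367, SWS 456, MWS 497, LWS 562 nm;
`inst/extdata/podarcis_a1_default.yaml`) are literature-derived values
for diurnal lacertid eyes, supplied as configuration rather than
hard-coded because measured sensitivities should replace them when
available. No ocular-media or oil-droplet filtering is applied by
default; a transmission vector hook exists.

Quantum catches are \(Q_i = \sum_\lambda R(\lambda)\,S_i(\lambda)\,
I(\lambda)\) (reflectance as a proportion), von Kries-normalized against
a perfect reflector under the same illuminant, and log-transformed. The
default illuminant is flat ("ideal"): nothing in the classification
depends on it, von Kries normalization removes its intensity entirely
(a tested invariant), and choosing a daylight standard would add a free
parameter without data to constrain it; a measured illuminant can be
supplied. Spectra with a non-positive catch in any channel are flagged
and excluded from distances, since their log-catch is undefined.

Channel noise is intensity-independent ("neural") noise,
\(\omega_i = w\sqrt{n_{\mathrm{ref}}/n_i}\) from the reference-cone Weber
fraction \(w = 0.05\) and relative cone abundances 1:1:1:4, giving
\(\omega = (0.1, 0.1, 0.1, 0.05)\). Chromatic distance uses the
tetrachromatic receptor-noise closed form over log-catch differences;
for other cone counts the equivalent weighted-least-squares form
\(\Delta S^2 = \min_x \sum_i (\Delta f_i - x)^2/\omega_i^2\) is used, and
the equality of the two on tetrachromats is asserted in the tests to
1e-9. Uniform log-catch shifts (pure intensity) yield exactly 0 JND.
Achromatic distance is \(|\Delta f_{\mathrm{ref}}|/\omega_{\mathrm{ref}}\)
on the long-wavelength channel.

## Two-step group statistics

*Step 1 — statistical.* A one-way distance-based PERMANOVA on the
pairwise chromatic JND matrix, implemented from the squared-distance
partitioning (total, within-group, between-group sums of squares;
pseudo-F with a−1 and N−a df). The permutation p-value uses the
\((1+x)/(1+n_{\mathrm{perm}})\) estimator so p is never 0 and its floor
is \(1/(n_{\mathrm{perm}}+1)\); the default is 9999 permutations. On a
Euclidean distance matrix from univariate data the pseudo-F reduces to
the classical ANOVA F (a tested limit), and the implementation is
cross-checked against an independent PERMANOVA implementation and
against exhaustive enumeration on small instances. Degenerate all-zero
distance matrices return an explicit degenerate result.

*Step 2 — perceptual.* The between-class distance that matters
perceptually is between class *centroids*: per-cone geometric means of
the normalized catches, i.e. arithmetic means of log-catches. The 95%
CI is a percentile bootstrap (default 1000 resamples), resampling
spectra with replacement within each class; percentile rather than BCa
because the estimand is a smooth functional of group means and the
plain percentile interval is the field's standard for this procedure.
The point estimate is verdict-banded: >3 JND easily discriminable, 1–3
JND discriminable only under good illumination, <1 JND below threshold.

Seeds are mandatory for every stochastic routine and are recorded in the
result objects; `runPipeline()` derives all stage seeds from one config
seed and writes an MD5 manifest, so a run is byte-reproducible.

## What the synthetic generator does and does not emulate

`simulateCohort()` draws long-pass sigmoid spectra
\(R(\lambda) = b + A/(1+e^{-(\lambda-\lambda_0)/s})\) with class-specific
midpoints: UV⁺white \(\lambda_0 \sim N(330, 5)\), UV⁻white
\(N(390, 5)\), yellow \(N(460, 8)\), orange \(N(520, 10)\) nm. The two
white means sit symmetric about the 345–365 nm gap so that, at default
noise, classes are unambiguous and the R_mid distribution is clearly
bimodal — deliberately so: the tests must attribute classification
errors to the algorithm, not to generator overlap. Remaining defaults,
chosen once as field-realistic values: slope 10 nm, baseline 5% and
amplitude 50% reflectance (white lizard venters peak near 50–60%),
a per-spectrum lognormal intensity factor (sdlog 0.05, probe-geometry
variation), additive per-wavelength noise (SD 0.5%, sensor noise),
sex ratio 0.5, 10% throat/belly class discordance (mixed ventral
patterns), 400 specimens × 2 patches.

The generator reproduces the *statistical structure* the analysis
assumes — bimodal cut-offs, locality-varying frequencies, morphs without
UV reflectance — not the physics of real skin: no pigment model, no
spectral autocorrelation in the noise, no ontogenetic change, and
midpoint variances are not calibrated to any field sample. Passing tests
therefore demonstrate that the pipeline recovers known structure of this
kind, not that any particular field estimate is correct.

## Problem sizes and numerical tolerances in the test suite

The suite exercises: closed-form/oracle agreement on 1000 random
tetrachromatic instances (tolerance 1e-9); PERMANOVA type-I error over
1000 null datasets of 16 points at 199 permutations; bootstrap CI
coverage over 500 replicates of 60-per-group cohorts at 500 resamples;
and an end-to-end 400-specimen cohort. These sizes give stable
Monte-Carlo bounds while keeping the default test run short on one CPU.

## Known limitations

* The A1 template is an alpha-band approximation; beta-bands and ocular
  media shift UVS sensitivity in real eyes.
* Only one-way PERMANOVA is provided (no strata, multi-factor designs or
  dispersion tests); mixed-effect analyses of the colorimetric variables
  are intentionally left to dedicated packages via the exported feature
  table.
* Bright-light (noise-limited) discrimination only: no dark noise or
  quantum-fluctuation terms, so JNDs at low light are overestimates of
  discriminability.
* The threshold classification is a fixed-rule classifier, not a mixture
  model; with heavily overlapping cut-off distributions the ambiguous
  class grows and the two-class statistics weaken accordingly.
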