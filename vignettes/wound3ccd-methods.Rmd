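---
title: "Spectral wound-image analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral wound-image analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wound3ccd)
```

## The problem

Traumatic extremity wounds are closed surgically after serial débridements,
and a fraction of closures fail (dehiscence or infection requiring
reoperation). Tissue oxygenation of the wound bed — driven by the balance of
oxy- and deoxyhemoglobin — shifts the red/blue balance of an ordinary RGB
photograph: deoxyhemoglobin absorbs far more strongly than oxyhemoglobin
around 610 nm, so better-oxygenated tissue reflects relatively more red.
`wound3ccd` implements an analysis chain that turns routine color
photographs of the wound bed into spectral indices and classifies wounds as
likely to heal or to dehisce.

The chain is: quality screening → region-of-interest channel statistics →
cohort normalization → a 14-variable spectral feature set → univariate and
multivariate classifiers → diagnostic statistics with permutation-based
overfitting control. A synthetic wound-image generator with a
hemoglobin-absorption optical model makes every stage testable end to end
without clinical images.

## The 14 spectral variables

From the mean R, G, B of the wound-bed ROI the package computes seven raw
indices — R, G, B, R−B, R−G, (R−B)/G and (R−B)/(R²+B²) — and the same seven
each divided by its overall cohort mean. R−B tracks oxygenation directly;
(R−B)/G and (R−B)/(R²+B²) are intensity normalizations that suppress
illumination, angle and distance variation: (R−B)/G is exactly invariant to
a uniform brightness rescaling of a single image, while (R−B)/(R²+B²)
magnifies the relative separation between darker (poorly perfused) and
brighter wound beds.

### Cohort normalization and a degeneracy worth knowing about

Images from different hospitals carry different camera gains and lighting.
The package removes them in two steps:

1. **Hospital channel normalization.** Each image's mean channels are
   divided by its hospital's mean channels and rescaled onto a fixed
   *reference tone* (defaults `r = 0.75, g = 0.60, b = 0.35`, a nominal
   well-perfused wound-bed color). Any per-channel gain common to a hospital
   cancels exactly in this ratio — for all 14 variables, which the test
   suite asserts to 10⁻¹⁰.
2. **Overall-mean normalization.** The seven raw indices (computed from the
   hospital-normalized channels) are each divided by their mean over the
   fit population, so every normalized variable averages exactly 1 there.

The reference tone deserves a note. The obvious alternative — rescaling each
hospital's channels to mean 1 — is degenerate: if every normalized channel
averages exactly 1 over the fit population, every difference composite
(R−G, R−B) averages exactly 0, and step 2 would divide by floating-point
noise. A data-derived grand mean avoids that but re-introduces a gain
dependence, because the grand mean itself moves when one hospital's gain
changes. A fixed constant is the only choice that keeps step 2 well-defined
*and* the gain cancellation exact; its actual value only sets the scale of
the raw variables and cancels out of the normalized ones.

Within model evaluation the reference is fit on the training split only and
applied to the validation split (`normalize_scope = "train"`), the leak-free
default; `"all"` reproduces pre-split normalization.

### The 1.00 threshold rule

The univariate baseline classifies a wound as dehisced when normalized
(R−B)/(R²+B²) ≥ 1.00. The cutoff is only meaningful on the normalized
scale, where the variable averages 1 by construction — poorly perfused
(darker) wound beds sit above the cohort mean, well-perfused ones below it.

## Quality screening

Three per-ROI checks, all configurable via `qc_thresholds()`:

| check | statistic | default rule |
|---|---|---|
| glare | fraction of pixels with any channel ≥ 250/255 | ≤ 0.05 |
| focus | variance of a 3×3 Laplacian of luminance (R+G+B)/3 | ≥ 10⁻⁴ |
| blood | fraction of pixels with R − max(G, B) > 0.25 | ≤ 0.50 |

The Laplacian-variance floor is a standard focus measure: defocus removes
high spatial frequencies, so the Laplacian response of a blurred image
collapses toward zero. The blood rule flags strong red dominance; the
detection threshold (0.25) is well above the red dominance of a clean wound
bed but well below that of frank blood pooling.

## Classifiers

### PLSDA

The discriminant model is PLS1 regression of a centered 0/1 class dummy on
autoscaled predictors, computed by NIPALS with deflation; the regression
vector is `b = W (PᵀW)⁻¹ q`. Autoscaling is the standard chemometrics
choice for predictors with mixed units (cm², days, years, unitless
indices). Identities the implementation is tested against: with one
predictor or at full rank, PLS fitted values equal ordinary least squares;
component scores are mutually orthogonal; the first latent variable matches
an independent PLS implementation (mixOmics) exactly up to sign.

The latent-variable count `A` can be fixed or chosen by stratified
cross-validation (`A = "auto"`, capped at 10, ties to the smaller model).
Prediction thresholds the predicted dummy at 0.5 by default. The
alternative `threshold = "prevalence"` places the cut at the training
positive rate — a sensitivity-seeking operating point analogous to the
Bayesian threshold used by commercial PLSDA tools. The distinction matters:
at 20% prevalence a 0.5 cut is conservative (the model rarely calls the
positive class and accuracy hugs the majority rate), while the prevalence
cut trades false positives for sensitivity.

### The sequential two-stage classifier

Wounds that heal only after day 21 ("delayed healing") resemble dehisced
wounds spectrally but are healed outcomes. The two-stage model handles
them explicitly:

* **Stage 1** — PLSDA of *delayed vs not-delayed* on all training rows.
* **Stage 2** — PLSDA of *healed vs dehisced*, trained only on rows whose
  true label is not delayed (`route_by = "truth"`; routing by stage-1
  predictions is available as `"prediction"`).
* **Prediction** — a sample called delayed by stage 1 is labeled healed and
  never reaches stage 2; otherwise stage 2's verdict is final. The final
  label space is exactly {healed, dehisced}.

When is this better than one flat PLSDA of dehisced-versus-rest? When the
delayed class overlaps the dehisced class in the spectral coordinates but is
separable on temporal ones. A flat linear model then either calls the whole
low-oxygenation cloud positive (false positives on every delayed image) or
goes conservative (missing the dehisced class); the sequential model removes
delayed wounds on their débridement-day signature first and applies a clean
spectral rule to what remains. The generator preset
`cohort_config_confounded()` constructs exactly this situation, and the test
suite requires the sequential model to match or beat the flat one in at
least 16 of 20 seeded replicates at the prevalence threshold. At the 0.5
threshold both models collapse toward majority-rate behavior and the
comparison is uninformative — one reason flat-model accuracy below the
majority rate in practice points to an aggressive threshold.

### Permutation overfitting control

The permutation test refits the identical modeling recipe on label-shuffled
data: `p = (1 + #{permuted ≥ observed}) / (1 + n_perm)`, with the
cross-validated accuracy as the score. The +1 correction keeps p strictly
positive; 200 permutations resolve p down to 0.005. A recipe that fails on
a shuffled draw (a fold losing a class) is retried up to three times and
then counted as performing at least as well as the observed model — a
conservative choice that can only inflate p. Under a true null the test is
calibrated: the suite checks a rejection rate ≤ 0.07 at α = 0.05 over 200
null datasets.

## Diagnostics

Sensitivity, specificity and accuracy follow their defining proportions
with dehisced as the positive class. The diagnostic odds ratio is
(TP·TN)/(FP·FN) with the Woolf (log-scale) 95% interval
`exp(log DOR ± 1.96 √(1/TP + 1/FN + 1/FP + 1/TN))`; zero cells take the
Haldane–Anscombe +0.5 correction when enabled. Reported percentages round
half away from zero. `enumerate_consistent_confusions()` inverts printed
(sensitivity, specificity, accuracy) triples back to the integer confusion
matrices consistent with them — useful for auditing published figures, and
the basis of the package's worked example, where the printed triple
76.9/76.5/76.6 at n = 64 and ~20% prevalence identifies the unique matrix
(TP 10, FN 3, FP 12, TN 39) and reproduces the printed interval 2.6–45.9.

Group comparisons (healed vs dehisced, with delayed counted as healed) use
the Mann–Whitney U test — exact when `n_x·n_y ≤ 400` without ties, normal
approximation with tie and continuity correction otherwise — with
Benjamini–Hochberg adjustment across the variable set. The chi-squared test
for cohort dehiscence rates is Pearson's without continuity correction.
Where the underlying publication names only a method family ("false
discovery rate", "chi-squared"), these concrete variants are this package's
documented choices.

## The synthetic cohort generator

`sample_cohort()` emulates the structure the analysis assumes:

* **Optics.** Wound-bed reflectance is Beer–Lambert:
  `I_c = gain_c · L_c · exp(−(s·ε_oxy,c + (1−s)·ε_deoxy,c) · c_Hb)` with
  StO₂ `s`. The extinction table (`optical_params()`) is an *effective*
  parameterization — deliberately approximate, with deoxyhemoglobin
  absorbing more in every channel and overwhelmingly so in red — chosen so
  that R−B increases strictly with StO₂ while (R−B)/(R²+B²) decreases
  (darker, poorly oxygenated beds score higher on the normalized ratio).
  It is not a spectroscopic tabulation and supports no absolute
  quantitation.
* **Cohort structure.** Patients (default 66, split ~73/27 between two
  hospitals with different camera gains) carry ~1.45 wounds each; wounds are
  débrided every ~15/`debridements_mean` days until closure, so longer-open
  wounds contribute more, and later, images (~280 images total). Outcomes
  are assigned at the wound level — every image of a wound shares its
  outcome — with exact class counts by largest remainder (healed 0.55,
  delayed 0.25, dehisced 0.20). Closure days: healed ≈ day 15 (by 21),
  delayed > 21 (≈ 28), dehisced ≈ day 11 by default (premature closure
  preceding failure).
* **Per-class StO₂.** Healed 0.75, delayed 0.62, dehisced 0.45 (wound-level
  spread 0.08), drifting up for healing wounds and down for dehiscing ones
  across débridements. These effect sizes are free parameters of the
  generator — the clinical literature does not quantify them — and are the
  package's definition of "medium separation".
* **Artifacts.** Glare (saturated discs), blur (Gaussian), blood (dark-red
  patches) injected at 4% each by default, with severities chosen to fail
  the corresponding QC rule.

What the generator does *not* emulate: real wound-bed texture and geometry,
specular color structure, myoglobin, camera spectral response curves, or
any correlation between covariates (age, wound area) and outcome. Passing
tests therefore demonstrate that the pipeline recovers planted structure of
the kind the optical argument predicts — not that real wounds are
classifiable at any particular accuracy.

## Numerical and procedural choices

* Images are analyzed on their stored (gamma-encoded) 8-bit values scaled
  to [0, 1]; no linearization, matching consumer-camera processing.
* Zero denominators in ratio indices propagate as missing values; rows with
  missing predictors are dropped from modeling with a logged count.
* The split is by image (each débridement an independent observation),
  stratified on the three-class outcome, preserving prevalence to within
  one sample per class; all randomness flows from named seeds and every
  pipeline output is written atomically, so a re-run is byte-identical.
* Test problem sizes: simulation-based properties run on 32-px fast-path
  cohorts (channel means drawn directly from the optical model) of ~280
  images, 10–20 seeds, 39–99 permutations; the acceptance script renders a
  64-px cohort end to end. These sizes are the package's chosen balance of
  statistical resolution against suite runtime.

## Known limitations

* PLS1 with a hard threshold has no probability calibration; the
  prevalence threshold is a crude stand-in for a full Bayesian decision
  rule.
* The hospital normalization assumes a multiplicative, channel-wise camera
  model; vignetting, white-balance drift within a hospital, or nonlinear
  tone curves are not corrected.
* With few wounds per hospital the hospital mean is itself noisy; that
  sampling error is shared by all images of the hospital and is not
  removed by normalization.
* Delayed-versus-not separation rests on débridement timing; in settings
  where imaging schedules do not reflect healing progress, stage 1 has
  nothing to work with.
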