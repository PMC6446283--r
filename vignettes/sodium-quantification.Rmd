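---
title: "Quantifying tissue sodium concentration and its test-retest reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tissue sodium concentration and its test-retest reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natsc)
```

## The quantification model

Sodium (^23^Na) MRI measures a signal proportional to the total sodium
content of each voxel, but the proportionality constant depends on
relaxation. `natsc` converts the measured signal into tissue sodium
concentration (TSC, mmol/kg wet weight) by referencing it against an
external tube of known NaCl concentration imaged in the same field of view:

$$
[\mathrm{Na}]_{tiss} \;=\; \frac{S_{tiss}}{S_{ref}}\,[\mathrm{Na}]_{ref}
\times
\frac{1-e^{-TR/T_1^{ref}}}{1-e^{-TR/T_1^{tiss}}}
\times
\frac{\alpha_r\,e^{-TE/T_{2f}^{ref}} + \beta_r\,e^{-TE/T_{2s}^{ref}}}
     {\alpha_t\,e^{-TE/T_{2f}^{tiss}} + \beta_t\,e^{-TE/T_{2s}^{tiss}}}.
$$

The first fraction corrects for incomplete longitudinal recovery at the
repetition time TR (`saturation_factor()`), the second for transverse decay
at the echo time TE (`te_decay()`). Sodium in tissue relaxes
*biexponentially* — quadrupolar interactions split the transverse decay into
a fast component (weight $\alpha$) and a slow component (weight $\beta$,
$\alpha + \beta = 1$) — while free fluid such as CSF decays
monoexponentially ($\alpha = 0$). With a short TE (0.2 ms) and a TR (120 ms)
long relative to the tissue T1 values, the whole correction is a number
close to 1:

```{r}
lib <- default_compartments()
acq <- acquisition_spec()      # TR 120 ms, TE 0.2 ms, 3.6 mm voxels
correction_factor(lib$entries$GM$relax, lib$reference$relax, acq)
correction_factor(lib$entries$CSF$relax, lib$reference$relax, acq)
```

### Compartment constants

All constants live in a single YAML config
(`system.file("extdata", "default_config.yaml", package = "natsc")`), nested
by region name. The shipped defaults: brain tissue
$T_{2f}/T_{2s} = 4/29$ ms with weights $0.6/0.4$ and $T_1 = 29$ ms; CSF
$T_{2s} = 55$ ms, monoexponential, $T_1 = 58.1$ ms; reference tube
$T_{2f}/T_{2s} = 7.15/33.7$ ms. Two constants are *not* measured values and
are flagged as assumptions wherever they appear:

* **Reference T1 = 35 ms** — typical for aqueous NaCl solutions at 3 T; a
  required config field with a documented default.
* **Reference concentration 102.67 mmol/L** — derived from the 0.6 % NaCl
  filling: 6 g/L ÷ 58.44 g/mol.

### Reference decay weights

A formula with a single $\alpha/\beta$ pair in numerator and denominator is
ambiguous once compartments with different weights are involved. `natsc`
defaults to each compartment using *its own* weights
(`ref_weights = "reference"`, with the reference tube at $0.6/0.4$ — the
biexponential character its configured $T_{2f} \ne T_{2s}$ pair implies). For
every brain-tissue region this is numerically identical to sharing one pair,
because the brain weights equal the reference weights. It matters only for
CSF: forcing the tissue's monoexponential weights onto a physically
biexponential reference (`ref_weights = "tissue"`, also available) would
mis-scale the reference decay by about 1.3 % at TE = 0.2 ms and break the
round-trip consistency between the forward simulator and the quantifier.
The self-consistent convention is the default; the shared-pair reading
remains available for sensitivity analysis.

## The synthetic cohort

No scanner data ship with the package. The `phantom_sim` layer builds a
digital head phantom and emulates the study design end to end, with known
ground truth:

* **Geometry** — a head/GM ellipsoid with a WM core, bilateral caudate-head
  spheres, a midline pons, bilateral cerebellum spheres, bilateral ventricle
  (CSF) ellipsoids, and an external reference cylinder, rasterised at 1 mm.
  Structures are sized so every default landmark sits at least the ROI
  half-extent plus 3 PSF sigma inside its region core; the grid origin is
  aligned so both grids place voxel centres exactly on the midline, making
  left/right sampling mirror-symmetric (a left/right difference of zero is
  measured as exactly zero).
* **Signal formation** — per-voxel noiseless signal is
  gain × concentration × saturation × decay; partial volume is modelled at
  image level by an isotropic Gaussian PSF of FWHM one sodium voxel
  (3.6 mm) followed by sampling at the sodium-grid voxel centres. Because an
  isotropic Gaussian commutes with rigid motion, the blur is precomputed
  once per phantom (per-label indicator volumes, `phantom_cache()`) and each
  session only re-samples it under its own repositioning — exactly
  equivalent to displacing first and blurring afterwards, and far cheaper
  across a cohort.
* **Study design** — visits V1/V2 on the same day and V3 after an 8-day
  interval; a subject's regional concentrations are drawn once
  (Normal around the config means with the config between-subject SDs,
  e.g. GM 51.5 ± 4.5 mmol/kg WW) and shared by all visits; visits differ
  only by session effects.
* **Session effects and noise** — gain drift uniform in ±2 %, repositioning
  uniform in ±2 mm / ±2°, and Rician noise (the magnitude-reconstruction
  noise model; sigma 2.0 signal units by default, about SNR 20 in brain
  tissue). These are simulator choices, not measured values: the study
  reports no SNR, so the noise level is a calibration-free default chosen
  to land in the regime where test-retest correlation is high but not
  degenerate.
* **Reader behaviour** — each reader re-places every ROI with an in-plane
  Normal jitter (SD 1 mm by default), deterministically per
  (reader, subject, visit, region, side).
* **Reproducibility** — one master seed; every draw uses a sub-seed derived
  by hashing the seed with a context key (`derive_seed()`), so adding
  subjects or visits never reshuffles existing sessions.

What the generator does *not* emulate: real anatomy (no atlas, no cortical
folding), k-space acquisition and radial reconstruction artifacts, coil
sensitivity and B0/B1 inhomogeneity, flip-angle/steady-state effects,
registration *estimation* error (the pipeline applies known transforms), or
systematic inter-reader bias (jitter is zero-mean, so reader disagreement in
the synthetic cohort is purely random). Passing tests therefore demonstrate
the correctness of the quantification arithmetic, the ROI machinery and the
statistics under a controlled forward model — not robustness to everything
a scanner can do.

## The ROI protocol

Measurements use identically-sized circular ROIs (0.508 cm², radius
≈ 4.02 mm) replicated on three consecutive slices at nine predetermined
landmarks (bilateral GM, WM, caudate head, cerebellum; midline pons), plus
bilateral CSF and the reference tube. ROI geometry is defined in world
millimetres and re-rasterised on the sodium grid — the grids differ (1 mm
vs 3.6 mm), so index-copying is not meaningful. A voxel belongs to the ROI
iff its centre lies inside the disc; at a volume edge the three-slice stack
shifts inward. Each session's known repositioning is applied to the ROI
centres so the ROI tracks the anatomy, mirroring co-registered reading.

```{r}
cohort <- simulate_cohort(n_subjects = 2, seed = 42, visits = c("V1", "V2"))
meas <- measure_all(cohort)
head(meas[meas$reader == "R1", ], 4)
```

## The statistical battery

`summarize_cohort()` reproduces the shape of a test-retest study report:
per-region visit comparisons (repeatability V1–V2, reproducibility V1–V3),
pooled Pearson r², per-region inter-individual fluctuation
(`max_pct_diff()`), laterality, inter-reader Spearman rho, Bland–Altman
limits on the reader ratio, and normality. Several design choices deserve
justification:

* **Paired visit comparisons** are subject-paired sign-flip permutation
  tests with $|\bar d|$ as the statistic — exact enumeration of all $2^n$
  sign patterns for $n \le 14$, seeded Monte-Carlo beyond. This replaces a
  repeated-measures ANOVA with contrast-vs-baseline testing by a
  distribution-free equivalent; a joint max-|t| version over all follow-up
  visits (`visit_maxt_test()`, permuting visit labels within subject) covers
  the family-wise reading. $|\bar d|$ rather than $t$ keeps the statistic
  finite on constant shifts and makes identical data give exactly p = 1.
* **Laterality** is the same paired sign-flip test on left-minus-right
  values. A chi-squared test is not meaningful for paired continuous
  concentrations, so none is offered.
* **Fluctuation denominator**: the maximum percentage difference is
  $100\,(\max-\min)/\max$. This convention reproduces all five healthy-cohort
  worked examples of the statistic (e.g. 65.4/42.4 mmol/kg WW giving 35.1 %) within 0.2 percentage points, which is
  how it was selected (and is frozen in a fixture test).
* **Reader handling**: readers (and sides) are averaged within
  (subject, visit, region) before any across-subject statistic; inter-reader
  statistics are computed before averaging, on matched
  (subject, visit, region, side) pairs.
* **The pooled "Mean" row** displays mean ± SD over all (subject, region)
  values, but its p-value pairs *subjects* (each subject's regions are
  averaged first): the regions of one subject share session effects, so
  sign-flipping (subject, region) pairs as if independent overstates
  significance.
* **Normality** uses the Kolmogorov–Smirnov distance against a normal with
  estimated mean/SD; since parameters are estimated, the p-value comes from
  a seeded Lilliefors-style Monte-Carlo null (2000 draws), not the naive KS
  distribution.
* **No multiplicity correction** is applied across regions, matching the
  reporting style the battery mirrors; the max-|t| family test is the
  corrected alternative where one is wanted.

```{r}
report <- summarize_cohort(meas, n_perm = 1000, seed = 1)
report$fluctuation
```

## Numerical choices and degenerate inputs

* Times are milliseconds, lengths millimetres, concentrations mmol/kg wet
  weight (tissue) and mmol/L (reference), treated as numerically
  interchangeable for calibration.
* Volumes use 0-based world-voxel conventions internally presented as R's
  1-based indices; voxel centres address world coordinates; only
  axis-aligned geometry is supported and oblique NIfTI headers are rejected
  explicitly rather than reinterpreted.
* Resampling is trilinear by default (nearest-neighbour available); nothing
  else is offered. Out-of-field voxels take a declared fill value.
* Sign-flip p-values compare permuted statistics with a relative tolerance
  of $10^{-12}$ so that exact ties (degenerate data) count as exceedances;
  identical visits give p = 1 by construction.
* Zero-variance inputs to correlations raise explicit errors at the
  function level; the report summarizer converts them to `NA` fields so a
  degenerate cohort still yields a complete report.
* ROI masks must fit inside the field of view; the offending landmark is
  named in the error. An ROI of one voxel footprint is valid.

## Problem sizes

The shipped test-suite and the acceptance script exercise: noiseless
recovery on 3–12 subjects (every region within 1 % of truth; observed
maximum error is below 0.1 %), noisy recovery on 50 single-visit subjects at
SNR ≈ 20 (region-mean bias well under the 3 % contract), type-I error of the
permutation tests on 1000 simulated null cohorts of n = 12, and the full
default cohort (12 subjects × 3 visits × 2 readers = 792 measurements).
These sizes were chosen so the whole battery runs in minutes on a single
CPU while keeping Monte-Carlo standard errors small relative to the
tolerances they check.

## Known limitations

* The digital phantom's partial-volume model (Gaussian PSF + sampling) is a
  stand-in for radial k-space reconstruction; absolute partial-volume
  severity in real data will differ.
* The reference-T1 default and the noise level are assumptions; both are
  single config fields and should be set from phantom measurements when
  real data are analysed.
* Only rigid, axis-aligned geometry is supported; registration must be
  performed (or known) upstream.
* With zero-mean reader jitter the synthetic inter-reader correlation is
  optimistic compared to human readers, who disagree systematically as well
  as randomly.
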