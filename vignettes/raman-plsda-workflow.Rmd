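---
title: "A chemometric PLS-DA workflow for dried-droplet Raman spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A chemometric PLS-DA workflow for dried-droplet Raman spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ramanpcad)
library(dplyr)
```

## The problem

Raman spectroscopy of dried biofluid droplets is a label-free way to probe
the molecular composition of cerebrospinal fluid (CSF). Solutes concentrate
at the rim of a dried droplet (the coffee-ring effect), where repeated
acquisitions give a strong fingerprint-region signal. The question this
package addresses is whether such spectra can separate cognitively normal
individuals with abnormal Alzheimer biomarkers (preclinical AD, "PC") from
healthy controls ("H"), and *which wavenumbers carry the discrimination*.

The differences between the two classes are far smaller than the
between-patient, between-replicate and between-cohort variation, so the
analysis stands or falls with its chemometric pipeline:

1. **Preprocessing** per spectrum: Savitzky–Golay smoothing, baseline
   subtraction with an asymmetric-least-squares Whittaker smoother, and
   standard normal variate (SNV) scaling, followed by averaging the
   replicates of each patient into one representative spectrum.
2. **Feature extraction**: iterative backward elimination of wavenumbers
   driven jointly by VIP (variable importance in projection) and the
   selectivity ratio, with cross-validated RMSECV as the objective.
3. **Classification**: PLS-DA (NIPALS PLS1 on a 0/1-coded class label with a
   decision threshold), tuned and evaluated by repeated random-subset
   cross-validation.
4. **Validation**: jackknife stability selection with frequency
   thresholding, and permutation tests of the final models.

Because the original patient data are not publicly distributable, the
package ships a synthetic-spectrum generator that reproduces the *structure*
of the study — two cohorts of 40 and 35 patients (20 H + 20 PC and
20 H + 15 PC), 15 replicate spectra per patient, class-discriminative bands
at known wavenumbers, cohort batch effects — so every stage is testable end
to end with known ground truth.

## The synthetic study

`generate_study()` draws pseudo-Voigt bands (50/50 Gaussian–Lorentzian, a
conventional approximation of Raman line shapes) on a 600–1800 cm⁻¹ grid at
1 cm⁻¹ by default. The amplitude of band $k$ for a spectrum of patient $i$
is

$$A_k \,(1 + c_k\,[\text{PC}])\,(1 + b_k\,[\text{cohort 2}])\,(1 + u_i),$$

with $c_k$ the class effect, $b_k$ the batch effect, and
$u_i \sim N(0, \sigma_\text{patient})$ a per-patient amplitude effect shared
by all of that patient's replicates — this is what makes replicate averaging
statistically meaningful. On top of the bands come a smooth random
polynomial baseline (degree 3), a lognormal per-spectrum multiplicative
scatter factor, and additive Gaussian noise; intensities are clipped at
zero. Noise is added *after* the scatter so that SNV can remove the scatter
and Savitzky–Golay the noise — each preprocessing stage has something real
to do.

The default planted discriminative bands sit at 727, 956, 1045 and
1065 cm⁻¹ with a +30 % amplitude effect in the PC class; together with the
default per-patient amplitude sd of 0.1 this gives a within-class
coefficient of variation of roughly 10 % at those bands. Thirteen filler
bands are non-discriminative, four of which carry a +20 % cohort-2 batch
effect, so batch structure exists without being confounded with class.
Defaults we had to choose ourselves (the spectral grid, band widths of
~12 cm⁻¹ FWHM, noise scales) are stated once here and were fixed before
use; none is a measured property of the real cohorts.

```{r generate}
cfg <- synth_config(grid_step = 6, replicates_per_patient = 3)
spectra <- generate_study(cfg)
dim(spectra)
```

What the generator does **not** emulate: droplet-drying physics and spatial
coffee-ring gradients, cosmic-ray spikes, wavenumber miscalibration between
sessions, and the real cohorts' absolute intensities. Passing tests
therefore demonstrate that the pipeline recovers structure it is designed to
recover, under noise of the assumed form — not that the real CSF
classification replicates.

## Preprocessing

```{r preprocess}
patients <- spectra |>
  preprocess_spectra(preprocess_config()) |>
  average_per_patient()
nrow(patients)
```

The stage order is fixed: smoothing, then baseline subtraction, then SNV.
The order matters — SNV before baseline removal would scale baseline
curvature into the signal — and is enforced by `preprocess_spectra()`;
permuting stages is only possible by calling the stage functions directly.

* **Savitzky–Golay** (window 11 points, polynomial order 3). At 1 cm⁻¹
  sampling an 11-point window denoises without flattening ~10 cm⁻¹ bands.
  Boundary points are handled by the polynomial fit itself, so polynomials
  up to the filter order are reproduced exactly everywhere.
* **Whittaker/AsLS baseline** ($\lambda = 10^5$, $p = 0.01$, second-order
  differences, 20 reweighting iterations). The smoother solves
  $(W + \lambda D_2^\top D_2)\,z = W x$ and resets weights to $p$ above the
  baseline and $1-p$ below, which pushes $z$ underneath the peaks.
  Constants and straight lines are in the penalty's null space and are
  reproduced exactly; the corrected spectrum $x - z$ may be negative and is
  not clipped. Non-convergence within `maxiter` returns the current
  baseline with a warning.
* **SNV** divides the centered spectrum by its sample standard deviation
  (ddof = 1 by default, configurable because conventions differ). A
  zero-variance spectrum is an error naming the offending
  patient/replicate; spectra whose variance is entirely absorbed by the
  baseline fit (featureless inputs) are reported the same way rather than
  having solver round-off scaled up to unit variance.

## PLS-DA and cross-validation

`fit_plsda()` codes H = 0, PC = 1, mean-centers the patient spectra (no
autoscaling — they are already SNV-scaled) and runs NIPALS PLS1 with
deflation. Classification applies a threshold (default 0.5) to the
predicted response; a prediction exactly at the threshold goes to H, a fixed
and documented tie-break.

```{r plsda}
fit <- fit_plsda(patients, n_lv = 3)
fit
glance(fit)
```

Model tuning and evaluation use repeated random-subset cross-validation:
the patients are partitioned into 15 stratified random subsets, each held
out once, and the partitioning is repeated 5 times (defaults). RMSECV pools
squared errors over all iterations; metrics (rank-statistic AUC with midrank
tie correction, accuracy, sensitivity, specificity; positive class PC) are
computed from the pooled cross-validated predictions, with per-iteration
metrics also reported. `select_n_lvs()` picks the RMSECV argmin over
candidate LV counts, breaking ties toward fewer LVs.

```{r cv}
cvres <- cross_validate(patients, n_lv = 3,
                        cv_config(n_subsets = 15, n_iterations = 5, seed = 7))
glance(cvres)
```

The partitions are functions of the CV seed alone, so results are exactly
reproducible; a partition that would leave a training split without both
classes is redrawn (bounded retries).

## Variable selection

`vip_scores()` implements the standard VIP
($\mathrm{VIP}_j^2$ averages to 1 by construction) and
`selectivity_ratio()` the target-projection SR: the centered training
matrix is projected onto $b/\lVert b \rVert$ and SR$_j$ is the
explained-to-residual variance ratio of column $j$ (zero-residual columns
are capped at a large sentinel and flagged). Neither formula is printed in
the source study; we adopt the standard literature definitions.

How the two scores are *integrated* was genuinely open; we use the
elementwise sum of the VIP ranks and SR ranks, a symmetric and scale-free
rule, and drop the worst 10 % of current variables per step (at least one).
Elimination stops when a step's RMSECV exceeds the best seen by more than
1 % relative, or at the `min_variables` floor; the returned subset is the
trajectory's RMSECV minimum. Within one elimination the same CV partitions
are reused at every step, so the RMSECV comparison across steps is not
confounded by partition noise.

```{r varsel}
sel <- iterative_selection(patients, cv_config(5, 2, seed = 11),
                           min_variables = 10, max_lv = 6)
sel
```

`stability_selection()` repeats the whole selection (by default) 100 times,
each time excluding 5 randomly chosen patients per class, and counts how
often each wavenumber survives; `threshold_scan()` then fits and
cross-validates one model per frequency threshold and reports the
accuracy-optimal threshold (ties toward the larger threshold, i.e. fewer
variables). Thresholds beyond the iteration count are allowed and come back
as empty rows rather than errors, so a fixed grid can be reused across runs
with different iteration counts. Whether the LV count is re-tuned inside
every jackknife iteration was not specified in the source; we re-tune, since
each iteration repeats "the same cross-validation structure".

## The experiment matrix and its report

`run_full_pipeline()` assembles the full experiment: per-cohort models, the
pooled two-cohort model, a model restricted to the wavenumbers common to all
three selections, and the frequency-threshold model — five report rows with
matrix shape (e.g. `40 × 93`), AUC, accuracy, sensitivity, specificity, LV
count and variable count, plus LV1/LV2 score tables and a JSON manifest of
every seed and parameter sufficient to replay the run bit-identically.

Variable selection runs once on the full patient table and the selected
subset is then cross-validated; this mirrors the source procedure but is
optimistically biased, since the held-out folds participated in selection.
The caveat is documented rather than silently "fixed" because the report's
purpose is structural comparison between arms under one shared protocol;
for unbiased error estimates the selection would have to be nested inside
every CV training split.

Permutation tests (`permutation_test()`) re-run the *entire*
cross-validation under label permutations and report
$p = (1 + \#\{\text{null} \ge \text{observed}\})/(n_\text{perm}+1)$.

## Numerical choices and degenerate inputs

* NIPALS over SIMPLS: for a single response they coincide up to scaling and
  NIPALS is the most transparent reference implementation. Scores are
  orthogonal to solver precision; the collapsed regression vector
  $b = W(P^\top W)^{-1} q$ reproduces factor-wise prediction to ~1e-10.
* A weight vector with zero norm (response orthogonal to every column)
  aborts with the component index; zero-variance responses abort.
* LV counts are capped at what the smallest training split supports; folds
  too small for the requested count carry the last feasible component
  forward.
* Selection-frequency counts, CV partitions, jackknife holdouts and
  permutations all derive their seeds from one master seed via a fixed
  derivation, so independent stages are decoupled yet reproducible.

## Problem sizes used by the test suite

The automated tests exercise reduced versions of the study design, chosen
as the smallest sizes at which each property is meaningfully testable: a
6 cm⁻¹ grid (201 variables) and single-cohort 20 + 20 patient tables for
recovery simulations; 25 jackknife iterations (instead of 100) for
stability checks, with a 15-subset CV; and a 20-patient, 15-replicate
two-cohort study for the structural pipeline run. Planted-band recovery is
scored by proximity (a selected wavenumber within one grid step of a
planted center), since on coarse grids the centers need not be grid points
and a band spans several channels.

## Limitations

* The generator's noise model is additive-Gaussian-after-scatter; detector
  artifacts, spikes and wavelength drift are out of scope.
* The selection-then-CV protocol overstates absolute performance (see
  above); reported metrics are for comparing arms, not clinical claims.
* Binary classification only (H vs PC); no multi-class extension, kernel
  PLS, or orthogonal signal correction.
* With strong batch effects, wavenumbers common to all per-cohort
  selections can collapse to a small, weakly discriminative set — the
  frequency-threshold model is the intended remedy, and the package
  reproduces that qualitative contrast on synthetic data.
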