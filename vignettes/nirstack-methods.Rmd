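---
title: "Wavelength selection and stacked calibration for Vis-NIR spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelength selection and stacked calibration for Vis-NIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Organic fertilizers are routinely characterized by their nitrogen (N) and
organic-matter (OM) content. Wet-chemistry reference methods are accurate but
slow; visible/near-infrared reflectance spectroscopy (Vis-NIR, 350-2500 nm)
offers a fast, non-destructive alternative, at the price of a multivariate
calibration problem: 2151 strongly collinear reflectance channels, broad
overlapping absorption bands, and baseline shifts driven by loading density
and particle size. `nirstack` implements a two-stage approach:

1. **Wavelength selection.** A binary particle swarm searches the space of
   channel subsets. The fitness of a subset is the cross-validated accuracy
   of a *stacked-generalization classifier* (called FSGC here) that predicts
   the fertilizer variety from the masked spectra, traded off against subset
   size.
2. **Calibration.** On the selected channels, a *stacked-generalization
   regressor* (SSGR) predicts N and OM jointly, and is benchmarked against
   multi-output ridge, SVR, and PLS with 3, 6 and 9 latent variables.

The variety label is used as a selection signal because channels that
discriminate the nine commercial varieties track the constituents —
protein/N-H features, O-H and C=O structure of organic matter — that also
carry the concentration information.

## Stacked generalization

Both stacks are classical Wolpert stacking. Given base learners
$f_1, \dots, f_B$ and internal folds $K$ (default 5), each base learner is
fit $K$ times on $K-1$ folds and predicts the held-out fold, producing
out-of-fold meta-features for every training row; the meta learner is
trained on those; the base learners are then refit on all rows for
prediction. No row's meta-feature is ever produced by a model that saw that
row, which is what lets the meta learner weight base models without
overfitting.

* **FSGC (classifier).** Base members SVM (RBF, $C = 1$, $\gamma = 0.01$),
  1-nearest-neighbour, L2-penalized multinomial logistic regression
  ($C = 100$), and a ridge classifier (one-hot ridge least squares,
  $\lambda = 0.1$) — the four survivors of an accuracy/time screen over
  seven candidate families (random forest, Gaussian naive Bayes and MLP are
  implemented as screening candidates). Meta-features are class-probability
  vectors (vote fractions for the SVM, softmax-mapped scores for the ridge
  classifier); the meta learner is the penalized logistic regression.
* **SSGR (regressor).** Same membership except logistic regression — defined
  only for categorical outcomes — is replaced by an MLP regressor, giving
  SVR, KNN, MLP, ridge with a multi-output ridge meta learner. Base
  regressors without native multi-output support (SVR, MLP) are wrapped
  per-target; the meta learner sees all base predictions for both targets
  jointly.

Hyperparameters above are the tuned values reported for this calibration
problem and are the package defaults; `grid_search_cv()` re-tunes any family.
The MLP hidden layout is the one deliberate departure: the `nnet` backend is
single-hidden-layer with logistic activation, so the package defaults to 16
hidden units, `decay = 1e-4`, `maxit = 500`, scaled targets. This is a
pragmatic substitute for a deep sklearn-style layout and is configurable.

## Binary PSO

Particles are bit-strings over channels (1 = selected). Velocities are real
vectors updated as

$$v \leftarrow w v + c_1 q (x^{pb} - x)/\Delta t + c_2 r (x^{sb} - x)/\Delta t$$

with inertia $w$, cognitive/social constants $c_1, c_2$, and fresh uniform
draws $q, r$ per particle per iteration (scalars by default; per-coordinate
draws are a flag). Positions are resampled through the logistic transfer
function $S(v) = 1/(1+e^{-v})$: bit $j$ becomes 1 with probability
$S(v_j)$. Personal and global bests use strict improvement, so the
best-so-far fitness history is non-decreasing; a stagnation escape re-draws
velocities and re-disperses positions around the personal and global bests
(probabilities 0.25/0.25/0.5 for personal best / global best / random bit)
when velocities saturate while position diversity collapses below 1% mean
pairwise Hamming distance. All-zero positions are repaired (one re-draw,
then the highest-$S(v)$ bit is forced), since an empty wavelength set has no
defined fitness ($-\infty$).

The subset fitness is
$J = \alpha P + (1-\alpha)(1 - N_f/N_t)$,
where $P$ is the CV accuracy of the classifier on the masked channels,
$N_f$ the selected count and $N_t$ the total. $\alpha = 0.5$, 50 particles
and 10 iterations are the tuned defaults.

Choices the original method description leaves open, decided here:

* **Transfer-function sign.** The printed form $1/(1+e^{v})$ is decreasing,
  which would make high velocity *suppress* selection and contradicts both
  the cited binary-PSO convention and the premature-convergence discussion;
  the standard increasing logistic is the default and
  `paper_literal_sigmoid = TRUE` restores the printed form.
* **Kinematics.** $w = 0.9$, $c_1 = c_2 = 2$, $\Delta t = 1$,
  $v_{\max} = 6$ — common binary-PSO settings, all configurable.
* **Convergence test.** The stagnation trigger (velocity saturation plus
  diversity collapse) is a reconstruction; the original description appeals to a
  criterion it never states.

## Synthetic study design

The study's spectra are not public, so the package ships a generator that
emulates the design: 9 varieties x 30 samples x 3 replicate spectra = 810
spectra on the canonical 2151-channel grid. Per-sample concentrations are
drawn Normal(mean, SD) from the published per-variety statistics, without
min/max truncation — several printed rows are internally inconsistent (e.g.
variety 1 OM: SD 0.083 exceeds half the min-max range 0.075; variety 8
resembles a two-component mixture), so no bounded distribution can match
all four statistics and the generator matches mean and SD exactly.

Spectra follow a Beer-Lambert-style additive model: a smooth per-variety
polynomial baseline, minus Gaussian absorption bands whose depth is
`depth + a_N * N + b_OM * OM`, plus a per-spectrum baseline shift
(SD 0.02, emulating loading-density/particle-size disparity) and white
channel noise (SD 0.005). Band placement follows the qualitative spectral
description: a shared absorption complex inside 1887-2200 nm
(nitrogen-coupled), a visible-range nitrogen band near 500 nm, overtone
structure near 950 nm, an organic-matter band near 1500 nm for all
varieties, an extra 1388-1549 nm peak for varieties 1, 3, 8, 9, and marker
bands at 844, 1733 and 2310 nm unique to variety 9. Couplings are confined
(at the 1% Gaussian-weight level) to the informative ranges 400-600,
900-1000, 1400-1600 and 1800-2300 nm, and `ground_truth_mask()` exposes the
coupled channels so selector recovery can be scored. Coupling magnitudes
(`a_N = 0.012-0.020`, `b_OM = 0.0012-0.0020` reflectance per concentration
unit) were set once so that stacked models reach the high $R^2$ regime the
method targets while selection stays non-trivial.

What the generator does *not* emulate: instrument drift, scattering
physics beyond the additive shift, wavelength-correlated noise, and any
within-variety covariance between N and OM. Passing tests therefore
demonstrate correctness of the algorithms under a controlled, solvable
design — not field performance on real fertilizer spectra.

A **reduced preset** (64 channels, 9 varieties x 10 samples x 1 replicate,
noise SD 0.02) provides the optimizer benchmark: 8 informative channels,
where variety $v > 1$ deepens only channel $v - 1$. Every informative
channel is then individually necessary for full classification accuracy
(dropping channel $k$ merges varieties 1 and $k+1$, costing far more
accuracy than the $(1-\alpha)/64$ size reward), so the fitness optimum is
exactly the 8-channel ground truth and recovery can be scored sharply.

## Splitting, preprocessing, metrics

* Savitzky-Golay smoothing (window 11 channels, polynomial order 2 —
  unreported in the original study; both configurable) is the only spectral
  preprocessing, via `signal::sgolayfilt`.
* The calibration/prediction split draws `ceiling(fraction * n)` prediction
  spectra — 203/607 from 810 at fraction 0.25 — stratified by variety with
  largest-remainder allocation. Replicates are independent rows by default
  (mirroring the 810-spectrum design); `group_by_sample = TRUE` prevents
  replicate twins from straddling the split.
* Standardization (zero mean, unit sample SD per channel) is fit on the
  calibration set only and applied to the prediction set.
* Metrics: $R^2 = 1 - SSE/SST$ and RMSE per set (R2c/RMSEC, R2p/RMSEP), and
  a **pseudounivariate limit of detection** $3.3\, s_{res}/|b_1|$ from the
  least-squares line of predictions on observations. The original study never
  defines its LOD (its printed values are nearly constant across models
  whose RMSEP differs twenty-fold), so the package's LOD is its own
  convention — comparable within a run, not to the printed values.
* Joint two-target metrics (used when comparing selectors through one
  multi-output ridge) standardize each target to unit calibration SD and
  stack the standardized columns before computing $R^2$/RMSE, so the OM
  scale (tens) cannot drown the N scale (units); how the original study aggregated
  its joint numbers is unstated.

## Problem sizes and numerical choices

Wrapper selection is the expensive stage: one fitness call is a full
stack CV. The pipeline therefore works at deliberately chosen sizes:

* Channels are **block-binned** (default width 10, 2151 -> 216 bins) before
  selection; the selected bin mask is expanded back to the full grid for
  reporting. Regressors are fit on the selected bins.
* The wrapper fitness averages **replicate spectra per sample** before its
  CV (default in the pipeline). Replicates of one sample are near-twins;
  letting them straddle CV folds inflates wrapper accuracy, and averaging
  both removes that leakage and cuts the fitness cost threefold.
* Inside the fitness, the accuracy CV and the stack's internal out-of-fold
  construction use 3 folds (the stack default elsewhere stays 5).
* The optimizer-vs-oracle benchmark (8 channels, all 255 subsets
  enumerable) uses the ridge-classifier wrapper fitness, whose closed-form
  fits make 20 repeated swarm runs cheap; the support-recovery benchmark
  runs the same wrapper objective for 50 iterations, long enough for the
  swarm to prune noise channels.
* Penalized multinomial logistic fits use a short warm-started lambda path
  down to $\lambda = 1/(C n)$ (cold single-lambda fits do not converge
  reliably), a stable softmax over link predictions, and a tenfold penalty
  escalation fallback for degenerate folds.
* Ridge solutions use the normal equations on centered data; zero-variance
  channels are rejected at standardization with the offending wavelength
  named.

## Known limitations

* Real Table-2-level numbers are not reproducible: the study data are
  private, and results here quantify the synthetic design.
* `nnet`'s MLP is a shallow stand-in for a deep MLP; with default settings
  it is the weakest SSGR member and mainly demonstrates the stacking
  machinery.
* The GA baseline uses standard settings (population 50, 10 generations,
  crossover 0.9, mutation 1/D, tournament 3, elitism 1) chosen to mirror
  the PSO budget; the original study states none.
* With 10 iterations on hundreds of channels the swarm reliably improves
  its objective but does not reach a minimal subset; tight support
  recovery needs the longer benchmark budget above.
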