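# nirstack

Wavelength selection and stacked-generalization calibration for Vis-NIR
reflectance spectra of organic fertilizers.

Commercial organic fertilizers must meet nitrogen (N) and organic-matter
(OM) specifications, but reference chemistry (ICP-OES after digestion) is
slow. Visible/near-infrared reflectance (350–2500 nm) predicts both
properties in seconds — if the 2151 collinear channels are tamed. This
package is for chemometricians and spectroscopists who want a complete,
testable implementation of a two-stage ensemble approach:

1. **PSO-FSGC wavelength selection.** A binary particle swarm searches
   channel subsets. A particle's fitness is
   `J = alpha * P + (1 - alpha) * (1 - N_f / N_t)`, where `P` is the
   cross-validated accuracy of a stacked-generalization classifier (SVM,
   1-NN, penalized logistic, ridge; logistic meta learner) predicting the
   fertilizer variety from the masked channels, `N_f` the subset size and
   `N_t` the channel count. Velocity update
   `v <- w v + c1 q (x_pb - x)/dt + c2 r (x_sb - x)/dt`, logistic transfer
   `S(v) = 1/(1+e^-v)`, strict-improvement personal/global bests, and a
   reset-swarm escape on premature convergence. Defaults: 50 particles, 10
   iterations, `alpha = 0.5`.
2. **SSGR calibration.** On the selected channels, a stacked regressor
   (SVR, KNN, MLP, ridge; multi-output ridge meta learner) predicts N and
   OM jointly, benchmarked against plain ridge, SVR and PLS (3/6/9 latent
   variables) with R²c/RMSEC, R²p/RMSEP and a pseudounivariate limit of
   detection `3.3 * s_res / |b1|`.

Because the study's spectra are private, the package includes a synthetic
generator reproducing the design — 9 varieties × 30 samples × 3 replicate
spectra on the 350–2500 nm integer grid, concentrations drawn from the
published per-variety statistics, Gaussian absorption bands with known
N/OM couplings — plus a reduced 64-channel benchmark with 8
ground-truth-informative channels for scoring selector recovery. Baseline
selectors (Lasso, a genetic algorithm, PSO with a lone SVM) share the same
harness.

## Worked example

The full pipeline — simulate the 810-spectrum design, Savitzky–Golay
smooth, split 607/203, bin to 216 channels, select wavelengths with
PSO-FSGC, calibrate — is one call (about 8 minutes on one CPU, almost all
of it the 500 stack-CV fitness evaluations):

```r
library(nirstack)
report <- run_full_pipeline(parse_config())   # all defaults, seed 1
#> [nirstack] simulating study-preset dataset (seed 1)
#> [nirstack] split: 607 calibration / 203 prediction spectra
#> [nirstack] PSO-FSGC selection (50 particles x 10 iterations, alpha 0.5)
#> [nirstack] selection fitness 0.8374, 67/216 bins selected
report$metrics
#>    method       property       R2c      RMSEC       R2p      RMSEP       LOD
#> 1    ssgr       nitrogen 0.9996150 0.02333865 0.9981986 0.05030852 0.1652397
#> 2    ssgr organic_matter 0.9938332 0.52982341 0.9557260 1.43664635 4.8221229
#> 3   ridge       nitrogen 0.9941391 0.09106319 0.9939722 0.09202670 0.3055025
#> 4   ridge organic_matter 0.8729550 2.40480950 0.8598225 2.55631623 9.1240246
#> ...
```

Reading: the swarm kept 67 of 216 bins (670 of 2151 nm channels) at
fitness 0.837 (perfect variety classification on about 31 % of the
channels). The stacked regressor then predicts the prediction set with
R²p = 0.998 for nitrogen (RMSEP 0.050 concentration units) and
R²p = 0.956 for organic matter, beating the plain ridge on OM by ~0.1 R²
— the stacked stages earn their keep on the harder target. PLS improves
monotonically from 3 to 9 latent variables.

Smaller pieces are exposed individually — `generate_dataset()`,
`savgol_smooth()`, `split_calibration_prediction()`, `build_fsgc()`,
`run_pso()`, `build_ssgr()`, `fit_stack()`, `evaluate_model()`,
`compare_feature_selectors()` — and a thin command-line wrapper lives at
`inst/cli/nirstack.R` (`simulate`, `select`, `run`). See the methods
vignette (`vignettes/nirstack-methods.Rmd`) for the model, the synthetic
design, and every numerical choice.

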