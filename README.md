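# bplquant

Quantification accuracy and image quality in penalized-likelihood PET
reconstruction, studied end-to-end on digital phantoms.

The only user-tunable parameter of Bayesian penalized-likelihood (BPL)
PET reconstruction is the noise-penalization weight *beta*. Raising beta
suppresses noise but also biases the uptake measured in small objects,
which is a problem precisely where quantification matters most: small
pulmonary nodules, whose standardized uptake values (SUVs) are already
depressed by the partial-volume effect. `bplquant` is a desk-scale R
pipeline for studying that trade-off: it simulates a NEMA-IQ-like
image-quality phantom and a clinical-lesion phantom, reconstructs them
over a sweep of beta values, quantifies every standard metric, and applies
a phantom-derived regression partial-volume correction (PVC) to the lesion
SUVs.

## The model

Images are reconstructed by maximizing the penalized Poisson likelihood

    x̂ = argmax_{x ≥ 0}  Σ_i [ y_i log(Px)_i − (Px)_i ]  −  β R(x)

where `y` are the measured coincidence counts, `P` the system (projection)
matrix, and `R` the relative difference penalty (RDP)

    R(x) = Σ_j Σ_{k ∈ N_j} w_jk (x_j − x_k)² / (x_j + x_k + γ|x_j − x_k|)

whose denominator makes the noise control activity-dependent and whose
`γ` term preserves edges. The optimizer is BSREM-style preconditioned
gradient ascent with the EM preconditioner; with one subset and β = 0 an
update is exactly one ML-EM iteration.

From the reconstructions the package computes the NEMA image-quality
metrics — recovery coefficient `RC = A_M/A_K`, contrast recovery
`CR = (A_M/A_B − 1)/(C − 1)`, background variability `BV = SD_B/C_B` over
60 background ROIs — and the lesion metrics SUVmean, SUVmax, SUVpeak
(highest-mean 1 mL kernel), SNR (SUVmax over reference-region SUV SD) and
CNR ((lesion − lung background)/lung SD). The PVC fits, per beta, an
ordinary least-squares line of sphere RC (%) against sphere diameter (mm),
predicts a lesion's RC from its diameter, and divides its SUVs by that
fraction.

## Worked example

A small noiseless sweep of the image-quality phantom (three betas on a
thin grid; the full study uses 19 betas on 96 x 96 x 32):

```r
library(bplquant)
cfg <- sweep_config(mode = "nema", betas = c(100, 350, 1000),
                    reference_beta = 350, noiseless = TRUE,
                    grid = grid_geometry(c(96, 96, 15)))
metrics <- run_sweep(cfg)
subset(metrics, beta == 350, c(diameter_mm, rc_pct, cr_pct, bv_pct))
#>    diameter_mm rc_pct cr_pct bv_pct
#> 7           10   46.0   27.3 0.1312
#> 8           13   54.9   39.2 0.1372
#> 9           17   67.6   56.1 0.0994
#> 10          22   74.7   65.6 0.1226
#> 11          28   80.8   73.8 0.2590
#> 12          37   85.3   80.0 0.3066
```

Recovery falls with sphere size — the partial-volume effect the PVC is
built to undo. Fitting the per-beta RC regression and predicting the
recovery of a 15 mm lesion:

```r
models <- fit_rc_models(metrics)
models[["350"]]
#> rc_regression (beta = 350): RC% = 1.424 * d + 38.09, R^2 = 0.8832, d in [10, 37] mm
predict(models[["350"]], 15)
#> $rc          [1] 0.594466
#> $extrapolated [1] FALSE
#> $clamped      [1] FALSE
```

A 15 mm nodule at this beta recovers ~59% of its true concentration, so
its SUVs are divided by 0.594. Reader-score aggregation over the packaged
subjective-rating table selects the preferred beta per lesion-size group:

```r
best_overall_beta(reader_scores())
#>      group best_beta best_beta_reader1 best_beta_reader2
#> 1   <10 mm       300               300               300
#> 2 10-30 mm       400               400               400
```

The full study — `run_sweep()` in `"clinical"` mode with three noise
replicates, `apply_pvc_to_metrics()`, and `build_report()` — produces the
SNR/CNR-versus-beta curves, the SUV-versus-beta correlations before and
after PVC, and the reader-agreement kappas. A command-line wrapper with
`simulate / reconstruct / quantify / pvc / sweep / report` subcommands is
installed at `inst/cli/bplquant`.

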