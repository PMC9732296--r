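# glucalib

Calibration and clinical agreement analysis for experimental blood glucose
meters, built around a from-scratch **relevance vector machine** (sparse
Bayesian kernel regression).

## The problem

An in-vitro glucose biosensor — here an ultrasonic transceiver pair reading
a blood sample to which glucose is titrated in 4 mg/dl increments — produces
a raw voltage, not a glucose concentration. Turning the device into a meter
requires two steps:

1. **Calibration**: learn the map from the measured features (added glucose
   `g_add`, receiver voltage `v_u`) to the glucose read simultaneously by a
   commercial reference meter (`cbgm`).
2. **Agreement analysis**: show that the calibrated device (`pbgm`) agrees
   with the reference meter well enough to be clinically safe.

`glucalib` implements both, plus a seeded synthetic-data generator that
reproduces the statistical structure of the titration experiment (equally
spaced latent glucose, a monotone voltage response around a 19 mV water
baseline, Gaussian sensor noise, constant-CV reference-meter error), so the
whole pipeline is testable end to end.

## The model

For training pairs (**m**_i, t_i), with **m**_i = (g_add, v_u) standardized,
the response model is

&nbsp;&nbsp;&nbsp;&nbsp;t_i = **w**ᵀφ(**m**_i) + ε_i, ε_i ~ N(0, σ²),

where φ(**m**) = [1, K(**m**, **m**₁), …, K(**m**, **m**_N)] stacks a bias
and one kernel basis per training exemplar (Gaussian kernel by default,
width set by the median pairwise distance). Each weight gets an independent
zero-mean Gaussian prior with its own precision α_i. The weight posterior is
Gaussian with

&nbsp;&nbsp;&nbsp;&nbsp;C = (σ⁻²ΦᵀΦ + A)⁻¹, μ = σ⁻²CΦᵀ**t**, A = diag(α),

and the hyperparameters are estimated by type-II maximum likelihood through
the fixed-point updates

&nbsp;&nbsp;&nbsp;&nbsp;γ_i = 1 − α_i C_ii, α_i ← γ_i/μ_i², σ² ← ‖**t** − Φμ‖²/(N − Σγ_i).

Most α_i diverge and their bases are pruned; the few surviving exemplars are
the *relevance vectors*. Prediction at a new point is Gaussian with mean
μᵀφ(z) and variance σ² + φ(z)ᵀCφ(z).

The agreement toolkit covers the field's standard instruments: the Clarke
and Parkes (consensus) error grids, the surveillance error grid machinery
(bilinear risk interpolation over a lattice, with a clearly tagged surrogate
surface for testing), normalized correlation (NCC = Σxy/√(Σx²Σy²)), bias /
MARD / SD of relative differences, modified Bland–Altman limits of
agreement, Welch's location test, and fasting/post-meal glycemic-class
summaries.

## Worked example

```r
library(glucalib)

run <- run_pipeline(pipeline_config(
  generator = titration_config(basal_glucose = 80),  # 125 batches, 4 mg/dl steps
  seed = 42))
run
#> Glucose calibration run
#>   125 records (generated), 93 train / 32 test, scope: all
#>   model: rbf kernel, 6 relevance vectors, noise SD 12 mg/dl
#>   NCC 0.9995 | bias 0.44% | MARD 3.03% | SD 4.19% | p = 0.994
#>   Clarke A: 100.0% | Parkes(type2) A: 100.0% | SEG no-risk: 97.6% (surrogate surface)

summary(run$model)
#> Relevance vector machine regression
#> Formula: cbgm ~ g_add + v_u
#> Kernel: rbf kernel (width = 1.445705), with bias
#> Exemplars: 93   relevance vectors: 6 (+ bias)   sparsity: 6.5%
#> Noise variance sigma^2: 144.571 (SD 12.02)
#> Log evidence: -383.6773 after 452 iterations
#> Training RMSE: 11.65
```

Reading the numbers: 125 synthetic titration batches were generated with a
3% reference-meter CV; the RVM trained on 93 of them kept only 6 of 93
exemplars as relevance vectors yet tracks the reference meter with a mean
absolute relative difference of 3.0% and NCC 0.9995 over all 125 batches;
its estimated noise SD (12 mg/dl) matches the meter noise actually injected
(3% of the ~300 mg/dl mean level); every prediction lands in the
clinically-correct zone A of the Clarke and consensus grids. The Welch
p-value near 1 says the two meters' mean levels are statistically
indistinguishable.

The pieces are usable on their own:

```r
clarke_zone(120, 123)          # "A" — within 20% of the reference
parkes_zone(300, 150, "type2")
ncc(c(3, 4), c(4, 3))          # 0.96
bland_altman(ref, pred)
fit <- rvm(cbgm ~ g_add + v_u, data = my_measurements)
predict(fit, newdata, se.fit = TRUE)
```

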