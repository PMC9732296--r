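---
title: "Calibrating a glucose biosensor with sparse Bayesian regression"
author: "glucalib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating a glucose biosensor with sparse Bayesian regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucalib)
```

## Overview

`glucalib` models the calibration problem of an experimental in-vitro
glucose meter: an ultrasonic transceiver reads a blood sample while glucose
is added in equal increments, and a commercial meter reads the same sample
as the reference. The package provides (i) a seeded generator for synthetic
measurement tables with that experiment's statistical structure, (ii) a
from-scratch relevance vector machine (RVM) that learns the map from
`(g_add, v_u)` to the reference glucose, and (iii) the standard clinical
agreement toolkit for judging the calibrated device.

## The regression model and its assumptions

The response model is Gaussian and additive,
$t_i = \mathbf{w}^\top \phi(\mathbf{m}_i) + \varepsilon_i$ with
$\varepsilon_i \sim N(0, \sigma^2)$, where the basis vector
$\phi(\mathbf{m}) = [1, K(\mathbf{m},\mathbf{m}_1), \dots,
K(\mathbf{m},\mathbf{m}_N)]$ places one kernel function on every training
exemplar plus a constant bias. Every weight carries an independent
zero-mean Gaussian prior with its own precision $\alpha_i$; with a flat
hyperprior on $(\alpha, \sigma^2)$, hyperparameters are chosen by type-II
maximum likelihood (maximizing the marginal likelihood after integrating
the weights out). The weight posterior given hyperparameters is Gaussian,

$$C = (\sigma^{-2}\Phi^\top\Phi + A)^{-1}, \qquad
  \mu = \sigma^{-2} C \Phi^\top \mathbf{t}, \qquad A = \mathrm{diag}(\alpha),$$

and the evidence is maximized by the classical fixed-point iteration
$\gamma_i = 1 - \alpha_i C_{ii}$, $\alpha_i \leftarrow \gamma_i/\mu_i^2$,
$\sigma^2 \leftarrow \|\mathbf{t}-\Phi\mu\|^2 / (N - \sum_i \gamma_i)$,
alternated with the posterior update and with pruning of bases whose
precision diverges. The surviving exemplars — typically a handful — are the
relevance vectors. The predictive distribution at a new point $z$ is
Gaussian with mean $\mu^\top\phi(z)$ and variance
$\sigma^2 + \phi(z)^\top C\, \phi(z) \ge \sigma^2$.

Assumptions worth keeping in mind: homoscedastic Gaussian noise on the
*target* (the reference meter actually has roughly constant *relative*
error, so the RVM's $\sigma^2$ absorbs an average of a level-dependent
variance); exchangeable exemplars; and a kernel whose length-scale is
meaningful on standardized features.

## Tunable parameters

* **Kernel** (`rvm_kernel()`): Gaussian (`rbf`) by default. The width is a
  length-scale in standardized feature units; its default is the median
  pairwise distance of the standardized training features, a scale-free
  heuristic that puts a substantial fraction of kernel mass between
  neighbouring exemplars. `linear` and `polynomial` kernels are provided;
  the bias column is on by default and prunable like any basis.
* **Feature standardization** is internal and mandatory: `g_add` spans
  hundreds of mg/dl while `v_u` spans a few mV, so an unstandardized rbf
  width would be meaningless. The parameters are stored on the model and
  re-applied at prediction time.
* **Initialization** (`rvm_control()`): $\alpha_i = 10^{-4}$ for every
  basis and $\sigma^2 = 0.1\,\mathrm{var}(t)$ — deliberately weak priors and
  no randomness, so a fit is a deterministic function of (data, kernel,
  control) and repeated fits are bit-identical.
* **Pruning** at $\alpha > 10^9$: on standardized targets a weight with
  that precision is numerically zero. A diagonal jitter of $10^{-10}$
  stabilizes the Cholesky factorization and is escalated a few steps
  before a numerical error is raised; $\sigma^2$ is floored at $10^{-12}$
  so perfect-fit instances stay defined.
* **Stopping**: the iteration ends when
  $\max(|\Delta\log\alpha_i|, |\Delta\log\sigma^2|) < 10^{-3}$, or when the
  log evidence has been stationary (change $< 10^{-8}$) for three
  consecutive iterations, with a cap of 500 iterations. Two of these rules
  deserve a note. The noise variance is watched alongside the precisions
  because on (near-)noise-free data the $\alpha_i$ settle while $\sigma^2$
  is still descending by a near-constant factor per step; stopping on
  $\alpha$ alone would freeze the fit with around 1% training error where
  exact interpolation is attainable. The evidence-plateau rule exists for
  the opposite regime: late in a noisy fit a doomed basis can spend
  hundreds of iterations drifting toward the pruning threshold
  (its $\alpha$ growing a few percent per iteration) while the evidence and
  every prediction are already stationary to ten decimal places; the
  plateau rule ends such runs honestly instead of reporting a spurious
  non-convergence.

## What the synthetic generator emulates

`titration_config()` defaults describe one titration run the way the
emulated experiment reports it: 125 batches of 4 mg/dl glucose additions, a
19 mV distilled-water baseline voltage, and a strictly monotone voltage
response. Choices the experiment's description leaves open were fixed once,
as follows:

* **Response form and direction**: the voltage–glucose curve is not
  published numerically, and any strictly monotone map is sufficient for a
  kernel regression to invert. The default is linear and *decreasing*
  (−0.01 mV per mg/dl) from the 19 mV baseline — the baseline is the only
  printed voltage — with the sign and a saturating logistic alternative
  exposed in the configuration.
* **Sensor noise** defaults to 0.25 mV: the instrument's baseline is
  reported as repeatable to ±0.5 mV, which we read as an approximate
  2-standard-deviation band.
* **Reference-meter error** is multiplicative with a 3% CV, the
  specification class of commercial strip meters at these levels. The
  generated reading is `true_glucose * (1 + N(0, cv))`, clamped at zero.
* **Basal glucose**: blood already contains glucose before any addition.
  `titration_config()` keeps the spec-level default of 0 (convenient for
  exactness tests); `pipeline_config()` raises it to 80 mg/dl — a realistic
  fasting level — which also keeps every reference reading strictly
  positive so relative-difference statistics are well defined.
* 125 batches at 4 mg/dl from 0 reach 496 mg/dl of added glucose, slightly
  past the device's stated 0–450 mg/dl sensing range; the two published
  figures (125 samples; 0–450 mg/dl at 4 mg/dl steps) cannot both hold
  exactly, and the batch count wins here. With `n_batches = NULL` the range
  and step determine the count instead.

What the generator does **not** emulate: acoustic physics (attenuation or
speed-of-sound modelling), hematocrit and protein confounders, drift,
temperature, or any between-run variability — each batch is independent
given the latent glucose. Passing tests on this generator therefore
demonstrate that the *pipeline machinery* is correct and that the RVM can
invert a monotone response under realistic noise; they say nothing about
how an ultrasonic sensor behaves in real blood.

The cohort generator (`generate_cohort()`) draws latent glucose uniformly
within fasting/post-meal glycemic-class intervals with the six-stratum
design (17/16/95 fasting, 39/14/71 post-meal normal/prediabetes/diabetes)
so the classification table can be exercised at its published shape. Meal
state is generator metadata; the emulated experiment never explains how
in-vitro batches would acquire such labels.

## Error grids and agreement statistics

* **Clarke**: the canonical 1987 rule set, applied in the order A, E, C, D,
  else B (a total function; boundary points belong to the first matching,
  lower-risk rule). Minor published variants of the boundary arithmetic
  exist; this dialect is documented in `?clarke_zone`.
* **Parkes (consensus)**: zone assignment interpolates the embedded
  boundary polylines at the reference value; a point exactly on a boundary
  goes to the lower-risk zone. The type 2 grid is exposed with zones A–D:
  this package's contract reads the consensus grid's missing lower E region
  as type 2 carrying no E zone at all, and reports readings above the
  type-2 D boundary as D. Values beyond the 550 mg/dl domain are clipped
  with a warning rather than dropped. The test suite cross-checks every
  assignment against an independent ray-casting point-in-polygon oracle
  built from the same vertex tables, and property-tests the geometry
  (partition, diagonal safety, monotone risk along verticals).
* **Surveillance error grid**: the official risk surface is an empirically
  derived clinician-survey lookup table that cannot be reconstructed from
  formulas, so the module evaluates any user-supplied lattice CSV
  (`read_seg_grid()`) by bilinear interpolation, and ships a *surrogate*
  surface — `4 * min(1, |pred - ref| / max(ref, 30))`, zero on the
  diagonal — for exercising the machinery. Surrogate results are tagged as
  such and are not official SEG risk scores. Risk categories use the
  standard 0.5-wide bins with the no-risk bin closed at 0.5.
* **NCC** is the zero-lag normalized cross-correlation
  $\sum xy/\sqrt{\sum x^2 \sum y^2}$ (not Pearson): on strictly positive,
  non-centred glucose series this is the similarity index that sits near 1
  for well-agreeing meters; Pearson is available by option.
* **Bias/MARD/SD** use per-pair relative differences in percent with the
  $n-1$ SD denominator; Bland–Altman limits are mean ± 1.96 SD of the raw
  differences. The location test is Welch's two-sided t-test
  (Mann–Whitney by flag), with the degenerate equal-constant case defined
  as $p = 1$.
* **Glycemic classes** are keyed on the *reference* reading and use
  right-closed intervals, so a fasting 125 mg/dl is prediabetes; values
  below 70 mg/dl fall outside the published bands and are flagged `hypo`.

## Pipeline and reproducibility

`run_pipeline()` chains generate (or load) → split → fit → predict →
error grids + agreement report. The master seed drives generation and
`seed + 1` the 93/32 random split, so every reported number is a
deterministic function of the configuration. The error grids are evaluated
over all 125 predictions by default (`scope = "all"`), with a test-only
option, since the emulated study grids 125 samples while plotting 32 test
predictions; both readings of that protocol are supported. Models persist
to JSON (`write_rvm()`/`read_rvm()`) and predict identically after the
round trip.

## Problem sizes used by the tests

The shipped tests run the study-scale configuration (125 batches, 93/32
split) and repeat the parameter-recovery experiment over 20 seeds; the
posterior and agreement oracles use 50–100 random small instances; the
Parkes geometry oracle uses 1,000 random points per grid; distributional
checks (meter CV, Bland–Altman coverage) use $n = 10^4$. These sizes make
the stochastic assertions stable at their stated tolerances while keeping
the whole suite around ten seconds.

## Known limitations

* The RVM is the batch fixed-point algorithm; the fast sequential
  (incremental basis selection) variant is out of scope, so fits are
  $O(N M^2)$ per iteration and comfortable only up to a few hundred
  exemplars — ample for this experiment's scale.
* Type-II ML can non-monotonically reorganize the evidence when a basis is
  pruned; the fit logs the evidence trace and the tests bound any decrease
  at $10^{-6}$ per step.
* The homoscedastic noise model mismatches a constant-CV reference meter at
  the extremes of a wide glucose range; over 80–576 mg/dl this shows up as
  mild over-coverage of predictive intervals at low levels.
* Clarke boundary dialects differ at a few line segments across published
  implementations; agreement percentages within a point or two of a zone
  boundary can differ accordingly.
* The surrogate SEG surface supports machinery tests only; clinical claims
  require the official lattice supplied as CSV.
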