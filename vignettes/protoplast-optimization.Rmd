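---
title: "Optimizing protoplast preparation with response surfaces and neural networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing protoplast preparation with response surfaces and neural networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protodoe)
```

## The problem

Releasing protoplasts from plant leaf tissue is a compromise: more cell-wall
enzyme and a harsher osmoticum raise the number of cells freed per milligram
of tissue but damage the membranes of the cells that are freed. A usable
single-cell system needs both a high yield (counted per 100 mg of tissue, in
units of 10^6 cells) and high viability (percent of cells excluding Evans
blue). `protodoe` packages the complete desk side of a three-factor
optimization of this trade-off — cellulase R-10 (% w/v), macerozyme R-10
(% w/v) and mannitol (mol/L) — together with the 17-run *Salsola laricifolia*
dataset it was developed on, so the same workflow can be replayed on any
small designed experiment.

The workflow has four stages, each usable on its own:

1. **Design** (`generate_bbd()`): a Box-Behnken design, i.e. the
   `4 * choose(k, 2)` edge midpoints of the factor cube plus replicated
   center runs. For three factors and five centers this is the familiar
   17-run plan.
2. **Response-surface model** (`fit_quadratic()`, `anova()`): the full
   second-order polynomial
   \[
   y = a + \sum_i b_i x_i + \sum_{i<j} c_{ij} x_i x_j + \sum_i d_i x_i^2
   \]
   fitted by ordinary least squares, with the complete adequacy panel.
3. **Network model** (`train_bpnn()`): a single-hidden-layer
   back-propagation network (3 inputs, H tanh units, linear output) trained
   by Levenberg–Marquardt or scaled conjugate gradient with early stopping.
4. **Optimization and comparison** (`optimize_desirability()`,
   `ga_optimize()`, `fit_metrics()`, `comparison_report()`): a Derringer
   desirability search over the quadratic models, a real-coded genetic
   algorithm over any predictor, and the R / R² / RMSE / MAPE comparison
   panel.

`run_pipeline()` chains all four and writes every number it prints to a
machine-readable `summary.json`.

## Unit spaces and the quadratic fit

Factors live in two unit systems: *actual* units (e.g. mannitol in mol/L)
and *coded* units, where each factor's range maps to \([-1, +1]\). The fit is
always performed in coded units — the coded Box-Behnken model matrix is
nearly orthogonal, so the normal equations are well conditioned — and the
coefficient vector is re-expressed in actual units by expanding the affine
substitution \(x_{\text{coded}} = (x - \text{mid})/\text{half-range}\)
through the polynomial. Both coefficient sets are stored; conversion is
exact (round-trip agreement to 1e-10 is tested), so F statistics, R² and
predictions are identical in either space.

```{r fit}
study <- load_protoplast_study()
fit_y <- fit_quadratic(study$design, study$response$yield, response_name = "yield")
anova(fit_y)
```

The adequacy panel follows the conventions of standard response-surface
software, which the packaged study used:

* `F_model = MS_model / MS_residual` with 9 and \(n - 10\) degrees of
  freedom; the p-value is the upper tail of the F distribution (printed as
  `<0.0001` below 1e-4).
* Residual variation splits into **pure error** (within replicated design
  points, here the five centers) and **lack of fit** (the remainder), with
  its own F test.
* `R2_adjusted` is \(1 - (SSE/(n-p)) / (SST/(n-1))\); `R2_predicted` is
  \(1 - \mathrm{PRESS}/SST\) where PRESS is the leave-one-out error sum
  computed from leverages as \(\sum_i (e_i/(1-h_{ii}))^2\) (tested against
  literal leave-one-out refits). A negative predicted R² is legal and
  returned as computed.
* `cv_percent` is \(100\sqrt{MS_{\text{residual}}}/\bar{y}\) and
  `adequate_precision` is the signal-to-noise ratio
  \((\max\hat{y} - \min\hat{y}) / \sqrt{p \cdot MS_{\text{residual}}/n}\)
  over the design points; values above 4 indicate a model worth using for
  navigation of the design space.

The published study's viability panel reproduces from the printed data to
better than 0.5% on every statistic. The yield panel does not reproduce
exactly (the printed yield equation itself disagrees with a refit of the
printed table by up to 0.26 on the C² coefficient, so the printed statistics
evidently derive from an unrounded internal dataset); the package always
refits the packaged table rather than hard-coding printed equations. For the
same reason the published viability equation, whose printed intercept
(18.883) predicts impossible center viabilities, is never evaluated
directly.

## Factor influence and optima

`main_effect_spans()` quantifies the "steepness" reading of surface plots:
each factor is swept across its range with the others at their midpoints,
and the span (max − min) of the predicted response is recorded. Extremes of
the 1-D quadratic slice are located analytically (endpoints plus interior
vertex), not by gridding. For the packaged yield model this ranks cellulase
> macerozyme > mannitol.

`optimize_desirability()` implements Derringer's approach to multi-response
optimization: each response is mapped to a desirability \(d \in [0,1]\) by a
linear ramp between anchors (observed minimum and maximum by default;
one-sided for maximize/minimize goals, tent-shaped for target goals, with
exponent `weight`, default 1), and the geometric mean \(D\) is maximized
over the factor box. The search seeds L-BFGS-B polishing runs from the best
nodes of a 21-per-axis lattice plus random starts (32 starts, seed 0 by
default), and the tests verify the result against an exhaustive
101-per-axis lattice. For the packaged study, maximizing yield and
viability jointly lands at cellulase 1.86%, macerozyme 1.00%, mannitol
0.50 mol/L — predicted yield 1.46 and viability 90.8.

`ga_optimize()` is the model-free counterpart used for network predictors: a
real-coded genetic algorithm with size-2 tournament selection, BLX-0.5
blend crossover, Gaussian mutation with standard deviation
`mutation_scale` × range (clipped to the box) and elitism. Defaults
(population 50, generations 200, crossover 0.8, mutation 0.1, elitism 2)
are conventional small-problem settings; the best-ever individual is
returned, making the per-generation trace monotone.

## The network model

`train_bpnn()` reproduces the toolbox conventions the study's workflow
implies but does not state: inputs and target min-max scaled to
\([-1, 1]\) (fitted on the full dataset — a deliberate small-n pragmatism,
since with 17 runs a train-only scaling can leave validation points outside
the scaled range), tanh hidden layer, linear output, weights initialized
uniformly in \([-0.5, 0.5]\). The data are split 70/15/15 into
train/validation/test by `split_data()` (sizes `floor(n f)`, remainder to
train then validation — 12/3/2 for n = 17); only the training split drives
weight updates.

Levenberg–Marquardt solves \((J^\top J + \mu I)\delta = J^\top e\) on the
analytic Jacobian (tested against finite differences), multiplying the
damping \(\mu\) by 10 until a step reduces the training SSE and dividing it
by 10 after each accepted step, so accepted epochs never increase training
error. The scaled-conjugate-gradient trainer follows Møller's algorithm
(\(\sigma_0 = 5\times10^{-5}\), initial \(\lambda = 5\times10^{-7}\)).
Training stops at `max_epochs` (1000), after `patience` (6) consecutive
epochs without a validation improvement, when the gradient infinity-norm
falls below 1e-7, or when \(\mu\) overflows 1e10; the returned weights are
those of the epoch with minimum validation MSE, and with `restarts > 1` the
restart with the lowest best validation MSE wins. Identical seed and
configuration give bitwise-identical results.

With 17 observations and H = 14–18 hidden units the network is heavily
over-parameterized; the study's protocol relies on early stopping and seed
selection rather than capacity control. The tests mirror that: over 50
seeds, the best 3–18–1 network reaches an all-data correlation above the
study's reported 0.96736 for yield. Per-epoch MSE values depend on the
(unstated) split seed and scaling, so no specific epoch-wise numbers are
asserted.

## Model comparison

`fit_metrics()` reports R (Pearson), R² (the square of R — the convention of
model-comparison tables, which coincides with \(1 - SSE/SST\) for OLS with
an intercept but not for network predictions), RMSE in response units and
MAPE in percent. `cv_percent()` is the data-dispersion coefficient of
variation (sample sd / mean), distinct from the ANOVA C.V.%.
`viable_cells()` implements the combined index yield × viability / 100, and
`relative_error()` the percent validation error used to judge optimum
predictions (credible below 5%).

## The synthetic generator

`surface_spec()` + `simulate_bbd_responses()` emulate the data-generating
situation of a Box-Behnken study: a known quadratic truth evaluated at the
design points plus i.i.d. homoscedastic Gaussian replicate noise. Gaussian
homoscedastic noise is the only structure the five center replicates of the
packaged study can support estimating. The packaged presets use the
published yield equation with noise sd 0.06 and a refit viability model
with noise sd 0.97 — the center-replicate standard deviations of the two
responses. Optional clipping keeps presets physical (yield ≥ 0, viability
in [0, 100]); `parameter_recovery_trial()` drops clipping so the
closed-form OLS standard errors \(\sigma\sqrt{[(X^\top X)^{-1}]_{jj}}\) it
reports against remain exact. What the generator does **not** emulate:
heteroscedastic or non-Gaussian counting error, run-order drift, and any
digestion-kinetics mechanism — so passing recovery tests demonstrate
correctness of the estimators, not realism of the noise model.

Problem sizes used in the shipped tests were chosen to keep the whole suite
in the tens of seconds while leaving the statistical checks sharp: 200
replicates for bias checks, 500 for sd-ratio and pure-error convergence
checks, 101-per-axis lattices for optimizer oracles, and 50 seeds for the
network capacity checks.

## Numerical and design choices

* Run order is the deterministic block order of the packaged study (factor
  pairs (A,B), (A,C), (B,C), first factor varying fastest, centers last);
  an optional `shuffle_seed` permutes runs when randomization is wanted.
  The study reports no randomization, and a fixed order keeps fixtures
  diff-stable.
* Factor count is limited to 3–7, where the edge-midpoint construction is
  standard and brute-force test oracles stay cheap.
* Desirability exponents default to 1 (the study does not state its goal
  weights); anchors default to the observed response range.
* Ties in ranked outputs (spans, comparison flags) keep input order.
* Degenerate cases are explicit: a perfect fit reports `F = Inf`, `p = 0`;
  a desirability field that is zero everywhere returns a flagged degenerate
  result; a zero observed value makes MAPE/relative error `NA` with a
  warning rather than silently dropping points.
* GA and desirability searches, splits, initializations and simulations all
  take explicit integer seeds, and `run_pipeline()` propagates one master
  seed so that two identical runs are byte-identical.

## Limitations

The packaged study is small (17 runs, 5 replicates), so lack-of-fit and
pure-error tests have little power, and network results are strongly
seed-dependent — which is faithful to the original workflow. The quadratic
model cannot represent asymmetries sharper than second order, and the
desirability optimum inherits any model bias at the box boundary, where
both packaged optima sit. Validation of an optimum remains a wet-lab step;
the package quantifies only the desk side (predictions and their relative
errors against whatever experimental values are supplied).
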