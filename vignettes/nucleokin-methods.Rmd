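---
title: "Methods: stochastic nucleation kinetics and scale-up correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic nucleation kinetics and scale-up correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The induction-time model

`nucleokin` analyses isothermal induction-time experiments in stirred
crystallizers under the single nucleus mechanism (SNM): one primary
nucleus forms at a random time, then grows (and secondary-nucleates) for a
deterministic growth time $t_g$ until the suspension crosses the detection
threshold. If nucleation events in a well-mixed volume $V$ form a
stationary Poisson process with rate $J$ per unit volume, the probability
that an experiment has nucleated by time $t$ is

$$P(t) = 1 - \exp\!\big(-J V (t - t_g)\big), \qquad t \ge t_g,$$

and $P(t) = 0$ below $t_g$. The model's assumptions matter for scope:
constant supersaturation (isothermal hold), a detection lag that is the
same in every repeat, and uncensored data — every run is observed until it
nucleates. Runs that never nucleate within the observation window are not
representable; `induction_dataset()` rejects missing or nonpositive times
rather than silently treating them as censored. For the same reason
`induction_summary()` reports the median alongside the mean: with finite
observation windows the sample mean of induction times is biased low.

### Empirical cumulative probability

With $M$ observed times sorted ascending, the observed cumulative
probability at the $i$-th time is $P_i = i/M$ by default, with
$P_i = i/(M+1)$ selectable (`convention = "i_over_M1"`). Both are standard
plotting positions; the choice matters for the direct fit because $i/M$
pins the largest observation at $P = 1$, which the model can only approach
asymptotically. Both conventions are exposed and every fitting function
takes the convention explicitly; the package default is $i/M$. Tied times
all carry the cumulative count of observations at or below them, so the
empirical curve equals the fraction nucleated by $t$.

## Estimators

**Direct fit** (`fit_direct()`): bounded nonlinear least squares of the
model CDF against the empirical CDF at the observed times. Defaults
$J \in [0.01, 20]$ #/(m³·s) and $t_g \in [3000, 30000]$ s, the ranges the
studied system spans; both are arguments. The objective is flat in $t_g$
above $\min t_i$ (all observations sit in the zero-probability region), so
the optimizer (L-BFGS-B with the analytic gradient) is multi-started at
$t_g \in \{\min t_i,\ 0.5\min t_i,\ \text{lower bound}\}$. With the
analytic gradient the solver reaches the objective floor ($\sim 10^{-15}$)
on noise-free data; a line-search stall at numerical precision (optim code
52) is accepted as convergence.

**Maximum likelihood** (`fit_mle()`): the likelihood is increasing in
$t_g$ up to $\min t_i$ and zero beyond, so $\hat t_g = \min_i t_i$
exactly; maximising $M \ln(JV) - JV\sum_i(t_i - \hat t_g)$ gives
$\widehat{JV} = M / \sum_i (t_i - \hat t_g)$. Both identities are tested
exactly. The estimator is upward-biased for both parameters
($\min t_i \ge t_g$ always, by $1/(JVM)$ in expectation), which the test
suite verifies rather than hides.

**Bootstrap** (`bootstrap_fit()`): $M$-out-of-$M$ resampling with
replacement, default 1000 resamples, refitting the base estimator (direct
or MLE) per resample; the reported parameters are the mean across
resamples and `std_J`/`std_tg` their standard deviations. Resamples in
which every drawn time is identical are degenerate for both bases; they
are skipped and counted (`n_skipped`). The bootstrap-of-MLE applies the
closed-form identities per resample (no re-optimisation). Note the
bootstrap mean does *not* converge to the single fit: the resampled
minimum is stochastically larger than the sample minimum, so a resampling
bias of order the bootstrap spread remains. The suite therefore checks
Monte-Carlo consistency (two independent seeds agree within
$3\,\mathrm{std}/\sqrt{n_\text{boot}}$) rather than agreement with the
single fit.

## The estimator benchmark

`estimator_benchmark()` generates synthetic datasets by drawing
$u \sim U[0,1)$ and inverting the model CDF ($u = 1$ is excluded so all
times are finite), then scores each estimator by the mean absolute error
of $\hat J$ and $\hat t_g$ against the generating values. Defaults are
the study conditions: $J = 0.1$ #/(m³·s), $V = 0.01$ m³,
$t_g = 10{,}000$ s, $M \in \{5, 10, 20, 40, 80\}$, 1000 datasets per $M$.
The benchmark also records the mean absolute log₁₀-error of $\hat J$,
which is the error measure used downstream for models that predict
$\log_{10} J$.

The acceptance suite runs this benchmark at full scale for the direct and
MLE estimators ($5 \times 1000$ datasets, about half a minute). The
bootstrap variants refit their base estimator 1000 times per dataset;
benchmarking them at the full scale with the direct-fit base would require
$5 \times 10^6$ bounded optimisations, so the suite exercises them at unit
scale (tens of datasets) where their contracts — finiteness, seeding,
skip accounting — are checked.

## Synthetic hydrodynamic features and the ground-truth mapping

The CFD field values and raw induction times of the original study are
not deposited, so `generate_hydrodynamic_features()` fabricates feature
tables with the canonical 19-column schema. This is a fixture generator,
not a physics model: each feature family starts from a classical mixing
scalar — a Metzner–Otto-like mean shear $11 N (D/T)$ for the shear
family, the mass-specific power $\bar\varepsilon/\rho$ for dissipation,
$0.1\,u_\text{tip}^2$ for turbulent kinetic energy, $0.3\,u_\text{tip}$
for velocity — multiplied by a per-row lognormal jitter
($\sigma = 0.1$), and the quantile columns are fixed multiples
$\{0.55, 0.8, 1.15\}$ of the jittered family mean. The fixed multiples
deliberately make each quantile family perfectly collinear with its mean,
and the shared dependence on impeller speed correlates families with each
other — reproducing the structure that makes correlation-based feature
reduction necessary on real CFD summaries. What the fixture does *not*
emulate: real CFD quantile ratios vary between geometries, axial/radial
means can be signed, and turbulence fields are not lognormal around a
power law. Passing tests therefore demonstrate that the workflow behaves
correctly on data with realistic collinearity and known truth, not that
the fabricated values match any particular vessel.

`generate_study()` gives every configuration known kinetics through a
fixed linear mapping in standardized feature space:

$$\log_{10} J = -3.9 - \log_{10} V + 0.15\, z(\text{sr\_mean}) + 0.20\, z(\text{ep\_mean}),$$
$$t_g = 11000 - 3000\, z(\text{rpm}) - 2000\, z(\text{ep\_mean}) \;\; (\text{clipped at } 600\text{ s}).$$

The intercept and volume coefficient make $JV$ roughly constant at
$1.3\times10^{-4}$ #/s across scales (the behaviour the fixture kinetics
table shows at its two smaller scales); shear and dissipation raise $J$
while speed and dissipation shorten $t_g$, so attribution tests have
unambiguous signs to recover. Induction times are then sampled from the
mapped kinetics, default $M = 10$ per configuration — sparse series of
the size the studied system actually yields (5–14 per configuration).

## Regression workflow

Preprocessing models $\log_{10} J$ (the rate spans orders of magnitude
across scales) and $t_g$ on its natural scale; numeric features are
standardized with statistics from the training split only (a mutation
test asserts no leakage), and impeller type becomes two binary
indicators. Pearson reduction scans the 24 numeric features in canonical
table order and drops any column correlating above $r_\max = 0.95$ (the
workflow default) with an already-kept column — dropping the *later*
column makes the result deterministic; the survivors are verified
brute-force in the tests. The train/test split is data, not code: the
fixture carries the original split labels (14 training/validation, 3
testing), and synthetic studies label their last ~18% of configurations
as testing.

The model zoo mirrors the study design: univariate benchmarks on
classical scale-up parameters, constant-value benchmarks for $t_g$
(global mean, and per-impeller-type means), and ridge, LASSO, random
forest, gradient boosting and kNN on the reduced feature set.
Hyperparameters are chosen by grid search minimising leave-one-out RMSE
on the training split. The original study's tuned grids are not
available, so the package ships small documented defaults: 6 log-spaced
penalties ($10^{-3}$–$10^2$) for ridge/LASSO, tree depth $\{2,3\}$ ×
rounds $\{50,200\}$ for boosting, $\{50,200\}$ trees × node size
$\{1,3\}$ for forests, $k \in \{2,3,5\}$ for kNN — sized for 13-row LOO
training sets, where larger grids only overfit the validation signal.
Stochastic learners are seeded per fit.

**Error-band metrics.** Because fitted kinetics from sparse series carry
experimental error, RMSE and $R^2$ alone are unreliable; the workflow
also reports the percentage of predictions within the estimator's mean
absolute error at $M = 5$ and $M = 20$ observations
(`error_band_metrics()`). The bands live on the scale the model predicts:
for $J$ models that is log₁₀ space, so the band is the benchmark's mean
absolute log₁₀-error (a symmetric band in $\log J$ corresponds to the
multiplicative error bounds that sparse induction-time series actually
produce). $R^2$ uses the NaN convention: a fit worse than predicting the
mean is reported as NaN, not as a negative number.

## Ensembles and attribution

`ensemble_predict()` back-transforms the $J$ model's log₁₀ prediction,
floors the $t_g$ prediction at zero, and evaluates the Poisson model over
a time grid — the predicted curve is by construction a valid CDF, never a
free-form curve. Scoring (`evaluate_ensemble()`) takes residuals at the
*observed* induction times between the empirical CDF and the curve's
closed-form value there, so a perfect model scores zero regardless of the
grid; residuals are pooled across configurations before the square root
(the per-config RMSEs and their mean are also reported, since the
aggregation choice is not neutral). A predicted $t_g$ beyond every
observed time is legal — the curve predicts $P = 0$ throughout — and is
flagged (`all_zero`) rather than rejected, since that failure mode is
diagnostic for benchmark ensembles at unfamiliar scales. The shipped
no-feature benchmark ensemble is tip-speed univariate $J$ + per-impeller
constant $t_g$.

`feature_attribution()` computes Shapley values by the exact closed form
for linear models ($\phi_j = \beta_j (x_j - \bar x_j)$ over the training
background), exact TreeSHAP for gradient boosting (the booster's
prediction contributions), and a seeded Monte-Carlo permutation sampler
for other classes (default 64 orderings per row). The summary reports
mean |attribution| (global importance) and a signed high-value effect:
mean attribution above the feature's median minus below. For sign
recovery checks the ridge models are the robust readout — with collinear
features a tree model may legitimately route all splits through one of
two correlated columns and attribute exactly zero to the other, while
ridge shares weight across them.

## Pipeline, seeds and problem sizes

`run_pipeline()` executes the stages in order (data → kinetics →
benchmark/bands → reduction → zoo → ensemble → attribution), writing every
intermediate table as CSV plus a manifest of the seeds used. Every
stochastic stage derives its seed deterministically from the root seed
(fixed offsets, recorded in the manifest), so identical configurations
give byte-identical artifacts. The test suite runs the full estimator
benchmark at 1000 datasets per $M$; pipeline-level tests use 10–200
benchmark datasets (the bands stage only needs stable MAE estimates) and
8–17 configurations, sizes chosen so the whole suite exercises every
stage end-to-end in about a minute.

## Limitations

- No censored-likelihood extension: non-nucleated runs must be excluded
  upstream, biasing fits from heavily censored campaigns.
- No competing induction-time models (Weibull, two-step nucleation); the
  Poisson/SNM model is assumed, not tested against alternatives.
- The fabricated features carry a known, linear ground truth; real
  feature–kinetics relationships need not be linear in standardized
  space, and conclusions about model rankings on synthetic studies do not
  transfer to real campaigns.
- With 14 training configurations, grid-searched hyperparameters are
  noisy; the grids are intentionally small and the leave-one-out RMSE
  should be read as a ranking signal, not an unbiased error estimate.
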