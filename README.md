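# nucleokin

Stochastic primary nucleation kinetics and hydrodynamic scale-up
correlations for stirred crystallizers.

## The problem

Primary nucleation from a clear, supersaturated solution is a stochastic
event: repeating the same isothermal crystallization experiment gives a
different induction time every run. Scaling such a process from a 100 mL
bench reactor to pilot and plant vessels is hard because nucleation
kinetics depend on agitation, and no single classical scale-up rule (equal
tip speed, equal power input, equal Reynolds number) captures that
dependence. `nucleokin` implements a complete analysis chain for this
problem, aimed at crystallization and process-development scientists:

1. **Kinetics estimation.** Under the single nucleus mechanism, induction
   times in a stirred volume *V* follow the shifted-exponential (Poisson)
   model

   *P*(*t*) = 1 − exp(−*J·V·*(*t* − *t*<sub>g</sub>)) for *t* ≥ *t*<sub>g</sub>, else 0,

   with nucleation rate *J* (#/(m³·s)) and growth time *t*<sub>g</sub> (s).
   The package fits (*J*, *t*<sub>g</sub>) to an observed induction-time
   series by bounded nonlinear least squares (`fit_direct()`), by maximum
   likelihood (`fit_mle()`, with the closed form
   *t̂*<sub>g</sub> = min *t*<sub>i</sub> and
   *Ĵ V* = *M*/Σ(*t*<sub>i</sub> − *t̂*<sub>g</sub>)), and by bootstrap
   resampling around either base estimator (`bootstrap_fit()`).
2. **Estimator benchmarking.** `estimator_benchmark()` measures each
   estimator's mean absolute error on seeded synthetic datasets across
   dataset sizes *M*, quantifying the experimental uncertainty attached to
   fitted kinetics from sparse series.
3. **Hydrodynamic features.** Classical scale-up quantities
   (*Re* = ρND²/μ, *u*<sub>tip</sub> = πND, ε̄ = N<sub>p</sub>ρN³D⁵/V) and
   validated ingestion of CFD-derived feature tables (means and quantiles
   of shear rate, turbulent dissipation, kinetic energy, velocity).
4. **Regression workflow.** Standardized preprocessing (log₁₀ *J*,
   train-split-only scaling, one-hot impeller type), Pearson-correlation
   feature reduction, a model zoo (linear/ridge/LASSO/random
   forest/gradient boosting/kNN plus univariate and constant-value
   benchmarks) with leave-one-out validation and error-band performance
   metrics (% of predictions within the estimator's MAE at *M* = 5 and
   *M* = 20).
5. **Ensembles and interpretation.** A *J*-model and a *t*<sub>g</sub>-model
   are ensembled through the Poisson model to predict full induction-time
   distributions for unseen vessel configurations
   (`ensemble_predict()`, `evaluate_ensemble()`), and Shapley-value
   attributions (`feature_attribution()`) rank which hydrodynamic features
   drive the kinetics.

The packaged fixtures carry the studied vessel geometries (100 mL / 1 L /
10 L with retreat-curve and pitched-blade impellers) and the fitted
kinetics table for 17 configurations (131 induction-time observations,
14 training / 3 testing). Raw induction-time series and CFD field values
for the original study are not publicly deposited, so the synthetic-data
module (`generate_study()`) fabricates feature tables and induction times
with a *known* ground-truth mapping, making the whole downstream workflow
testable against truth.

## Worked example

```r
library(nucleokin)

params <- distribution_params(J = 0.1, tg = 10000)   # 10 L-scale kinetics
obs <- generate_induction_times(params, volume = 0.01, M = 20, seed = 42,
                                config_id = "demo_10L_RC")
induction_summary(obs)
#>   config_id       n mean_s median_s
#> 1 demo_10L_RC    20 11331.   11048.

fit_mle(obs)
#> Induction-time fit (mle): J = 0.0829 #/(m^3 s), t_g = 10125 s, RMSE = 0.04256

bootstrap_fit(obs, n_boot = 1000, base = "mle", seed = 42)
#> Induction-time fit (mle_bootstrap): J = 0.08835 #/(m^3 s), t_g = 10154.6 s, RMSE = 0.04477
#>   bootstrap: n = 1000 (skipped 0), std J = 0.0181, std t_g = 77.27 s
```

The MLE recovers the generating kinetics to within its sampling error: the
growth time estimate is the smallest observed induction time (10,125 s vs
the true 10,000 s — always biased high, by about 1/(J·V·M)), and the
bootstrap spread (±0.018 #/(m³·s), ±77 s) quantifies what 20 observations
can resolve.

The full pipeline — synthetic study, kinetics estimation, error bands,
feature reduction, model zoo, ensembles, attribution — runs as one call:

```r
run <- run_pipeline(run_config(seed = 1, benchmark = list(n_datasets = 200L)))
run
#> nucleokin pipeline run (seed 1): 17 configurations
#>   kinetics estimator: mle; reduced features: volume, impeller_speed, sr_mean,
#>   ep_mean, k_mean, U_mean, axial_mean, radial_mean
#>   ensemble J6 + T6: pooled RMSE 0.282 (benchmark 0.479)
```

Here the 24 hydrodynamic features collapse to 8 under the 0.95 Pearson
threshold, the best leave-one-out models for log₁₀ *J* and *t*<sub>g</sub>
are ensembled, and the predicted induction-time distributions for the
three held-out configurations score a pooled RMSE of 0.28 in cumulative
probability — well below the 0.48 of the no-CFD/no-ML benchmark ensemble
(tip-speed univariate *J* + per-impeller mean *t*<sub>g</sub>). Every
intermediate table is written to the run directory as CSV.

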