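# pstrim — weight trimming for propensity score weighting

`pstrim` is a simulation laboratory for a practical question in
observational epidemiology: when propensity score weights misbehave, does
*trimming* the large ones help, and does the answer depend on how the
propensity scores were estimated?

Propensity score weighting by the odds estimates the average treatment
effect among the treated (ATT): treated subjects get weight 1, untreated
subjects get

$$w_i = \frac{p_i}{1 - p_i},$$

where $p_i = \Pr(A_i = 1 \mid x_i)$ is the propensity score.  A
misspecified propensity model can hand a few untreated subjects enormous
weights that dominate the weighted estimate.  Weight trimming (truncation)
replaces every weight above a cutpoint $w_0$ with $w_0$, where $w_0$ is a
percentile of the weight distribution — scanned here from the 99th to the
50th percentile at 1% steps (100 = no trimming).

The package provides, as composable pieces with a classed S3 interface:

* **a scenario-based data generator** — $n = 500$ subjects, 10
  correlated covariates (6 thresholded to binary), binary exposure from a
  true logistic model in three scenarios of increasing non-additivity and
  non-linearity, continuous outcome with true exposure effect $-0.4$
  (`scenario_spec()`, `simulate_dataset()`, `simulate_study()`);
* **four propensity estimators** — main-effects logistic regression,
  CART, random forests (out-of-bag votes), and boosted trees stopped at
  the iteration minimizing mean weighted Kolmogorov–Smirnov covariate
  imbalance (`fit_propensity()`, `weighted_ks()`);
* **ATT odds weighting and percentile trimming** (`odds_weights()`,
  `trim_weights()`, `trim_grid()`);
* **weighted least-squares effect estimation** with model-based or
  sandwich standard errors (`estimate_effect()`);
* **a Monte-Carlo metrics engine** — absolute percent bias, mean reported
  SE, the Monte-Carlo SD of the estimates, 95% CI coverage, weight
  distribution diagnostics, between-method Spearman correlations of
  weights, and optimal-trim-level lookup (`performance_table()`,
  `weight_diagnostics()`, `optimal_trim_level()`);
* **an orchestrated experiment runner** over the full factorial
  (scenario × method × trim level × replicate) with deterministic
  seeding, CSV persistence and plotting (`run_experiment()`,
  `summarize_experiment()`, `plot_trim_curves()`), plus a thin CLI at
  `inst/scripts/pstrim`.

## A worked example

One replicate under the most misspecified scenario, comparing the
untrimmed logistic-regression weighted estimate with trimming at the 90th
percentile:

```r
library(pstrim)

spec <- scenario_spec(3)          # moderate non-additivity/non-linearity
d    <- simulate_dataset(spec, n = 500, seed = 1)
fit  <- fit_propensity(d, "logistic")
ws   <- odds_weights(fit, d$exposure)
ws
#> ATT odds weights (logistic): 271 exposed (weight 1), 229 unexposed
#>   trim percentile: none
#>   unexposed weights: q1 0.485, median 0.901, q3 1.467, max 8.578

estimate_effect(d, ws)
#> ATT estimate: -0.5844 (SE 0.1090, 95% CI -0.7985 to -0.3702) [model variance]
#>   weights: logistic, trim percentile 100

estimate_effect(d, trim_weights(ws, 90))
#> ATT estimate: -0.4901 (SE 0.1075, 95% CI -0.7013 to -0.2790) [model variance]
#>   weights: logistic, trim percentile 90
```

The true effect is $-0.4$: in this replicate the untrimmed misspecified
fit overshoots by 46%, and capping the largest unexposed weights at the
90th-percentile cutpoint pulls the estimate back toward the truth.
Single replicates are noisy, so the real object of interest is the
Monte-Carlo experiment:

```r
cfg <- run_config(scenarios = 1:3, methods = "logistic",
                  trim_grid = 50:100, n_reps = 1000)
ex  <- run_experiment(cfg)
summ <- summarize_experiment(ex)
print(subset(summ$performance, scenario == 3 & trim_percentile %in% c(100, 87),
             select = c(trim_percentile, abs_percent_bias, mc_sd,
                        coverage_percent)), row.names = FALSE)
#>  trim_percentile abs_percent_bias      mc_sd coverage_percent
#>              100        28.041740 0.10534349             81.1
#>               87         2.358501 0.07702548             98.7
plot_trim_curves(ex, "bias")      # bias vs trim percentile, per scenario
```

Untrimmed, the misspecified logistic model is badly biased (≈28%) with
under-covering intervals; trimming near the 87th percentile removes most
of that bias and shrinks the estimator's sampling SD from ≈0.105 to
≈0.077.  The full four-method factorial is packaged as
`replicate_paper_config()` (612 000 records; `reduced = TRUE` for a
250-replicate version), also reachable from the shell:

```sh
Rscript inst/scripts/pstrim replicate-paper --reduced --seed 1 --out results/
```

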