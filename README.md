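# retscreen

Risk-based screening intervals for diabetic retinopathy.

Diabetic eye screening programmes photograph the retina at fixed (usually
annual) intervals and refer anyone found with sight-threatening disease.
`retscreen` implements the statistical engine for *individualised* intervals:
a continuous-time four-state Markov model of retinopathy progression —
states 1 (no retinopathy), 2 (non-referable, one eye), 3 (non-referable,
both eyes), 4 (referable / screen-positive, absorbing) — fitted to
interval-censored screening panel data. Transition intensities are
log-linear in five clinical covariates (age at diagnosis, diabetes duration,
HbA1c, total cholesterol, systolic BP),

    log λ_ij = β0_ij + Σ_C β_ij^C (x_C − x̄_C),

and time runs on a Weibull operational clock u = t^α (α ≈ 0.9: transitions
concentrate early), so interval transition probabilities are
P(t1, t2) = expm(Q (t2^α − t1^α)). Each person's probability of becoming
screen-positive within 6, 12 or 24 months is read off the (state, 4) entry
of that matrix, and they are allocated the longest interval whose risk does
not exceed an agreed threshold (2.5% by default).

The package covers the full workflow:

* panel data I/O and validation; flat-text model files (`read_panel`,
  `write_model`, ...)
* interval-censored maximum likelihood with analytic gradients (`fit_mle`),
  joint Wald statistics, AICc, and ranked nested covariate selection
  (`select_covariates`)
* chained-equations multiple imputation for fitting and 75th-percentile
  worst-case imputation for deployed prediction (`multiple_impute`,
  `worst_case_impute`)
* risk prediction and threshold-based interval allocation (`predict_risk`,
  `allocate_interval`, `predict_cohort`)
* internal validation and policy accounting: concordance index,
  fixed-horizon AUC/sensitivity/specificity, fourfold cross-validation,
  bootstrap optimism, 2-year episode accounting (`kfold_validate`,
  `bootstrap_optimism`, `episode_accounting`, `allocation_error_rates`)
* an exact event-driven cohort simulator whose defaults reproduce reference
  hazard ratios and 1-year baseline transition probabilities
  (`simulate_cohort`, `calibrate_baseline_intensities`)

See `vignettes/risk-engine-methods.Rmd` for the methods account.

## Worked example

```r
library(retscreen)

# a synthetic cohort: 1,000 subjects, ~annual visits, 5% missing covariates
d <- simulate_cohort(sim_config(n_subjects = 1000, miss_rate = 0.05, seed = 42))
d
#> Screening panel: 1000 subjects, 4925 episodes, 42 screen-positive
#> Covariates: age_at_diagnosis, disease_duration, hba1c, total_cholesterol,
#>   systolic_bp (1247 missing values)

imp <- multiple_impute(d, m = 10, seed = 42)
fit <- fit_mle(imp$datasets[[1]], c("disease_duration", "hba1c", "systolic_bp"))
fit
#> Panel MLE fit: log-likelihood -2528.41, 25 parameters, 1000 subjects
#> Four-state retinopathy transition model
#>   Weibull shape alpha: 0.8892
#>   Baseline intensities exp(intercept):
#>     1-2     2-1     2-3     2-4     3-2     3-4
#> 0.24710 1.22597 0.51430 0.01518 0.91341 0.08114
#>   Per-unit hazard ratios:
#>     disease_duration   hba1c systolic_bp
#> 1-2          1.03144 1.00727     1.01220
#> ...
```

The fitted shape (0.889) says progression risk is front-loaded; the
baseline intensities are per year of operational time for a person at
cohort-mean covariates; each hazard ratio multiplies one transition
intensity per unit of covariate (e.g. one extra year of diabetes duration
raises the 1→2 intensity by 3.1%).

```r
fit$model$percentile75 <- worst_case_reference(d)   # for missing-at-prediction
pred <- predict_cohort(fit$model, d, threshold = 0.025)
#> Warning: 42 subject(s) already screen-positive were skipped
table(pred$interval_months)
#>   6  12  24
#> 108  98 752

episode_accounting(as.integer(table(factor(pred$interval_months,
                                           levels = c(6, 12, 24)))))
#> Screening episodes over 2 years (6m/12m/24m multipliers 4/2/1)
#>   persons: 108 / 98 / 752   episodes: 432 / 196 / 752
#>   total 1380 vs annual reference 1916 (-536, -28.0%)
```

About 75% of the cohort earns a 24-month interval, and the individualised
policy needs 28% fewer screening episodes over two years than blanket
annual screening of the same people.

A thin command-line front end over the same functions is installed at
`inst/cli/retscreen.R` (subcommands `simulate`, `fit`, `predict`,
`evaluate-policy`).

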