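# glovekin

Quantitative analysis of finger-opposition motor performance from
sensor-glove touch-event streams, for researchers studying fine hand motor
impairment — in particular in multiple sclerosis (MS), where the standard
disability scale (EDSS) is weighted toward ambulation and misses early upper
limb involvement.

Subjects cycle thumb-to-finger touches (index → medium → ring → little) in
60-s trials, self-paced at spontaneous (SV) or maximal (MV) velocity, or
metronome-paced at 2 Hz uni- (2HZ) or bimanually (2HZ_BIM), while a glove
records every contact at 1 kHz. From each trial the package extracts

* **TD** — touch duration, the thumb-finger contact time (ms),
* **ITI** — inter-tapping interval, the gap to the next contact (ms),
* **RATE** = 1000 / (mean TD + mean ITI) (Hz),
* **IHI** — inter-hand interval, the mean absolute left-right onset
  difference in bimanual trials (ms); larger IHI = worse bimanual
  coordination,

and carries them through the full analysis chain:

* **Reliability** — two-way random-effects absolute-agreement ICC (single and
  average measures), SEM, and the smallest real difference
  SRD = 1.96·√2·SD·√(1−ICC) with SRD% of the grand mean;
* **Group statistics** — Mann-Whitney comparisons (exact for small samples),
  age-adjusted partial Spearman correlations against clinical scales (EDSS,
  MSFC, 9-HPT, T25W, PASAT, MFIS), and an ANOVA linear-trend test across
  EDSS strata;
* **Finger Motor Impairment score** — forward stepwise logistic regression
  (likelihood-ratio entry at α = 0.05, age forced, IHI on the natural-log
  scale); the score is the linear predictor over the selected motor
  features. Discrimination is evaluated by ROC/AUC with DeLong inference and
  leave-one-out cross-validation;
* **Synthetic cohorts** — a calibrated generator (group laws from published
  means ± SEM, Gaussian-copula clinical covariates, simulated paced and
  self-paced event streams) so every stage is testable without patient data.

See `vignettes/glovekin-methods.Rmd` for the models, calibrations and design
decisions.

## Worked example

Simulate a cohort of 80 controls and 40 patients at the default
(publication-matched) profile, extract kinematics, and build the impairment
score:

```r
library(glovekin)
set.seed(2026)

cfg <- paper_defaults(n_hc = 80, n_ms = 40)
sim <- simulate_cohort(cfg)
params <- extract_params(sim$trials)
features <- merge(params_wide(params),
                  sim$cohort[, c("subject_id", "group", "age")],
                  by = "subject_id")

group_comparison(features, sim$cohort)
#>                 label mean_hc sem_hc mean_ms sem_ms        p
#> 1      RATE (SV) [Hz]    2.41 0.0533    2.03  0.101 7.20e-04
#> 2      RATE (MV) [Hz]    3.24 0.0579    2.68  0.102 1.26e-05
#> 3      TD (2 Hz) [ms]  216.86 4.4572  249.63 11.468 3.03e-03
#> 4     ITI (2 Hz) [ms]  280.08 5.5145  258.14  9.544 7.17e-02
#> 5 IHI (2 Hz_bim) [ms]   18.02 0.7692   35.64  4.248 6.09e-06
```

Patients are slower in both self-paced conditions, hold contacts longer when
paced, and show roughly double the bimanual asynchrony — each mean lands
within sampling error of the configured group laws.

```r
model <- stepwise_logistic(features, features$group)
model
#> <fmi_model> finger motor impairment score
#>   selected: log_ihi, rate_mv, rate_sv
#>   forced  : age
#>   log_ihi  OR = 9.365 (95% CI 3.259-26.908)
#>   rate_mv  OR = 0.136 (95% CI 0.046-0.398)
#>   rate_sv  OR = 0.189 (95% CI 0.067-0.536)

roc_auc(fmi_score(model, features), features$group)
#> <roc_result> AUC = 0.887 (95% CI 0.826-0.949, p = 3.79e-35); 40 pos / 80 neg

loo_cv_auc(features, features$group, selected = model$features)$auc
#> [1] 0.855
```

Log-IHI enters with an odds ratio well above 1 (asynchrony marks
impairment), the rates below 1 (speed protects); the apparent AUC of ~0.89
drops only slightly under leave-one-out. The score separates disability
strata with a strong monotone trend, already distinguishing the lowest
strata from controls:

```r
meta <- merge(features, sim$cohort[, c("subject_id", "edss")],
              by = "subject_id")
tr <- edss_strata_trend(fmi_score(model, features),
                        edss_strata(meta$group, meta$edss))
tr$strata
#>      stratum  n   mean   sem
#> 1         HC 80 -1.471 0.164
#> 2     EDSS 0  6 -0.443 0.236
#> 3   EDSS 1-2 14  1.118 0.660
#> 4 EDSS 2.5-4 16  2.237 0.390
#> 5    EDSS >4  4  2.698 1.232
tr$trend_p
#> [1] 2.7e-08
```

## Pipeline and CLI

`run_pipeline()` chains simulate → extract → reliability → compare →
correlate → score → report into a directory of provenance-stamped CSV/JSON
outputs (re-runs with the same seed are byte-identical):

```sh
Rscript inst/cli/glovekin.R run --seed 7 --out runs/demo --skip reliability
```

Subcommands `simulate … report` run the pipeline up to that stage; flags:
`--config PATH` (JSON, see `write_sim_config()`), `--seed INT`, `--out DIR`,
`--profile paper_defaults`, `--skip STAGE[,STAGE]`, `--n-hc/--n-ms/--n-retest`,
`--sessions N`.

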