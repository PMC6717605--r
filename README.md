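# swallowscreen

Development and evaluation tooling for **accelerometry-based swallow
screening** in adults at risk of oropharyngeal dysphagia. The package
is aimed at researchers building or auditing device classifiers that
detect impaired swallowing from neck-surface vibration signals, with
simultaneous videofluoroscopy (VFSS) as the reference standard.

Dysphagia splits into two deficits, each with its own binary reference
label per administered bolus:

* **safety** — airway invasion, rated on the 8-point
  Penetration–Aspiration Scale (PAS): scores 1–2 safe, 3–8 unsafe
  (PAS 8 = silent aspiration);
* **efficiency** — pharyngeal residue filling ≥ 50% of the valleculae
  and/or pyriform sinuses.

A participant is impaired on a consistency if **at least one** bolus of
that consistency is impaired (the roll-up rule). The classifier is a
**regularized linear discriminant** with a single shared covariance,

&nbsp;&nbsp;&nbsp;&nbsp;Σ<sub>reg</sub> = (1 − λ)·Σ<sub>pooled</sub> + λ·v̄·I,

whose posterior probability of impairment is averaged over a
participant's first boluses (up to 4 thin / 3 thicker) for
participant-level screening. Accuracy is estimated by **Monte-Carlo
repeated random sub-sampling**: 10,000 participant-stratified 80/20
splits, refitting each time, reporting bolus- and participant-level
ROC AUC and operating-point sensitivity/specificity as mean ± SD
across iterations.

The package covers the full chain:

| stage | functions |
|---|---|
| data model & dialects | `cohort()`, `read_cohort()`, `recording()`, `read_recording()` |
| reference labels | `map_pas_to_safety()`, `map_residue_to_efficiency()`, `rollup_participant()`, `apply_stopping_rules()` |
| cohort summaries | `prevalence_summary()`, `cumulative_detection_curve()`, `silent_aspiration_summary()` |
| signal processing | `preprocess()` (0.1 Hz high-pass + 1 kHz low-pass Butterworth, zero phase), `segment_swallows()`, `energy_envelope()` |
| features | `extract_features()` (30 time/spectral/wavelet features), `build_feature_table()` |
| classifier | `fit_rlda()`, `predict_proba()`, `select_shrinkage()` |
| evaluation | `make_split()`, `roc_auc()`, `operating_point()`, `monte_carlo_evaluate()`, `run_suite()`, `validation_sample_size()` |
| synthetic data | `simulate_cohort()`, `simulate_recording()`, `make_table2_fixture()` |
| orchestration | `run_pipeline()`, `sws_cli()` |

The original study recordings were never deposited, so a synthetic
subsystem generates cohorts with the published outcome structure and
dual-axis burst signals with ground-truth annotations; every pipeline
stage is tested against closed-form or brute-force oracles on that
synthetic world. See `vignettes/methods.Rmd` for the full methods
account, including which published numbers are arithmetically
irreproducible (two cells; the tests assert them anyway and are
deliberately red there).

## Worked example

Reconstruct the deterministic outcome fixture and summarise it:

```r
library(swallowscreen)
fx <- make_table2_fixture()
prevalence_summary(fx)
#> Prevalence of impaired swallowing safety and efficiency
#> consistency        outcome      boluses      n      %    parts      n      %
#> thin               safety          1730    125    7.2      305     70   23.0
#> thin               efficiency      1716    115    6.7      305     60   19.7
#> mildly_thick       safety           866     51    5.9      302     42   13.9
#> mildly_thick       efficiency       872     86    9.9      302     54   17.9
#> moderately_thick   safety           833     17    2.0      281     14    5.0
#> moderately_thick   efficiency       830     75    9.0      280     51   18.2
#> extremely_thick    safety           794     11    1.4      268     10    3.7
#> extremely_thick    efficiency       794     67    8.4      268     48   17.9

cumulative_detection_curve(fx, "thin", "safety")
#>    1    2    3    4    5    6
#>  7.5 15.0 18.4 22.2 23.4 25.6
silent_aspiration_summary(fx, "thin")$pct
#> [1] 7.5
```

Each row gives the impaired count and percentage at bolus and
participant level; e.g. 7.2% of rateable thin boluses were unsafe,
rolling up to 23.0% of participants, and 7.5% of participants
aspirated silently (PAS 8) on at least one thin bolus. The cumulative
curve shows what fraction of participants had revealed their
impairment by each thin bolus — the flattening after bolus four is why
participant scores average only the first four thin boluses.

End-to-end on fully synthetic signals (fast mode: 60 participants,
200 iterations, 4 kHz):

```r
co <- simulate_cohort(cohort_sim_params(n_participants = 60, seed = 61))
p  <- signal_sim_params(fs = 4000, duration_s = 3, class_effect = 1,
                        seed = 7100)
co <- simulate_cohort_recordings(co, p, consistency = "thin",
                                 outcome = "safety")
ft  <- build_feature_table(co, pipeline_config())
monte_carlo_evaluate(ft, "thin", "safety",
                     pipeline_config(n_iterations = 200), seed = 62)
#> <sws_eval> thin / safety (200 iterations, 0 skipped)
#>   bolus AUC         96.4 +/-  2.9 %
#>   participant AUC   90.4 +/-  9.6 %
#>   sensitivity       90.5 +/- 16.2 %
#>   specificity       59.7 +/- 14.1 %
```

With a unit class effect injected into impaired trials, the pipeline
recovers it well above chance; specificity sits at the configured 60%
operating target. (These numbers characterise the synthetic world, not
the clinical device.)

Sample size for a fixed-design validation study:

```r
validation_sample_size(prevalence = 0.60)
#> sample size N = 532 (exact binomial; sens 0.86 vs null 0.7, spec 0.6
#> vs null 0.5, alpha 0.05 one-sided each, joint power 0.903 >= 0.9)
```

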