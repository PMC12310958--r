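# rehabdst

Decision-support tools for robotic upper-limb rehabilitation, built on a
systematic data-management chain for the kinematic time series that
rehabilitation robots record during serious-game therapy.

Post-stroke patients play virtual exercises ("serious games") mediated by a
planar rehabilitation robot. Every round yields high-level kinematic
features (work, speed, precision, smoothness, energy), and the therapist
sets three difficulty parameters per session: stiffness and weight
(Low/Mid/High) and viscosity (Low/High). From these logs the package builds
two tools:

* an **outcome predictor** — a six-layer stacked LSTM (32 tanh units per
  layer, 20% dropout after each, a time-distributed dense head) that emits,
  at *every* time-step of a patient's series, the predicted discharge
  scores on three clinical scales: ARAT ∈ [0, 57], FMA ∈ [0, 66],
  MI ∈ [0, 100];
* a **difficulty recommender** — three LSTM classifiers that read the last
  *L* time-steps (stiffness: 2×64 units, L = 3; weight: 1×32, L = 3;
  viscosity: 1×64, L = 5) and predict the therapist's next level choice per
  parameter.

The data-management chain turns per-round logs into model-ready tensors:
automode (passive) rounds are excluded but counted; same-day rounds of a
game are averaged into sessions; kinematic features recorded by fewer than
70% of the games are dropped; missing values fill from same-date means and
then forward; patients need ≥ 10 distinct therapy dates and complete
discharge assessments; every series is harmonized to exactly 64 time-points
by masked zero-padding or by a deterministic date-group shrinking
algorithm; each time-step becomes a 36-feature vector (3 demographics + 16
kinematics + 3 robot parameters + 7 one-hot game + 7 time-related
features), normalized to [0, 1] by invertible, training-fold-only maxima.

Random-forest baselines (outcome: 300 trees / depth 10 / min split 5 / min
leaf 20; recommendation: 350/15/5/5), patient-level k-fold evaluation with
pooled per-session RMSE/MAE and OA/F1, MCID-based grouping of prediction
errors (±10% of each scale), and normalized permutation feature importance
complete the workflow. Since clinical datasets of this kind are
request-only, a seeded synthetic-cohort generator with latent ground truth
(per-day ability, true recovery rate) stands in for real data in all tests.

The recurrent engine itself (stacked-LSTM forward/backward, RMSprop/Adam,
dropout, masking) is implemented in the package in C++ (RcppArmadillo),
single-threaded and bit-reproducible under a seed.

## Worked example

```r
library(rehabdst)

# a 30-patient synthetic cohort with a persistence-biased therapist policy
cfg <- sim_config(n_patients = 30, seed = 42, noise_sd = 0.05,
                  therapist_persistence = 0.9)
cohort <- simulate_cohort(cfg)

prep <- prepare_cohort(cohort$rounds, cohort$patients,
                       cfg$game_feature_masks)
prep
#> Prepared cohort: 26 patients, 1537 sessions on a 64-point grid, 16 kinematic features retained
prep$report
#> Patient exclusions: 30 in, 26 retained (2 missing post assessment, 2 with too few attendances)

# train/test split by patient, normalizer fitted on training patients only
folds <- make_cv_folds(prep$patients$patient_id, k = 5, seed = 1)
test_ids <- folds$folds$fold1
train_ids <- setdiff(prep$patients$patient_id, test_ids)
state <- fit_normalizer(
  prep$sessions[prep$sessions$patient_id %in% train_ids, ],
  prep$patients[prep$patients$patient_id %in% train_ids, ],
  prep$features)
train <- assemble_cohort_tensor(prep, state, train_ids)
test <- assemble_cohort_tensor(prep, state, test_ids)
train
#> Cohort tensor: 20 patients x 64 time-points x 36 features (1200 real time-steps)

# outcome DST with the engine's recommended training profile
fit <- outcome_lstm(train, stable_outcome_config(n_ensemble = 2))
pred <- predict(fit, test, denormalize = TRUE)
round(tail(pred[[1]], 2))  # predicted discharge scores at the last 2 steps
#>       arat fma mi
#> [37,]   54  63 96
#> [38,]   54  63 96
# this patient's actual discharge scores were ARAT 53, FMA 61, MI 93

# pooled per-session test error (normalized scale), vs the trivial baseline
agg <- aggregate_session_errors(predict(fit, test), test$labels,
                                list(fold1 = test_ids))
agg$rmse
#> [1] 0.1241403 0.1244953 0.1247601
base <- cohort_mean_predictor(train)
aggregate_session_errors(predict(base, test), test$labels,
                         list(fold1 = test_ids))$rmse
#> [1] 0.1472951 0.1463185 0.1463806

# next-session difficulty recommendation
cfg_s <- difficulty_model_config("stiffness")
rec_fit <- difficulty_lstm(build_lookback_windows(train, cfg_s$lookback),
                           cfg_s)
wte <- build_lookback_windows(test, cfg_s$lookback)
mean(predict(rec_fit, wte)$class == wte$labels$stiffness)  # held-out OA
#> [1] 0.9592476
```

The predicted discharge triple is available at every time-step, so the same
model monitors an ongoing therapy. The recommender's held-out accuracy is
against the levels the simulated therapist actually chose next.

## Command line

A thin CLI over the same functions ships in `inst/cli/rehabdst`:

```sh
Rscript inst/cli/rehabdst simulate --seed 7 --out demo/
Rscript inst/cli/rehabdst run-all --config run.yaml --out demo/
```

`run-all` writes the session logs, exclusion report, fold metrics and
summary tables (CSV/JSON) to the output directory.

## Package layout

* `R/simulate.R` — synthetic cohort generator and therapist policy
* `R/ingest.R`, `R/features.R` — round logs to sessions, time features
* `R/normalize.R`, `R/harmonize.R`, `R/tensors.R` — scaling, 64-grid,
  tensors and lookback windows
* `src/lstm.cpp` — the recurrent engine
* `R/models.R` — the two DSTs, baselines, random forests
* `R/evaluate.R` — metrics, CV drivers, MCID, permutation importance
* `vignettes/rehabdst-methods.Rmd` — models, assumptions, numerical
  choices, limitations
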