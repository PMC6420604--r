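# ictalloop

Analytics for closed-loop optogenetic seizure experiments on single-channel
ECoG (electrocorticogram) recordings.

In the pilocarpine model of acute focal cortical seizures, each
electrographic discharge opens with a large negative *sentinel spike*. A
closed-loop system detects that spike online by voltage threshold crossing
and triggers a 10-s light pulse after a programmed delay (0, 0.5, 2 or
\>2 s), on alternate trials only, so that every photostimulated seizure can
be compared to the immediately preceding unstimulated one. The effect of
photostimulating an interneuron population (PV+ or SOM+, depolarized by
ChR2 or hyperpolarized by Arch, with or without KCC2 overexpression in
principal cells) is summarized as the **normalized seizure duration**

    ND = 100 * T_stimulated / T_control   (percent)

averaged first within animal and then across animals. `ictalloop`
implements this analysis pipeline end to end, for people who need to
simulate, benchmark or reanalyze such experiments:

* **`synthetic ECoG generator`** — seeded, with complete ground truth:
  quiescent baseline, brief interictal bursts (State 1), discrete seizures
  with sentinel spikes and a high-frequency body (State 2), continuous
  epileptiform activity (State 3), and per-condition stimulation effects on
  seizure duration (`generate_recording()`, `condition_profile()`).
* **Feature extraction** — min-max scaling, 10-s epochs, the fixed
  20-feature set (moments, prominence-based peaks/valleys, eight Morlet
  wavelet powers, baseline points) (`epoch_features()`).
* **Network-state classifier** — seeded probability random forest over the
  four states with the 2x confidence rule for mixed-state exclusion, ROC /
  macro-F1 evaluation that enforces by-animal splits, and a 3-D LDA
  projection (`train_state_classifier()`, `classify_epochs()`,
  `lda_project()`).
* **Closed-loop path** — robust auto-threshold, causal threshold-crossing
  onset detector, alternate-trial scheduler with randomized delays and
  ≥20-s spacing, full session simulation (`detect_onsets()`,
  `schedule_stimulations()`, `run_closed_loop_session()`).
* **Seizure analysis** — offline event segmentation, paired
  stimulated-vs-control comparison with the control-substitution rule,
  pre/during/post light-window analysis, the reshuffled pseudo-stimulation
  null, per-animal aggregation, paired t and repeated-measures ANOVA with
  Bonferroni post hocs (`segment_events()`, `pair_trials()`,
  `window_analysis()`, `reshuffle_null()`, `rm_anova_bonferroni()`).

Everything downstream of the raw signal is tabular: functions take and
return tibbles, results have `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` figures, and a thin command-line front end
(`exec/ictal-loop`, plus `run_pipeline()`) ties the stages together over
EDF/CSV artifacts.

## Worked example

Simulate a small PV-ChR2 cohort with immediate (0-s delay) photostimulation,
then run the paired analysis:

```r
library(ictalloop)
library(dplyr)

prof <- condition_profile("PV_ChR2")        # 0-s multiplier 0.655, >2-s 1.351
pol  <- scheduler_policy(delay_weights = c("0" = 1))
cohort <- simulate_cohort(prof, n_animals = 3, pol, duration = 600, seed = 42)

pairs <- bind_rows(lapply(cohort, function(s) {
  rec <- minmax_scale(s$recording)
  pair_trials(segment_events(rec), s$stim_log)
}))
res <- group_normalized_duration(pairs)
res
#> <group_result> normalized duration 66.0 +- 0.2% (35 trials in 3 animals)
#>   two-tailed paired t-test: t(2) = -11.61, p = 0.00734
tidy(res)
#> # A tibble: 3 x 5
#>   animal_id mean_normalized_pct mean_stim_duration_s mean_control_duration_s
#> 1 m01                      66.5                 2.68                    4.10
#> 2 m02                      66.0                 2.26                    3.32
#> 3 m03                      65.7                 2.46                    3.68
```

The generator programmed a duration multiplier of 0.655 for this condition;
the pipeline — threshold detection, event segmentation, pairing each
stimulated seizure with the immediately preceding control, per-animal
aggregation — recovers a group mean of 66.0%, i.e. a 34% reduction in
seizure duration, with each simulated animal near the programmed value.
`autoplot(res)` draws the per-animal means against the 100% no-effect
line; `autoplot(cohort[[1]]$recording)` shows the session trace with its
state annotation.

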