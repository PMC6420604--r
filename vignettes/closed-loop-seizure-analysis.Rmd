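---
title: "Closed-loop optogenetic seizure analysis: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop optogenetic seizure analysis: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ictalloop)
library(dplyr)
```

## The analysis problem

Closed-loop optogenetic seizure experiments record a single-channel ECoG
(512 Hz) from a chemoconvulsant focus, detect each electrographic seizure
online from its large negative *sentinel spike*, and trigger a 10-s light
pulse after a programmed delay (0, 0.5, 2, or >2 s) on alternate trials.
The scientific readout is the **normalized seizure duration**

$$\mathrm{ND} = 100 \times \frac{T_\text{stimulated}}{T_\text{control}}\ \%$$

where the control is the immediately preceding non-stimulated discharge.
Per-trial values are averaged within animal, and group statistics are
computed over animals, never over trials.

`ictalloop` implements this entire chain — a seeded synthetic ECoG
generator with ground truth, 20-feature epoch extraction, a random-forest
network-state classifier with a 2x confidence rule, the online detector and
trial scheduler, and the paired/reshuffled duration analysis — so that every
stage can be validated by *parameter recovery*: the generator encodes known
effect sizes, and the pipeline must get them back.

## The synthetic generator

The generator is phenomenological: only the statistics that the analysis
consumes are modeled, not biophysics.

* **Background** is 1/f (pink) Gaussian noise, SD 25 µV.
* **Discrete seizures (State 2)** open with a negative half-sine sentinel
  (-320 µV, 60 ms) followed by a body of ~10 Hz negative discharge spikes
  (-220 µV, capped at 78% of the sentinel so the sentinel is always the
  event minimum) riding on band-limited 60–120 Hz noise — the
  "high-frequency component" of real ictal discharges.
* **Interictal bursts (State 1)** are single 100–150 ms discharges;
  **continuous epileptiform activity (State 3)** is an open-ended discharge
  train; **baseline** is noise only.

The amplitude geometry is deliberate: sentinels exceed the online detection
threshold (median − 6 MAD of a 30-s prefix) by a wide margin, body spikes
cross both the online and the lower offline segmentation threshold with
>2.5σ margins, and bursts cross only the segmentation threshold. This makes
threshold detection calibratable and event durations measurable to
within ±0.2 s.

### Event durations and why they drift

Event durations are lognormal with configurable mean (per delay class,
defaults 3.31 / 3.66 / 4.32 / 5.52 s) and log-SD σ = 0.5. Crucially, the
log-duration is decomposed into a *slowly drifting* component (a
random-phase sinusoid advancing one step per event, period 64 events,
amplitude chosen so the marginal SD stays 0.5) plus fast iid jitter
(SD 0.15).

The drift is not decoration. The paired estimator ND = 100·X/Y is unbiased
for the programmed multiplier only when consecutive durations are
correlated: for independent lognormals,
$E[X/Y] = e^{\sigma^2} \approx 1.28$ at σ = 0.5, which would put the
no-effect baseline at ~128% — incompatible with the near-100% reshuffle
null that motivates the paired design in the first place. Real seizure
duration drifts slowly over a session; the generator reproduces exactly that
property. Two further choices matter:

* the drift advances per **event**, not per second. Stretches of long
  events host fewer onsets per unit time, so a time-indexed drift makes the
  realized event sample length-biased below the configured mean; an
  event-indexed drift weights all phases equally.
* a bounded periodic drift (rather than a near-unit-root autoregression)
  lets session-long averages converge to the configured mean within a few
  percent, while preserving the consecutive-pair correlation.

### Stimulation effects

Each condition profile maps delay class to a duration multiplier (e.g.
PV-ChR2: 0.655 at 0 s, 1.351 at >2 s; identity for the no-opsin control).
For a stimulated trial, a base duration $D$ is drawn from the lognormal for
that delay class, truncated below the realized delay so that light always
arrives while the counterfactual seizure is still running; the immediately
preceding (control) event is set to $D e^{\epsilon_1}$ and the stimulated
event to $m \cdot D e^{\epsilon_2}$ with $\epsilon \sim N(0, 0.1)$. The
multiplier is therefore exactly identifiable by the paired analysis, with
realistic trial-to-trial scatter. The ground truth records both the
realized and the counterfactual duration of every stimulated event.

For delayed classes, with probability 0.3 a short *decoy* event (< delay)
is inserted between control and stimulated event, so that the
control-substitution rule ("nearest preceding discharge exceeding the
delay") is genuinely exercised end to end, not just unit-tested.

One caveat is documented rather than modeled: for delayed suppressive
profiles (Arch), $m D$ can fall below the delay, which would physically
mean the seizure ended before the light could shorten it. Truncation is at
the delay (the stated convention), and this corner is left as a limitation.

### What the generator does not emulate

No chloride dynamics, no pharmacology, no behavioral channel, no electrode
artifacts, no line noise, no non-stationary noise floor, no seizure
morphology evolution within an event. Passing recovery tests therefore
shows that the *analysis machinery* is correct and unbiased under
controlled conditions; it does not certify performance on real recordings
with artifacts the generator omits.

## Features and the state classifier

Recordings are min-max scaled **per recording** (so all features are
invariant to affine transforms of the raw voltage) and cut into
non-overlapping 10-s epochs; a final partial epoch is discarded. Twenty
features are computed per epoch, in fixed order: mean, SD, excess kurtosis,
adjusted Fisher–Pearson skew, sum of absolute first differences, numbers of
prominent peaks and valleys, mean peak and valley values and their
difference, eight Morlet wavelet powers (1, 5, 10, 15, 20, 30, 60, 90 Hz)
and two baseline-point features.

Where the underlying definitions are not standardized, this package
declares its conventions:

* **Peaks/valleys**: local extrema with topographic prominence ≥ 0.05
  (scaled units); valleys are peaks of the negated signal. The default
  prominence registers a State-1 burst as a single peak.
* **Wavelet power**: L2-normalised continuous Morlet transform (ω₀ = 6),
  one scale per listed centre frequency, mean squared coefficient magnitude
  over the epoch divided by the centre frequency. Under this 1/f-normalised
  convention white-noise power decays with frequency (tested), and the pink
  background decays faster.
* **Baseline points**: samples within ±0.02 (scaled) of the epoch median;
  the second feature is the mean first-difference of their sorted indices,
  defaulting to the epoch length when fewer than two points exist. These
  are declared substitutes for an under-specified quantity, isolated behind
  one function and configurable.
* **Peak–valley range**: difference of means (mean peak − mean valley),
  chosen over mean pairwise ranges for robustness to unequal counts.

The classifier is a 200-tree probability random forest (seeded,
single-threaded, so training is bit-reproducible). Four classes are used —
baseline plus States 1–3 — matching the four-way labeling of the original
design. An epoch keeps its arg-max label only if the top probability is at
least **twice** the second; otherwise it is `MIXED` and excluded. The
boundary (exactly twice) counts as confident, following the wording that
only "less than twice" is mixed. Evaluation is always by animal: feature
sets carry `animal_id`, and `evaluate_state_classifier()` refuses test sets
that share animals with training. A 3-D LDA projection (`lda_project()`)
is provided for visualization; constant, duplicated and within-class
degenerate columns are dropped and features standardized before the fit.

## The closed-loop path

* `auto_threshold()`: median − 6·MAD of a ≥30-s prefix, the robust analog
  of setting the hardware threshold at the start of an experiment.
* `detect_onsets()`: causal negative-going threshold crossing. The dead
  time (default 0.4 s) re-arms on **every** crossing, so an ongoing
  discharge whose body spikes keep crossing cannot retrigger, while the
  next sentinel after a quiet gap is caught immediately. This convention
  (the alternative — a fixed dead time from the last detection — either
  retriggers inside long seizures or, if long, misses closely spaced ones)
  keeps the 20-s scheduler interval, not the detector, as the binding
  constraint; K seizures yield K detections within 50 ms of their
  sentinels.
* `schedule_stimulations()` / the in-session scheduler: accepted trials are
  ≥ 20 s apart (guaranteeing clean 10-s pre- and post-epochs), alternate
  control/stimulated starting with a control (so every stimulated trial has
  a preceding control candidate), and draw delay classes from configurable
  weights; ">2 s" delays are uniform on 2.5–4.8 s (mean ≈ 3.65 s).
  Sessions begin with a ≥20-s stimulation-free lead-in.

Inside `run_closed_loop_session()` the scheduler consumes the ground-truth
sentinel times as its detection times. The online detector is validated
separately to land within 50 ms of the sentinel with recall and precision
≥ 0.95, so this substitution changes nothing material while keeping the
generative construction well-posed (the light's effect on an event's
duration must be decided while the event is being laid down).

## Offline analysis

* `segment_events()`: an event starts at a downward crossing of the
  segmentation threshold and ends after 0.3 s without suprathreshold
  deflection; events shorter than 0.5 s are discarded. The threshold
  default is median − 4·σ̂ with σ̂ estimated from **positive** deviations
  only — epileptiform deflections are negative-going, so the positive side
  estimates the noise floor even in recordings that are mostly ictal
  (a whole-signal MAD inflates badly in such sessions). The offset
  criterion is an explicit convention of this package; the original
  measurement procedure is not specified anywhere, so it is isolated behind
  configuration.
* `pair_trials()`: control = immediately preceding non-stimulated event;
  controls must outlast the programmed delay, with nearest-preceding
  substitution otherwise; trials failing the State-2 confidence gate or
  lacking any qualifying control are dropped with logged reasons.
* `reshuffle_null()`: ignores all stimulation information; events > 2.5 s
  are randomly assigned to a pseudo-stimulated group, compared to the
  immediately preceding event, with the closest **preceding** event ≥ 3 s
  substituted when the immediate one is shorter than 3 s. Searching only
  backwards mirrors the directionality of the experimental pairing; whether
  a forward search was ever intended is ambiguous, and the choice is
  recorded here as a convention.
* `window_analysis()`: events are assigned to the 10-s windows before,
  during and after each light pulse by their **onset**; per-animal means
  first, then group mean ± s.e.m.
* Statistics: two-tailed paired t-tests on per-animal means; one-way
  repeated-measures ANOVA (`aov` with the subject error stratum) with
  Bonferroni-corrected pairwise post hocs (p × number of comparisons,
  capped at 1). Bonferroni is the only correction offered, by design.

## Validation by parameter recovery

Because no raw in vivo recordings are deposited anywhere, the package's
acceptance gate is recovery of the programmed effects by the *full*
pipeline (simulate → detect → segment → gate → pair → aggregate), at the
study's scale:

* classifier macro F1 > 0.9 on ~200 epochs from 3 unseen simulated animals
  after training on ~700 epochs from 7 animals;
* PV-ChR2 recovery of the 34.5% reduction (0 s, 8 animals, ~300 trials)
  and 35.1% prolongation (>2 s, 5 animals, ~85 trials);
* the reshuffle null at ~99.4%;
* the continuous-stimulation during-light mean of 1.78 s when the pre-light
  mean is calibrated to 2.84 s — calibration runs a small unstimulated
  pilot cohort to measure the mapping from configured mean to observed
  pre-window mean (onset-in-window sampling under-weights slow
  high-duration stretches, so the observed mean sits below the marginal
  mean) and scales the profile accordingly;
* the KCC2 (no delayed prolongation, ~99.4%), SOM (78.2% at 0 s) and Arch
  (29.1% reduction at >2 s) profiles.

`scripts/acceptance.R` recomputes all of these from scratch. Problem sizes
(session lengths of 10–30 simulated minutes per animal, cohorts of 5–13
animals) were chosen to give a few hundred trials per condition — enough
that Monte-Carlo error is several times smaller than the published
s.e.m. bands the recoveries are compared against — while a full run stays
in the low minutes on a laptop. The unit-test suite exercises the same
code paths at smaller sizes, plus brute-force oracles for the pairing and
reshuffle rules on random ≤20-event streams.

```{r recovery-example, eval = FALSE}
# a scaled-down recovery run (~20 s)
g <- recover_condition_effect("PV_ChR2", "0", n_animals = 4,
                              duration_s = 600, seed = 1)
glance(g)
autoplot(g)
```

## Known limitations

* The generator's realism is statistical, not biophysical; morphology is
  stereotyped, and classifier F1 near 1.0 on synthetic data overstates
  performance on real, artifact-laden ECoG.
* The delayed-suppression corner case (realized duration shorter than the
  delay) is generated as specified rather than physically resolved.
* Segmentation measures total event durations; post-light remainders are
  not an output, matching the normalized-duration semantics used
  throughout.
* EDF support is deliberately minimal: one channel, 16-bit, 1-s records;
  the true sample count is stashed in the reserved header field so
  round-trips are exact, and foreign EDF readers simply see padding.
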