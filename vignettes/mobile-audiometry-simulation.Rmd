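---
title: "Simulating biologically calibrated mobile audiometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating biologically calibrated mobile audiometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Hearing self-tests on phones face one fundamental obstacle: every handset
model has a different acoustic output, so the same commanded level produces
different sound pressures at the ear. Clinical audiometers solve this with
laboratory calibration against a standard (dB HL, where 0 dB HL is the
average normal-hearing threshold at each frequency). A consumer app cannot
calibrate millions of devices in a lab, but it can calibrate *biologically*:
let self-declared normal-hearing users measure their own thresholds, and
define the model-specific reference — 0 dB **mHL** (mobile hearing level) —
from the crowd's central tendency, corrected by the literature median
threshold of the same age group. `hearsim` implements that whole pipeline in
silico: synthetic listeners with known true thresholds, the three
measurement procedures, the crowd calibration estimator, and the agreement
and screening statistics by which such a system is validated against
clinical pure-tone audiometry.

Because every listener is synthetic, every procedure's output can be
compared against the hidden truth it estimates — something no clinical
study can do.

## The listener model

A listener is a row of hidden state: continuous true thresholds $T_{e,f}$
for both ears over the grid 250 Hz–8 kHz, plus psychometric response
parameters. A single yes/no presentation at effective level $L$ is heard
with probability

$$P(\text{heard}) = g + (1 - g - \ell)\,\Phi\!\left(\frac{L - (T + s)}{\sigma}\right),$$

with guess rate $g$ (default 0.02), lapse rate $\ell$ (0.02), spread
$\sigma$ (3 dB — a typical pure-tone detection spread) and a per-exam
session offset $s \sim N(0, 2.5^2)$ representing headphone repositioning
and day-to-day variation; 2.5 dB is chosen so the simulated test–retest
difference SD lands near the 4.4 dB such studies report. Setting
$\sigma = 0$ gives the exact deterministic limit (hears iff
$L \ge T + s$), which the exactness tests rely on: a presentation exactly
at threshold under a tiny-but-positive $\sigma$ would be a coin flip.

When the contralateral ear is unmasked, the tone also reaches the other
cochlea attenuated by the interaural attenuation (40 dB, supra-aural
convention), and the tone is detected if either ear's detector fires;
masking (triggered above 40 dB on the measurement scale) removes that path
entirely. No central masking or overmasking is modelled, since only the
masking trigger is specified by the validated procedure.

Three hearing classes generate cohorts with the composition of the
validation study (36/70 normal, 21/70 sensorineural, 13/70
conductive/mixed):

* **normal** — $T \sim N(5, 5^2)$ per frequency, truncated to
  $[-10, 20]$ dB HL, so a normal listener always passes the 25 dB
  normal-hearing screen;
* **sensorineural** — a flat base severity (15/25/40/55 dB with weights
  .4/.3/.2/.1) plus a $+10$ dB/octave slope above 1 kHz and
  $N(0, 5^2)$ per-frequency noise (presbycusis-like profiles);
* **conductive/mixed** — a flat elevation uniform on $[20, 50]$ dB plus
  the same per-frequency noise.

Loss classes receive a between-ear asymmetry $\pm a/2$,
$a \sim N(0, 5^2)$. These archetypes reproduce the qualitative marginal
spread of a mixed clinic cohort; the exact shapes are free parameters of
the generator, not estimates.

## The measurement procedures

**Clinical bracketing (`hughson_westlake`)** — the conventional
10-down/5-up staircase from 40 dB HL: drop 10 dB after each heard
response, rise 5 dB after each miss; the threshold is the lowest level
heard on at least 2 of up to 4 ascending presentations. For a
deterministic listener this returns exactly the smallest 5 dB grid level
$\ge T$. The clinical audiometer is modelled as perfectly calibrated, so
its results live on the true dB HL scale. Results the staircase cannot
bracket inside the output range are flagged (`below_min`/`above_max`) and
carry no threshold.

**Self-adjustment (`self_adjust_test`)** — the app procedure: the listener
steps the level down in 5 dB steps while hearing and up while not, and
confirms the lowest audible level. The validated procedure only says the
user confirms "barely audible"; we define confirmation as the up-reversal
pattern (miss at $L-5$, hear at $L$) observed **twice** at the same level
(`confirm_repeats = 2`). With a single observation, one attention lapse
during the initial descent terminates the test with a gross overestimate
often enough to push the simulated test–retest SD far above anything a
usable self-test shows; requiring the pattern twice makes a false stop need
two lapses at the same level ($\ell^2$) while leaving
deterministic-listener behaviour exactly the smallest grid level $\ge T$.
Levels are commanded in dB mHL; the device maps them through its
calibrated reference, so the level at the ear is
`level + reference - instance_offset` and any reference error shifts all
measured thresholds linearly (tested exactly).

**Bekesy tracking (`bekesy_track`)** — the calibration measurement: the
level falls 1 dB per tick while the "I can hear" button is held and rises
while released; the raw threshold is the mean midpoint of 4 reversal pairs
after discarding the first 2 reversals. It runs on the raw command scale
over (-30, 100) dB — deliberately wider than the guaranteed (-10, 80)
dB mHL test range, because after calibration the command for a given mHL
level shifts by the reference, and clamping raw tracks at the mHL limits
would selectively censor sensitive listeners on loud devices (we measured
that censoring to bias the crowd percentile by up to +2.5 dB before
widening the range). The track starts at 50 dB, comfortably suprathreshold
for any eligible calibrator. A track is invalid when it cannot collect its
reversals, reverses within 3 ticks of the start (a listener who cannot
hold a response to a clearly audible tone), touches the hardware limits at
a reversal, or spreads its pair midpoints by more than 6 dB. These checks
are what make grossly inattentive listeners (lapse rates far beyond the
normal range) fail calibration instead of polluting it.

## The crowd calibration estimator

For each device model, 0 dB mHL is defined per frequency as

$$\text{reference}_f = Q_{0.37}(\text{raw thresholds}_f) - \text{median}^{lit}_f,$$

over the most recent session of each distinct device, from users aged
18–35 (closed interval), with at least 15 distinct devices required before
the reference is usable. $Q_{0.37}$ is the 37th percentile with linear
interpolation between order statistics (`stats::quantile` type 7 — the
definition is fixed and documented because the estimator's source does not
state one). The design logic: if 26% of self-declared normal-hearing
calibrators are actually impaired and their thresholds sit above the clean
crowd's upper range, then $0.37 = 0.5 \times 0.74$ puts the mixture's 37th
percentile exactly at the clean population's median. Two consequences worth
stating plainly:

* at the design contamination rate the estimator recovers the true device
  offset up to sampling noise (the package's recovery experiment verifies
  ±1.5 dB at 500 sessions);
* on a perfectly clean crowd it *undershoots* the clean median by about
  $0.33\,\sigma_{crowd}$ (≈ 1.8 dB under the default archetype), and at
  contamination far above design (60%) it breaks down upward by several
  dB. Both behaviours are asserted in the tests as documented properties,
  not defects.

The literature median defaults to 5 dB at every frequency — the median of
the package's own normal-hearing archetype — so that the simulated mHL
scale aligns with the simulated HL scale (self-consistency). Supply real
literature values when modelling a specific population; the percentile is
applied per frequency independently, with no cross-frequency smoothing.

## The study pipeline

`run_study()` chains the stages exactly as a crossover validation would:
generate the device fleet (8 models, per-frequency output offsets
$N(0, 5^2)$, device-to-device spread 2 dB); generate the crowd (240 users,
26% contamination) and 30 calibration sessions per model (each a distinct
device — comfortably above the 15-device validity minimum); fail loudly if
any model cannot be calibrated; generate the 70-subject cohort; assign a
counterbalanced order (35 clinical-first, 35 mobile-first) and one fresh
device instance per subject; run the clinical exam once and the mobile test
twice (test and retest, separate session offsets); then compute the
order-effect comparison, per-frequency and pooled agreement tables (mean
difference with normal-approximation CI, SD with chi-square CI, mean
absolute difference, consistency ICC, cumulative difference shares),
Cronbach alpha, and screening sensitivity/specificity. One global seed is
expanded into independent per-stage streams, so changing one stage's draw
count does not perturb the others, and a (config, seed) pair reproduces the
report bit for bit.

Statistical conventions, chosen to reproduce the validation study's
printed accounting and intervals: differences are oriented clinical minus
mobile; every ear×frequency record is treated as independent (the study's
"Total n" counts cells, not subjects — a faithful-replication choice, not a
statistical endorsement; no mixed-effects correction for within-subject
clustering is attempted); mean CIs use z rather than t quantiles (at these
n they reproduce the printed intervals; `use_t` switches); the ICC is the
two-way random-effects consistency form for single measurements with the
F-ratio interval, and alpha's interval maps through the exact k = 2
identity $\alpha = 2\,\mathrm{ICC}/(1+\mathrm{ICC})$; sensitivity and
specificity use Wald intervals clipped to [0, 100]% (Wilson by flag);
missing and out-of-range cells are treated identically (discarded), and
rounding to the printed precision happens only at the formatting boundary
(`format_agreement`, `study_tables`).

The screening criterion reads its source literally: loss iff the threshold
strictly exceeds 30 dB at one of 500/1000/2000 Hz, or 25 dB at two or more
of them, or 50 dB at 4 kHz. The screening unit is the ear (the agreement
analysis is per-ear; a worse-ear subject-level rule would be a trivial
wrapper). In the simulated screening experiment, out-of-range cells are
scored as censored infinities, which is the only information an
out-of-range flag carries.

```{r}
library(hearsim)
report <- run_study(study_config(), seed = 1)
report
glance(report)
study_tables(report)$agreement
```

## What the generator does and does not emulate

The synthetic data reproduce: the cohort composition and age structure,
the 5 dB measurement grid, per-model and per-device output offsets,
psychometric response noise with session-to-session shifts, a
self-selected 18–35 calibration crowd with impaired contamination, device
dynamic-range censoring (the few-percent out-of-range discard rates emerge
at realistic magnitudes), and the counterbalanced test/retest design.

They do **not** emulate: ambient noise during uncontrolled calibration or
testing, ear-canal and transducer acoustics, listener learning or fatigue,
non-stationary attention beyond the constant lapse rate, or real handset
coefficients. The main observable consequence is that the simulated
between-method difference SD (about 6 dB under defaults, as the acceptance
script reports) sits below clinical field values (~8 dB): in the field, a
large share of that variance is calibration performed in uncontrolled
acoustic conditions, which is out of scope here. Passing tests therefore
demonstrate the correctness of procedures and statistics and the internal
consistency of the calibration logic — not that a real deployment would
achieve any particular agreement with clinical audiometry.

## Numerical choices and degenerate inputs

Problem sizes in the shipped tests are chosen for sub-minute feedback:
500-replicate Monte-Carlo checks for staircase bias, 500-session
calibration recovery, and the full 70-subject study (≈ 15 s) run twice for
the determinism check. Midpoint grid rounding goes away from zero
(symmetric for negative levels). Staircases that keep responding at the
output floor, or keep missing at the ceiling, flag `below_min`/`above_max`
after two pinned responses; a threshold exactly at the floor is
indistinguishable from one below it and is reported as censored. Degenerate
statistics (zero total variance for ICC, zero variance of sums for alpha,
truth vectors without positives or negatives) raise errors rather than
returning conventional values.
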