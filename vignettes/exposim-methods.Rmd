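---
title: "Methods: the virtual-patient engine and the bounded-outcome trial analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the virtual-patient engine and the bounded-outcome trial analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exposim)
```

# Overview

`exposim` has two halves that meet in the middle:

1. a **deterministic, headless simulator** of a virtual patient used for
   experiential exposure-therapy training — a clinician titrates exposure
   difficulty on a 10-task hierarchy while the patient's Subjective Units of
   Distress (SUDS, 0–10) habituate over time; and
2. an **analysis toolkit** for the kind of small randomized training trial
   such a simulator is evaluated in: bounded questionnaire outcomes measured
   repeatedly in two arms, analyzed with binomial-logit marginal models fit
   by estimating equations, sandwich covariance, orthogonal contrasts, and
   Holm multiple-testing control — plus a synthetic-trial generator so the
   whole pipeline is testable without any real participant data.

This vignette records the model, its assumptions, the tunable parameters,
and every place where the design was genuinely open and a choice had to be
made. It states no empirical result that the package's tests and acceptance
script do not themselves compute.

# The virtual-patient engine

## State machine and clock

The patient is a state machine over integer seconds on a 15 s tick grid.
A session consists of **9 decision points**; the initial task selection (from
anywhere on the hierarchy) counts as decision 1, decisions 2–9 follow at
**45 s intervals**, and the session ends one decision interval after the
last decision, at t = 405 s. Whether "9 decision points" includes the
initial selection is genuinely ambiguous in the source design; we adopted
the inclusive reading (the decision sequence "begins with the initial task
selection") and made the count configurable (`n_decision_points`).

At each decision the therapist may keep the current task or move to any task
within **2 hierarchy positions** (`reach`, frozen at session start), the
training-design constraint that prevents large jumps in exposure intensity.

## SUDS dynamics

Three rules govern distress:

* **Habituation.** SUDS drops 1 point after every 120 s of *continuous*
  exposure to the same task (`habituation_interval_seconds`), floored at 0.
  "Continuous" is read literally: any task change resets the habituation
  clock. Holding one task from t = 0 therefore gives the closed form
  `suds(t) = max(0, L - floor(t/120))`, which the tests check against the
  tick loop.
* **Elicitation.** The deployed system does not document how SUDS responded
  to task changes, so the package makes the rule explicit and configurable:
  entering task *p* evokes SUDS `L(p) = p` (monotone difficulty→distress).
  Upward moves set SUDS to the new task's elicitation level; downward moves
  set it to `min(current, L(p'))` — easing never *raises* distress; keeping
  the task leaves SUDS unchanged.
* **Bounds.** SUDS is clamped to [0, 10] at all times; the property suite
  verifies bound conservation under random policies.

Verbalization cues fire every tick, keyed to a coarse distress band
(low ≤ 3, moderate 4–7, high ≥ 8 by default). The deployed system names
distress states but not thresholds; these edges are a package choice, shared
with the feedback rubric and configurable in both places. Cues are template
identifiers, not audio — assets are out of scope.

All events (session start/end, decisions with their offered option sets,
task selections, habituation updates, SUDS checks, cues) go to an
append-only log serialized as JSONL (header object with schema version,
config and hierarchy snapshot + digest; one JSON object per event). The
reader rejects unknown schema versions, and replaying a log's decisions
through the engine must reproduce its SUDS trajectory exactly.

Engine dynamics are fully deterministic; random seeds affect only policy
randomness.

## Policies

Scripted policies stand in for trainees: `gradual_titration_policy(theta)`
(step up one rung whenever observed SUDS ≤ θ, never step down — the idealized
graded delivery the training nudges learners toward), `avoidant_policy`
(retreat when SUDS reaches a panic threshold — the premature-easing pattern
linked to suboptimal exposure delivery), `fixed_policy` and
`random_policy`. Policies observe SUDS through `suds_check()`, so SUDS-check
events appear in logs at each decision point, as they would for a trainee
sampling distress. Between repetitions the program is reset: the patient
remembers nothing; only hierarchy and config carry over
(`reset_for_repetition()`).

## Feedback rubric

The post-session feedback screen is reconstructed as data: the SUDS
trajectory plus one classified item per decision. The deployed system's
feedback text and rubric are not documented; the rubric here is an explicit
modeling stance (thresholds shared with the distress bands, all
configurable): decreases are always flagged `avoidant_retreat`; increases
are `well_timed_advance` at low SUDS, `aggressive_advance` for jumps of ≥ 2
positions or at high SUDS; holding is `supported_persistence` at high SUDS
and `missed_opportunity` at low SUDS; anything else is `acceptable`.
Classification is total and deterministic (exhaustively enumerated in the
tests). Messages are fixed templates — no language generation, and no claim
of validated pedagogical scoring.

# The trial analysis

## Binomial rescaling

Every outcome is bounded, so each score is shifted by its minimum possible
value to give binomial "successes", with the score range as "trials":
TBES 21 → (21, 84); self-efficacy 27 → (0, 108); knowledge 50% → (50, 100).
Percent-scored knowledge gives non-integer successes; the estimating
equations work on proportions with trials as prior weights, so they are
quasi-binomial by construction and never require integrality. (An exact
alternative is to register knowledge on its 0–12 correct-count grid via
`measure_spec()`; the machinery is agnostic.)

## Marginal model and sandwich covariance

For the three longitudinal measures the mean model is **saturated** over the
8 arm × timepoint cells on the logit scale, fit by Fisher-scoring
generalized estimating equations with participants as clusters. The working
correlation defaults to **independence** — the sandwich keeps contrast
inference valid regardless of the true correlation, and with a saturated
mean structure the point estimates are then exactly the tabulated cell
proportions (a test oracle) — with **exchangeable** available as an option.
The covariance is the classical (Liang–Zeger) sandwich with no small-sample
correction, matching the stated analysis. Convergence tolerance is 1e-10 on
the max coefficient update, 50 iterations maximum; with one observation per
cluster the sandwich reduces to the HC0 covariance of the corresponding
quasi-binomial GLM (checked numerically).

Cells observed entirely at a boundary (all scores at the floor or ceiling)
would have infinite logits; they receive a 0.5 continuity adjustment to
successes and failures, and are reported in the fit's `adjusted_cells`.

## Contrasts, Holm, effect sizes

Sixteen orthogonal linear contrasts over the 8 cell logits, in three
families: within-condition changes (T1−T0, T2−T1, T3−T1, T3−T2 in each arm;
8), cross-sectional arm comparisons at each timepoint (4), and arm
differences in the four change definitions (4). The source design states
only the family sizes (8/4/4); the change-definition composition is inferred
from the reported tables (changes from baseline and from post-didactic, plus
the post-experiential→follow-up maintenance comparison). Whether the Holm
family spans measures jointly was ambiguous; the default is one family of 16
per measure, holding familywise α at .05 within each measure's GEE
hypotheses.

Contrast tests default to a standard-normal reference; a t reference with
user-chosen df is available (`analyze_trial(df = )`) because the reported
df in the source trial (117) is not derivable from the design quantities.

Cohen's *d* formulas are explicit package choices (none are stated in the
source): within-condition change uses mean(change)/SD(change) over
participants; cross-sectional uses the mean difference over the pooled SD;
difference-in-change uses the pooled SD of change scores. Cell CIs are
unadjusted Wald intervals on the logit scale back-transformed to the score
scale.

Endpoint measures (SUS, virtual-patient evaluation, TARS subscales) are
collected once; each gets a binomial-logit two-group comparison with
sandwich covariance and exactly one unadjusted hypothesis test.

# The synthetic-trial generator

The generator emulates the trial's *design*: 2 arms (n = 20 headset / 21
desktop), 4 timepoints, 3 bounded longitudinal measures, complete data (the
real trial had no attrition and no missing items, so no missingness is
modeled). Participant *i* draws a latent effect `b_i ~ N(0, subject_sd²)` on
the logit scale, and each cell score is
`total_min + Binomial(range, plogis(qlogis(mu_cell) + b_i))`, with the
published group means by timepoint as default cell means (knowledge is drawn
on its 0–12 grid, then converted to percent). The model is deliberately the
analysis model's data-generating twin: its purpose is parameter recovery and
error-rate measurement, not replication of the raw data.

Choices a user should know about:

* `subject_sd = 0.6` — the real within-participant correlation is
  unreported; 0.6 on the logit scale yields T0–T3 score correlations in the
  0.4–0.6 range typical of repeated questionnaire measures. Chosen once,
  documented here, not tuned. Correlation increases monotonically in
  `subject_sd` (tested), and `subject_sd = 0` gives independence.
* Cell SDs are matched only approximately (binomial + subject effect), not
  fitted to the published SDs.
* Endpoint means for SUS are the published 86.2/93.4; the virtual-patient
  evaluation and TARS totals are *not* published, so their defaults are
  invented "positive in both groups" values — synthetic stand-ins, clearly
  overridable.

What a green test does **not** establish: the generator shares the
analysis's logit-binomial skeleton, so recovery tests validate the
estimation machinery, not the model's fit to real questionnaire data (real
items are discrete, skewed, and have measure-specific ceilings the binomial
does not capture).

# Known limitations

* **Small-sample sandwich anticonservativeness.** At 41 clusters the
  classical sandwich underestimates standard errors; the acceptance suite
  measures unadjusted CI coverage of about 93% (vs the nominal 95%) and a
  familywise type-I error around 0.07–0.10 under the global null across the
  16 Holm-adjusted tests, exceeding .05. This is a property of the stated
  method at the stated sample size, reported honestly (the corresponding
  acceptance criterion fails) rather than patched with small-sample
  corrections the analysis plan does not describe.
* The engine's elicitation rule, distress-band thresholds and feedback
  rubric are explicit models of undocumented behavior, not reproductions.
* The 8 intermediate hierarchy task labels are placeholders; only the two
  endpoint tasks are anchored.
* No rendering, audio, hardware input or cloud storage; no adaptive or
  learning policies; no psychometric validation of the scored instruments.
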