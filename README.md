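# exposim

A headless virtual-patient simulator for training clinicians in graded
exposure therapy, together with the analysis toolkit for the kind of small
randomized trial such training is evaluated in.

## The problem

Exposure therapy is a first-line treatment for anxiety disorders but is
badly underused, partly because therapists hold negative beliefs about its
safety and tolerability. Experiential training — practicing exposure
delivery on a simulated, distressed patient — targets those beliefs
directly. `exposim` provides:

* **A discrete-event virtual patient.** An ordered 10-task exposure
  hierarchy (from "look at shoe" up to "touch shoe to face"); a session of 9
  therapist decision points (the initial task selection, then one every
  45 s) where moves are restricted to within ±2 hierarchy positions; patient
  verbalization cues every 15 s keyed to distress bands; and SUDS
  (Subjective Units of Distress, 0–10) that habituate by 1 point per 2
  minutes of continuous exposure: `suds(t) = max(0, L − ⌊t/120 s⌋)` for a
  task with entry level `L` held from `t = 0`. Every event goes to an
  append-only JSONL log that replays deterministically.
* **Scripted therapist policies** (gradual titration, avoidant, fixed,
  random) and a cohort simulator (3 repetitions per trainee, full reset in
  between), plus a rule-based feedback report reconstructing the
  post-session SUDS graph with a classification of every decision.
* **Instrument scorers** for SUS (0–100), TBES (0–84), exposure knowledge
  (percent of 12 items), exposure self-efficacy (27–135), TARS and a
  virtual-patient evaluation.
* **The trial analysis.** Bounded scores are rescaled to binomial
  successes/trials (`successes = score − min`, `trials = range`) and fit
  with a saturated arm × timepoint binomial-logit marginal model by
  generalized estimating equations, with the classical sandwich covariance
  clustered on participants. Sixteen orthogonal contrasts (8 within-condition
  changes, 4 cross-sectional comparisons, 4 differences in change) are
  tested with Holm step-down adjustment at familywise α = .05, with Cohen's
  *d* effect sizes and unadjusted 95% CIs back-transformed to the score
  scale. Single-timepoint endpoints get a one-hypothesis binomial GLM
  comparison.
* **A synthetic-trial generator** (2 arms, n = 20/21; 4 timepoints;
  logit-normal-binomial scores with within-participant correlation) so the
  whole pipeline is testable end to end without real data.

## Worked example

Simulate a session under the gradual-titration policy (step up a rung while
observed SUDS ≤ 4) and inspect the feedback screen:

```r
library(exposim)
h   <- load_hierarchy("shoe")
log <- run_session(h, session_config(), gradual_titration_policy(theta = 4),
                   seed = 1)
build_report(log)
#> <feedback_report ...> 9 decisions, peak SUDS 6, 2 habituation events
#> D1  t=  0s initial_select SUDS  3 |###       | start_level_note
#> D2  t= 45s increase SUDS  3 |###       | well_timed_advance
#> D3  t= 90s increase SUDS  4 |####      | acceptable
#> D4  t=135s same     SUDS  5 |#####     | acceptable
#> D5  t=180s same     SUDS  5 |#####     | acceptable
#> D6  t=225s increase SUDS  4 |####      | acceptable
#> D7  t=270s same     SUDS  6 |######    | acceptable
#> D8  t=315s same     SUDS  6 |######    | acceptable
#> D9  t=360s same     SUDS  5 |#####     | acceptable
```

The therapist started at task 3 (SUDS 3), advanced whenever distress was
tolerable, and ended holding task 6: nine decisions, two habituation drops,
no avoidant retreats.

Generate a synthetic trial and run the full analytic plan:

```r
ds  <- generate_trial(generator_config(), seed = 1)   # 41 x 4 x 3 = 492 rows
rep <- analyze_trial(ds)
rep$measures$tbes$contrasts[1:8, c("label", "p_raw", "p_holm", "cohen_d")]
#>              label        p   p_holm     d
#> 1     hmd: T1 - T0 1.47e-06 1.62e-05 -1.03
#> 2     hmd: T2 - T1 6.21e-13 8.69e-12 -1.34
#> 3     hmd: T3 - T1 1.01e-13 1.51e-12 -1.36
#> 4     hmd: T3 - T2 4.36e-01 1.00e+00 -0.17
#> 5 desktop: T1 - T0 2.72e-09 3.27e-08 -1.26
#> 6 desktop: T2 - T1 7.91e-13 1.03e-11 -1.36
#> 7 desktop: T3 - T1 6.07e-16 9.71e-15 -1.55
#> 8 desktop: T3 - T2 2.62e-03 2.62e-02 -0.64
```

Negative beliefs (TBES) fall in both arms from baseline through follow-up —
the direction and size the generator was configured with — with raw and
Holm-adjusted p values for each of the 16 hypotheses per measure, and cell
means with back-transformed 95% CIs in `rep$measures$tbes$cells`.

A command-line interface wraps the same operations:

```sh
Rscript inst/exec/exposim simulate --policy titration --theta 4 --seed 1 --out session.jsonl
Rscript inst/exec/exposim feedback --log session.jsonl --plot suds.png
Rscript inst/exec/exposim synth-trial --seed 1 --out trial.csv
Rscript inst/exec/exposim analyze-trial --input trial.csv --out-dir analysis
```

## Notes on scope and honesty

The simulator is a behavioral model, not a port: rendering, audio, hardware
and cloud storage are out of scope, and the elicitation rule, distress-band
thresholds and feedback rubric model behavior the deployed system does not
document (see the methods vignette). The analysis follows the stated plan
exactly — including the classical sandwich with a normal reference, whose
small-sample anticonservativeness at 41 clusters the test suite measures and
reports rather than papers over.
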