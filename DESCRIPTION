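Package: exposim
Title: Virtual-Patient Exposure Therapy Training Simulator and Bounded-Outcome
    Trial Analysis
Version: 0.1.0
Authors@R:
    person("Exposim", "Developers", email = "exposim@example.org",
           role = c("aut", "cre"))
Description: A headless, discrete-event simulator of a virtual patient used to
    train clinicians in graded exposure therapy: an ordered ten-task exposure
    hierarchy, a deterministic state machine with Subjective Units of Distress
    (SUDS) habituation dynamics, timed therapist decision points with a
    restricted move radius, distress-band verbalization cues, append-only
    JSONL session logs, scripted therapist policies, and rule-based decision
    feedback with SUDS trajectory plots. Also implements the companion trial
    analysis toolkit: instrument scorers (SUS, TBES, exposure knowledge and
    self-efficacy, TARS, virtual-patient evaluation), a correlated
    logit-normal-binomial synthetic trial generator for a two-arm,
    four-timepoint repeated-measures design, marginal binomial-logit models
    fit by generalized estimating equations with sandwich covariance, sixteen
    orthogonal contrasts with Holm step-down adjustment, Cohen's d effect
    sizes, and single-timepoint binomial endpoint comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
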