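#' Instrument scoring and the bounded-measure registry
#'
#' The trial's outcomes are all bounded scores: exposure knowledge (percent
#' correct on 12 multiple-choice items, 0-100), exposure self-efficacy (27
#' items on 1-5, total 27-135), the Therapist Negative Beliefs about Exposure
#' Scale (TBES; 21 items on 0-4, total 0-84), the System Usability Scale
#' (SUS; 10 items on 1-5 converted to 0-100), the Training Acceptability
#' Rating Scale (TARS; acceptability and utility subscale means) and a
#' 12-item virtual-patient evaluation.  The registry records each measure's
#' bounds, which the analysis uses to rescale scores to binomial
#' successes/trials.
#'
#' @name measures
NULL

#' Define a measure
#'
#' @param name measure identifier.
#' @param n_items number of items.
#' @param item_min,item_max per-item response bounds.
#' @param total_min,total_max bounds of the total score.
#' @param scoring one of `"sum"`, `"percent_correct"`, `"sus"`,
#'   `"subscale_means"`.
#' @return A list of class `measure_spec`.
#' @export
measure_spec <- function(name, n_items, item_min, item_max,
                         total_min, total_max,
                         scoring = c("sum", "percent_correct", "sus",
                                     "subscale_means")) {
  scoring <- match.arg(scoring)
  if (total_min >= total_max) stop("total_min must be below total_max")
  structure(list(name = name, n_items = as.integer(n_items),
                 item_min = item_min, item_max = item_max,
                 total_min = total_min, total_max = total_max,
                 scoring = scoring),
            class = "measure_spec")
}

#' Registry of the study's measures
#'
#' Longitudinal measures (`knowledge`, `self_efficacy`, `tbes`) are assessed
#' at all four timepoints; `sus`, `vp_eval` and the TARS subscales only after
#' the experiential session.  Endpoint subscale measures are registered on
#' their total-score ranges so the binomial rescaling applies uniformly.
#'
#' @return Named list of [measure_spec()] objects.
#' @export
measure_registry <- function() {
  list(
    knowledge = measure_spec("knowledge", 12L, 0L, 1L, 0, 100,
                             "percent_correct"),
    self_efficacy = measure_spec("self_efficacy", 27L, 1L, 5L, 27, 135, "sum"),
    tbes = measure_spec("tbes", 21L, 0L, 4L, 0, 84, "sum"),
    sus = measure_spec("sus", 10L, 1L, 5L, 0, 100, "sus"),
    vp_eval = measure_spec("vp_eval", 12L, 1L, 5L, 12, 60, "sum"),
    tars_acceptability = measure_spec("tars_acceptability", 6L, 1L, 6L,
                                      6, 36, "sum"),
    tars_utility = measure_spec("tars_utility", 9L, 1L, 4L, 9, 36, "sum"))
}

longitudinal_measures <- function() c("knowledge", "self_efficacy", "tbes")

check_items <- function(responses, n, lo, hi, what) {
  if (length(responses) != n) {
    stop(what, " requires exactly ", n, " responses, got ", length(responses))
  }
  if (anyNA(responses)) stop(what, ": missing items are not accepted")
  if (any(responses < lo | responses > hi)) {
    stop(what, ": responses must lie in ", lo, "..", hi)
  }
  if (any(responses != round(responses))) {
    stop(what, ": responses must be integers")
  }
  invisible(TRUE)
}

#' Score the System Usability Scale
#'
#' Standard SUS conversion: odd items contribute `response - 1`, even items
#' `5 - response`, and the total is multiplied by 2.5, giving 0-100.
#'
#' @param responses 10 integers in 1..5.
#' @return SUS score in 0..100.
#' @export
score_sus <- function(responses) {
  check_items(responses, 10L, 1L, 5L, "SUS")
  odd <- responses[seq(1L, 9L, by = 2L)] - 1
  even <- 5 - responses[seq(2L, 10L, by = 2L)]
  (sum(odd) + sum(even)) * 2.5
}

#' Score a sum- or percent-scored measure
#'
#' TBES and self-efficacy are item sums; knowledge is the percentage of the
#' 12 retained multiple-choice items answered correctly (responses coded
#' 0/1).
#'
#' @param spec a [measure_spec()] with scoring `"sum"` or `"percent_correct"`.
#' @param responses item responses.
#' @return Total score within `[total_min, total_max]`.
#' @export
score_scale <- function(spec, responses) {
  stopifnot(inherits(spec, "measure_spec"))
  check_items(responses, spec$n_items, spec$item_min, spec$item_max, spec$name)
  switch(spec$scoring,
    sum = sum(responses),
    percent_correct = 100 * sum(responses) / spec$n_items,
    stop("score_scale does not handle scoring '", spec$scoring, "'"))
}

#' Score the Training Acceptability Rating Scale
#'
#' @param acceptability 6 integers in 1..6.
#' @param utility 9 integers in 1..4.
#' @return Named numeric vector with the two subscale means.
#' @export
score_tars <- function(acceptability, utility) {
  check_items(acceptability, 6L, 1L, 6L, "TARS acceptability")
  check_items(utility, 9L, 1L, 4L, "TARS utility")
  c(acceptability = mean(acceptability), utility = mean(utility))
}

#' Score the virtual-patient evaluation
#'
#' Items 1-6 address the authenticity of working with the virtual patient;
#' items 7-12 its value as a training tool.
#'
#' @param responses 12 integers in 1..5.
#' @return Named numeric vector with the two subscale means.
#' @export
score_vp_eval <- function(responses) {
  check_items(responses, 12L, 1L, 5L, "VP evaluation")
  c(authenticity = mean(responses[1:6]),
    training_utility = mean(responses[7:12]))
}
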