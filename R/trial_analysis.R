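#' Trial analysis: contrasts, Holm adjustment, effect sizes, reports
#'
#' Implements the trial's analytic plan for the three longitudinal measures:
#' a saturated binomial-logit marginal model over the 2 x 4 arm-by-timepoint
#' cells (see [fit_marginal_binomial()]), sixteen orthogonal linear contrasts
#' in three families — within-condition changes (8), cross-sectional
#' condition comparisons at each timepoint (4), and condition differences in
#' change (4) — with Holm step-down adjustment holding familywise alpha at
#' .05 across the sixteen hypotheses, Cohen's d effect sizes, and a
#' tabular report.  Endpoint measures collected once (SUS, the
#' virtual-patient evaluation, TARS) get a single-hypothesis binomial
#' comparison of the two conditions.
#'
#' @name trial_analysis
NULL

change_definitions <- function() {
  list(c(to = "T1", from = "T0"),
       c(to = "T2", from = "T1"),
       c(to = "T3", from = "T1"),
       c(to = "T3", from = "T2"))
}

#' Build the sixteen-contrast set for the 2 x 4 design
#'
#' Contrast vectors act on the eight cell logits ordered arm-major
#' (arm 1: T0..T3, then arm 2: T0..T3).  The within-condition change family
#' uses the four change definitions T1-T0, T2-T1, T3-T1 and T3-T2 in each
#' arm (8 contrasts); the cross-sectional family compares the arms at every
#' timepoint (4); the difference-in-change family compares the arms on each
#' change definition (4).  Every contrast vector sums to zero.
#'
#' @param arms character vector of exactly 2 arm labels.
#' @param timepoints character vector of exactly 4 timepoint labels
#'   (T0..T3).
#' @return A 16 x 8 matrix of class `contrast_set` with a `family` attribute
#'   and per-row metadata in attribute `meta`.
#' @export
build_contrasts <- function(arms = c("hmd", "desktop"),
                            timepoints = c("T0", "T1", "T2", "T3")) {
  if (length(arms) != 2L || length(timepoints) != 4L) {
    stop("the contrast set is defined for exactly 2 arms x 4 timepoints")
  }
  cells <- as.vector(t(outer(arms, timepoints, cell_name)))
  unit <- function(cell) as.numeric(cells == cell)
  rows <- list()
  meta <- list()
  add <- function(label, family, vec, info) {
    rows[[label]] <<- vec
    meta[[label]] <<- c(list(label = label, family = family), info)
  }
  for (a in arms) {
    for (ch in change_definitions()) {
      lab <- sprintf("%s: %s - %s", a, ch[["to"]], ch[["from"]])
      add(lab, "within_condition",
          unit(cell_name(a, ch[["to"]])) - unit(cell_name(a, ch[["from"]])),
          list(arm = a, from = ch[["from"]], to = ch[["to"]]))
    }
  }
  for (tp in timepoints) {
    lab <- sprintf("%s: %s - %s", tp, arms[1], arms[2])
    add(lab, "cross_sectional",
        unit(cell_name(arms[1], tp)) - unit(cell_name(arms[2], tp)),
        list(timepoint = tp))
  }
  for (ch in change_definitions()) {
    lab <- sprintf("(%s - %s): %s - %s", ch[["to"]], ch[["from"]],
                   arms[1], arms[2])
    vec <- (unit(cell_name(arms[1], ch[["to"]])) -
              unit(cell_name(arms[1], ch[["from"]]))) -
           (unit(cell_name(arms[2], ch[["to"]])) -
              unit(cell_name(arms[2], ch[["from"]])))
    add(lab, "difference_in_change", vec,
        list(from = ch[["from"]], to = ch[["to"]]))
  }
  C <- do.call(rbind, rows)
  colnames(C) <- cells
  structure(C,
            family = vapply(meta, `[[`, "", "family"),
            meta = meta, class = c("contrast_set", "matrix"))
}

#' Holm step-down adjusted p values
#'
#' Sorts the raw p values ascending, multiplies the i-th smallest of m by
#' (m - i + 1), enforces monotone non-decrease down the sequence, caps at 1,
#' and returns the adjusted values in the input order.
#'
#' @param raw_p numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values, same order as the input.
#' @export
holm_adjust <- function(raw_p) {
  if (any(is.na(raw_p)) || any(raw_p < 0 | raw_p > 1)) {
    stop("p values must lie in [0, 1]")
  }
  m <- length(raw_p)
  if (m == 0L) return(numeric(0))
  o <- order(raw_p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * raw_p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Cohen's d effect sizes on the score scale
#'
#' Three variants matching the contrast families: `"change"` standardizes the
#' mean within-participant change from `from` to `to` in one arm by the SD of
#' those change scores; `"cross_sectional"` standardizes the between-arm mean
#' difference at one timepoint by the pooled SD; `"difference_in_change"`
#' standardizes the between-arm difference in mean change by the pooled SD of
#' the change scores.
#'
#' @param dataset long-format `trial_dataset`.
#' @param measure measure name.
#' @param kind effect-size variant.
#' @param arm arm label (for `"change"`).
#' @param timepoint timepoint label (for `"cross_sectional"`).
#' @param from,to timepoint labels defining a change.
#' @return Cohen's d (numeric scalar); error on zero variance.
#' @export
cohens_d <- function(dataset, measure,
                     kind = c("change", "cross_sectional",
                              "difference_in_change"),
                     arm = NULL, timepoint = NULL, from = NULL, to = NULL) {
  kind <- match.arg(kind)
  d <- dataset[dataset$measure == measure, , drop = FALSE]
  if (nrow(d) == 0L) stop("no rows for measure ", measure)
  wide_change <- function(sub) {
    a <- sub[sub$timepoint == from, c("participant_id", "score")]
    b <- sub[sub$timepoint == to, c("participant_id", "score")]
    merged <- merge(a, b, by = "participant_id", suffixes = c("_from", "_to"))
    merged$score_to - merged$score_from
  }
  pooled_sd <- function(x1, x2) {
    n1 <- length(x1); n2 <- length(x2)
    sqrt(((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) /
           (n1 + n2 - 2))
  }
  arms <- unique(d$arm)
  if (kind == "change") {
    stopifnot(!is.null(arm), !is.null(from), !is.null(to))
    ch <- wide_change(d[d$arm == arm, , drop = FALSE])
    s <- stats::sd(ch)
    if (!is.finite(s) || s == 0) stop("zero variance in change scores")
    mean(ch) / s
  } else if (kind == "cross_sectional") {
    stopifnot(!is.null(timepoint), length(arms) == 2L)
    x1 <- d$score[d$arm == arms[1] & d$timepoint == timepoint]
    x2 <- d$score[d$arm == arms[2] & d$timepoint == timepoint]
    s <- pooled_sd(x1, x2)
    if (!is.finite(s) || s == 0) stop("zero pooled variance")
    (mean(x1) - mean(x2)) / s
  } else {
    stopifnot(!is.null(from), !is.null(to), length(arms) == 2L)
    c1 <- wide_change(d[d$arm == arms[1], , drop = FALSE])
    c2 <- wide_change(d[d$arm == arms[2], , drop = FALSE])
    s <- pooled_sd(c1, c2)
    if (!is.finite(s) || s == 0) stop("zero pooled variance in change scores")
    (mean(c1) - mean(c2)) / s
  }
}

contrast_tests <- function(fit, C, conf_level = 0.95, df = Inf) {
  est <- drop(C %*% fit$coefficients)
  se <- sqrt(diag(C %*% fit$vcov %*% t(C)))
  stat <- est / se
  p <- if (is.finite(df)) 2 * stats::pt(-abs(stat), df = df)
       else 2 * stats::pnorm(-abs(stat))
  q <- if (is.finite(df)) stats::qt(1 - (1 - conf_level) / 2, df = df)
       else stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(label = rownames(C), family = attr(C, "family"),
             estimate_logit = est, se_logit = se, statistic = stat,
             p_raw = p, ci_low_logit = est - q * se,
             ci_high_logit = est + q * se, row.names = NULL)
}

#' Analyze a longitudinal trial dataset
#'
#' Runs the full analytic plan on each longitudinal measure present: the
#' saturated marginal binomial fit, the sixteen orthogonal contrasts with
#' raw and Holm-adjusted p values (one Holm family of sixteen per measure),
#' Cohen's d per contrast, and cell summaries with unadjusted Wald CIs
#' back-transformed from the logit to the score scale.
#'
#' @param dataset long-format `trial_dataset` containing the longitudinal
#'   measures.
#' @param registry measure registry supplying bounds.
#' @param working_correlation passed to [fit_marginal_binomial()].
#' @param conf_level confidence level for unadjusted CIs (default 0.95).
#' @param df reference-distribution degrees of freedom for contrast tests;
#'   `Inf` (default) uses the standard normal.
#' @return An object of class `trial_analysis_report`: per-measure fits,
#'   cell tables and contrast tables.
#' @export
analyze_trial <- function(dataset, registry = measure_registry(),
                          working_correlation = "independence",
                          conf_level = 0.95, df = Inf) {
  stopifnot(is.data.frame(dataset))
  measures <- intersect(longitudinal_measures(), unique(dataset$measure))
  if (length(measures) == 0L) stop("dataset contains no longitudinal measures")
  out <- list()
  for (m in measures) {
    fit <- fit_marginal_binomial(dataset, m, registry, working_correlation)
    C <- build_contrasts(fit$arms, fit$timepoints)
    tests <- contrast_tests(fit, C, conf_level = conf_level, df = df)
    tests$p_holm <- holm_adjust(tests$p_raw)
    meta <- attr(C, "meta")
    tests$cohen_d <- vapply(meta, function(mi) {
      switch(mi$family,
        within_condition = cohens_d(dataset, m, "change", arm = mi$arm,
                                    from = mi$from, to = mi$to),
        cross_sectional = cohens_d(dataset, m, "cross_sectional",
                                   timepoint = mi$timepoint),
        difference_in_change = cohens_d(dataset, m, "difference_in_change",
                                        from = mi$from, to = mi$to))
    }, numeric(1))
    tests <- cbind(measure = m, tests)
    out[[m]] <- list(fit = fit, cells = fit$cells, contrasts = tests)
  }
  structure(list(measures = out, conf_level = conf_level, df = df,
                 working_correlation = working_correlation),
            class = "trial_analysis_report")
}

#' All contrast rows of a report as one data.frame
#' @param report a `trial_analysis_report`.
#' @export
report_contrasts <- function(report) {
  stopifnot(inherits(report, "trial_analysis_report"))
  out <- do.call(rbind, lapply(report$measures, `[[`, "contrasts"))
  rownames(out) <- NULL
  out
}

#' Write a trial analysis report to disk
#'
#' Writes `contrasts.csv` (one row per hypothesis), `cells.csv` (group means
#' and CIs by timepoint) and `report.json` (full structure) into `dir`.
#'
#' @param report a `trial_analysis_report`.
#' @param dir output directory (created if needed).
#' @export
write_analysis_report <- function(report, dir) {
  stopifnot(inherits(report, "trial_analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  contrasts <- report_contrasts(report)
  cells <- do.call(rbind, lapply(names(report$measures), function(m) {
    cbind(measure = m, report$measures[[m]]$cells)
  }))
  rownames(cells) <- NULL
  utils::write.csv(contrasts, file.path(dir, "contrasts.csv"),
                   row.names = FALSE)
  utils::write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE)
  json <- list(
    conf_level = report$conf_level,
    working_correlation = report$working_correlation,
    df = if (is.finite(report$df)) report$df else "normal",
    measures = lapply(report$measures, function(x) {
      list(cells = x$cells, contrasts = x$contrasts,
           converged = x$fit$converged, alpha = x$fit$alpha,
           adjusted_cells = x$fit$adjusted_cells)
    }))
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.trial_analysis_report <- function(x, ...) {
  for (m in names(x$measures)) {
    cat("==", m, "==\n")
    cells <- x$measures[[m]]$cells
    cat("Group means (95% CI) by timepoint:\n")
    print(data.frame(arm = cells$arm, timepoint = cells$timepoint,
                     mean = round(cells$empirical_mean, 2),
                     sd = round(cells$empirical_sd, 2),
                     ci = sprintf("%.2f-%.2f", cells$ci_low, cells$ci_high)),
          row.names = FALSE)
    ct <- x$measures[[m]]$contrasts
    cat("Hypotheses (Holm family of", nrow(ct), "):\n")
    print(data.frame(label = ct$label, family = ct$family,
                     p = signif(ct$p_raw, 3),
                     p_adj = signif(ct$p_holm, 3),
                     d = round(ct$cohen_d, 2)),
          row.names = FALSE)
    cat("\n")
  }
  invisible(x)
}

#' Single-timepoint binomial comparison of the two conditions
#'
#' For measures collected only once (SUS, virtual-patient evaluation, TARS
#' subscales): a binomial-logit model with an arm effect, sandwich
#' covariance (one observation per participant), and exactly one hypothesis
#' test of the condition difference, unadjusted.
#'
#' @param scores data.frame with columns `participant_id`, `arm`, `score`
#'   (one row per participant).
#' @param spec the [measure_spec()] for the score.
#' @param conf_level confidence level (default 0.95).
#' @return A list of class `endpoint_analysis`: `cells` (per-arm summary) and
#'   `comparison` (a single hypothesis row).
#' @export
analyze_endpoint <- function(scores, spec, conf_level = 0.95) {
  stopifnot(is.data.frame(scores), inherits(spec, "measure_spec"))
  arms <- unique(scores$arm)
  if (length(arms) != 2L) stop("endpoint comparison needs exactly 2 arms")
  bin <- rescale_to_binomial(scores$score, spec)
  y <- bin$successes / bin$trials
  arm_f <- factor(scores$arm, levels = arms)
  # guard degenerate arms the same way as the longitudinal fit
  arm_succ <- tapply(bin$successes, arm_f, sum)
  arm_tr <- tapply(bin$trials, arm_f, sum)
  degenerate <- names(arm_succ)[arm_succ == 0 | arm_succ == arm_tr]
  if (length(degenerate)) {
    in_deg <- as.character(arm_f) %in% degenerate
    y[in_deg] <- (bin$successes[in_deg] + 0.5) / (bin$trials[in_deg] + 1)
  }
  X <- stats::model.matrix(~ 0 + arm_f)
  colnames(X) <- arms
  fit <- gee_binomial(y, bin$trials, X, cluster = scores$participant_id,
                      corstr = "independence")
  if (!fit$converged) stop("endpoint model failed to converge")
  range_ <- spec$total_max - spec$total_min
  se <- sqrt(diag(fit$vcov))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  cells <- data.frame(
    arm = arms,
    n = as.vector(table(arm_f)),
    empirical_mean = as.vector(tapply(scores$score, arm_f, mean)),
    empirical_sd = as.vector(tapply(scores$score, arm_f, stats::sd)),
    model_mean = spec$total_min + range_ * stats::plogis(fit$coefficients),
    ci_low = spec$total_min +
      range_ * stats::plogis(fit$coefficients - z * se),
    ci_high = spec$total_min +
      range_ * stats::plogis(fit$coefficients + z * se))
  rownames(cells) <- NULL
  C <- matrix(c(1, -1), nrow = 1,
              dimnames = list(sprintf("%s - %s", arms[1], arms[2]), arms))
  est <- drop(C %*% fit$coefficients)
  se_c <- sqrt(drop(C %*% fit$vcov %*% t(C)))
  stat <- est / se_c
  comparison <- data.frame(
    measure = spec$name, label = rownames(C), estimate_logit = est,
    se_logit = se_c, statistic = stat, p_raw = 2 * stats::pnorm(-abs(stat)),
    ci_low_logit = est - z * se_c, ci_high_logit = est + z * se_c,
    row.names = NULL)
  structure(list(cells = cells, comparison = comparison, fit = fit,
                 spec = spec),
            class = "endpoint_analysis")
}

#' @export
print.endpoint_analysis <- function(x, ...) {
  cat(sprintf("Endpoint comparison for '%s':\n", x$spec$name))
  print(x$cells, row.names = FALSE, digits = 4)
  print(x$comparison, row.names = FALSE, digits = 4)
  invisible(x)
}
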