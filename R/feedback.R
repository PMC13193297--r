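#' Decision feedback and SUDS trajectory reports
#'
#' After a session the trainee is shown the patient's SUDS path together with
#' targeted feedback on each decision.  The rubric here is rule-based and
#' deliberately simple, sharing its thresholds with the engine's distress
#' bands; every threshold is configurable.
#'
#' @name feedback
NULL

#' Default feedback thresholds
#'
#' @param low_max largest SUDS treated as low distress (default 3).
#' @param high_min smallest SUDS treated as high distress (default 8).
#' @param aggressive_step upward jump size flagged as aggressive (default 2).
#' @export
feedback_thresholds <- function(low_max = 3L, high_min = 8L,
                                aggressive_step = 2L) {
  stopifnot(low_max < high_min, aggressive_step >= 1L)
  list(low_max = low_max, high_min = high_min,
       aggressive_step = aggressive_step)
}

feedback_messages <- c(
  well_timed_advance   = "Good timing: distress was low, so raising the difficulty keeps the exposure productive.",
  supported_persistence = "Staying with the task while distress is high lets habituation do its work.",
  acceptable           = "A reasonable choice at this distress level.",
  missed_opportunity   = "Distress was already low; this was a chance to raise the difficulty.",
  aggressive_advance   = "This jump in difficulty risks overwhelming the patient; titrate more gradually.",
  avoidant_retreat     = "Easing the task in response to distress teaches avoidance; consider holding instead.",
  start_level_note     = "Starting level noted; any entry point on the hierarchy is workable.")

#' Classify one therapist decision
#'
#' Deterministic rubric over (action, magnitude, SUDS at decision):
#' \itemize{
#'   \item any decrease: `avoidant_retreat`;
#'   \item increase by `aggressive_step` or more, or any increase at high
#'     SUDS: `aggressive_advance`;
#'   \item increase at low SUDS: `well_timed_advance`;
#'   \item keep-same at high SUDS: `supported_persistence`;
#'   \item keep-same at low SUDS: `missed_opportunity`;
#'   \item the initial selection: `start_level_note`;
#'   \item everything else: `acceptable`.
#' }
#'
#' @param action one of `"increase"`, `"decrease"`, `"same"`,
#'   `"initial_select"`.
#' @param magnitude signed position change.
#' @param suds SUDS observed at the decision.
#' @param thresholds a [feedback_thresholds()] list.
#' @return Classification string.
#' @export
classify_decision <- function(action, magnitude, suds,
                              thresholds = feedback_thresholds()) {
  th <- thresholds
  switch(action,
    initial_select = "start_level_note",
    decrease = "avoidant_retreat",
    increase = {
      if (magnitude >= th$aggressive_step || suds >= th$high_min) {
        "aggressive_advance"
      } else if (suds <= th$low_max) "well_timed_advance" else "acceptable"
    },
    same = {
      if (suds >= th$high_min) "supported_persistence"
      else if (suds <= th$low_max) "missed_opportunity" else "acceptable"
    },
    stop("unknown action: ", action))
}

#' Build a feedback report from a session log
#'
#' Reconstructs the post-session feedback screen: the SUDS trajectory over
#' the whole session plus one classified feedback item per decision point,
#' and summary statistics.
#'
#' @param log a complete `session_log`.
#' @param thresholds a [feedback_thresholds()] list.
#' @return A list of class `feedback_report` with elements `session_id`,
#'   `trajectory` (data.frame `t`, `suds`, `kind`), `items` (data.frame, one
#'   row per decision point) and `summary`.
#' @export
build_report <- function(log, thresholds = feedback_thresholds()) {
  validate_session_log(log, complete = TRUE)
  dps <- log_events(log, "decision_point")
  items <- do.call(rbind, lapply(dps, function(ev) {
    p <- ev$payload
    cls <- classify_decision(p$action, p$magnitude, p$suds_before, thresholds)
    data.frame(decision_index = as.integer(p$index), t_seconds = ev$t,
               suds_at_decision = as.integer(p$suds_before),
               action = p$action, magnitude = as.integer(p$magnitude),
               classification = cls,
               message = unname(feedback_messages[[cls]]))
  }))
  rownames(items) <- NULL
  traj <- log_suds_trajectory(log)
  class_counts <- table(factor(items$classification,
                               levels = names(feedback_messages)))
  summary <- list(
    counts = as.list(class_counts),
    peak_suds = max(traj$suds),
    mean_suds = mean(traj$suds),
    habituation_events = length(log_events(log, "suds_update")),
    final_suds = traj$suds[nrow(traj)])
  structure(list(session_id = log$session_id, trajectory = traj,
                 items = items, summary = summary, thresholds = thresholds),
            class = "feedback_report")
}

#' Write a feedback report as JSON
#' @param report a `feedback_report`.
#' @param path output file.
#' @export
write_feedback_report <- function(report, path) {
  stopifnot(inherits(report, "feedback_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Render the SUDS trajectory
#'
#' Purely presentational: writes a step plot of SUDS versus time with the
#' decision points marked (PNG or SVG, when `file` is given) and returns a
#' monospaced text chart with one row per decision point.  Values are taken
#' verbatim from `report$trajectory`.
#'
#' @param report a `feedback_report`.
#' @param file optional image path ending in `.png` or `.svg`.
#' @param quiet suppress printing of the text chart.
#' @return The text chart lines, invisibly.
#' @export
render_trajectory <- function(report, file = NULL, quiet = FALSE) {
  stopifnot(inherits(report, "feedback_report"))
  traj <- report$trajectory
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    dev <- switch(ext,
                  png = function() grDevices::png(file, width = 720, height = 480),
                  svg = function() grDevices::svg(file, width = 7.5, height = 5),
                  stop("unsupported image format: ", ext))
    dev()
    on.exit(grDevices::dev.off())
    graphics::plot(traj$t, traj$suds, type = "s", ylim = c(0, 10),
                   xlab = "time (s)", ylab = "SUDS",
                   main = paste("SUDS trajectory -", report$session_id))
    dp <- report$items
    graphics::points(dp$t_seconds, dp$suds_at_decision, pch = 19,
                     col = "firebrick")
    graphics::text(dp$t_seconds, dp$suds_at_decision, labels = dp$decision_index,
                   pos = 3, cex = 0.8)
  }
  lines <- vapply(seq_len(nrow(report$items)), function(i) {
    it <- report$items[i, ]
    bar <- paste(rep("#", it$suds_at_decision), collapse = "")
    sprintf("D%-2d t=%3ds %-8s SUDS %2d |%-10s| %s", it$decision_index,
            it$t_seconds, it$action, it$suds_at_decision, bar,
            it$classification)
  }, "")
  if (!quiet) cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.feedback_report <- function(x, ...) {
  cat(sprintf("<feedback_report %s> %d decisions, peak SUDS %d, %d habituation events\n",
              x$session_id, nrow(x$items), x$summary$peak_suds,
              x$summary$habituation_events))
  render_trajectory(x)
  invisible(x)
}
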