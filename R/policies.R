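#' Scripted therapist decision policies
#'
#' Policies stand in for human trainees when exercising the engine in bulk.
#' A policy bundles an initial-task rule with a decision function mapping the
#' observed SUDS, the current position, the offered option set and the
#' decision index to a chosen position (always within the offered set).
#'
#' @param name short policy name.
#' @param decide `function(suds, position, allowed, index)` returning a
#'   position from `allowed`.
#' @param initial `function(h)` returning the initial task position.
#' @param params named list of policy parameters, kept for provenance.
#' @param seed optional default seed used by [run_session()] when no seed is
#'   passed explicitly.
#' @return An object of class `exposure_policy`.
#' @export
exposure_policy <- function(name, decide, initial, params = list(),
                            seed = NULL) {
  stopifnot(is.function(decide), is.function(initial))
  structure(list(name = name, decide = decide, initial = initial,
                 params = params, seed = seed),
            class = "exposure_policy")
}

#' @export
print.exposure_policy <- function(x, ...) {
  ps <- if (length(x$params)) {
    paste0("(", paste(names(x$params), unlist(x$params), sep = "=",
                      collapse = ", "), ")")
  } else ""
  cat(sprintf("<exposure_policy %s%s>\n", x$name, ps))
  invisible(x)
}

#' Gradual titration policy
#'
#' Idealizes the graded delivery style the training nudges learners toward:
#' step up one hierarchy position whenever the patient's observed SUDS is at
#' or below the tolerance threshold `theta`, otherwise hold the current task;
#' never move down.
#'
#' @param theta SUDS threshold at or below which the policy advances.
#' @param start initial task position (default 3: a low rung that leaves room
#'   to titrate upward).
#' @export
gradual_titration_policy <- function(theta, start = 3L) {
  stopifnot(theta >= 0, theta <= 10)
  exposure_policy(
    name = "gradual_titration",
    params = list(theta = theta, start = start),
    initial = function(h) start,
    decide = function(suds, position, allowed, index) {
      up <- position + 1L
      if (suds <= theta && up %in% allowed) up else position
    })
}

#' Uniform random policy
#'
#' Chooses uniformly among the offered options (including "keep the same").
#' Randomness comes from the R RNG; seed it through [run_session()] or
#' [simulate_cohort()] (or via the `seed` recorded on the policy) for
#' reproducible decision sequences.
#'
#' @param seed optional default seed recorded on the policy.
#' @param start initial rule: `"random"` picks uniformly from the whole
#'   hierarchy, or give a fixed position.
#' @export
random_policy <- function(seed = NULL, start = "random") {
  exposure_policy(
    name = "random",
    params = list(start = start),
    seed = seed,
    initial = function(h) {
      if (identical(start, "random")) sample(initial_options(h), 1L)
      else as.integer(start)
    },
    decide = function(suds, position, allowed, index) {
      allowed[sample.int(length(allowed), 1L)]
    })
}

#' Avoidant policy
#'
#' Caricature of premature easing: whenever the observed SUDS reaches the
#' panic threshold, retreat one position; otherwise hold.
#'
#' @param panic_threshold SUDS level triggering a downward move.
#' @param start initial task position (default 8, a high rung that makes the
#'   avoidant pattern visible).
#' @export
avoidant_policy <- function(panic_threshold, start = 8L) {
  exposure_policy(
    name = "avoidant",
    params = list(panic_threshold = panic_threshold, start = start),
    initial = function(h) start,
    decide = function(suds, position, allowed, index) {
      down <- position - 1L
      if (suds >= panic_threshold && down %in% allowed) down else position
    })
}

#' Fixed policy
#'
#' Selects one task and keeps it for the whole session.
#'
#' @param position the task held throughout.
#' @export
fixed_policy <- function(position) {
  exposure_policy(
    name = "fixed",
    params = list(position = position),
    initial = function(h) position,
    decide = function(suds, position_now, allowed, index) position_now)
}

# Internal: replays a recorded decision sequence (used for log replay).
replay_policy <- function(choices) {
  exposure_policy(
    name = "replay",
    params = list(n = length(choices)),
    initial = function(h) stop("replay policy needs an explicit initial"),
    decide = function(suds, position, allowed, index) {
      as.integer(choices[[index - 1L]])
    })
}

#' Simulate a cohort of trainees
#'
#' Runs `cfg$repetitions` independent sessions per trainee (the program is
#' reset between repetitions, so nothing carries over), with per-session seeds
#' derived deterministically from the cohort seed.
#'
#' @param h an [exposure_hierarchy()].
#' @param cfg a [session_config()].
#' @param policy an [exposure_policy()] applied to every session.
#' @param n_trainees number of simulated trainees (>= 1).
#' @param seed cohort seed.
#' @param out_dir optional directory; when given, each log is written as
#'   `<session_id>.jsonl` alongside a `manifest.csv`.
#' @return A list of class `session_cohort`: `logs` (list of `session_log`)
#'   and `manifest` (data.frame with one row per session).
#' @export
simulate_cohort <- function(h, cfg = session_config(), policy, n_trainees,
                            seed = 1L, out_dir = NULL) {
  stopifnot(n_trainees >= 1L)
  logs <- list()
  rows <- list()
  for (i in seq_len(n_trainees)) {
    for (r in seq_len(cfg$repetitions)) {
      session_seed <- as.integer(
        (as.numeric(seed) + i * 7919 + r * 104729) %% 2147483647)
      sid <- sprintf("trainee%03d-rep%d", i, r)
      log <- run_session(h, cfg, policy, seed = session_seed,
                         session_id = sid)
      logs[[sid]] <- log
      traj <- log_suds_trajectory(log)
      rows[[sid]] <- data.frame(
        trainee = i, repetition = r, session_id = sid, seed = session_seed,
        policy = policy$name, initial_suds = traj$suds[1],
        final_suds = traj$suds[nrow(traj)], peak_suds = max(traj$suds))
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (sid in names(logs)) {
      write_session_log(logs[[sid]], file.path(out_dir,
                                               paste0(sid, ".jsonl")))
    }
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  structure(list(logs = logs, manifest = manifest, seed = seed),
            class = "session_cohort")
}
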