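#' Session configuration for the virtual-patient engine
#'
#' The engine is a discrete-event simulator on an integer-second clock with a
#' fixed tick grid: verbalization cues fire every tick, decision points every
#' `decision_interval_seconds`, and the virtual patient habituates (SUDS drops
#' one point) after every `habituation_interval_seconds` of continuous
#' exposure to the same task.  The defaults encode the deployed training
#' scenario: 15 s cues, decisions every 45 s, 9 decision points (the initial
#' task selection counts as the first), a 1 point / 2 min habituation rate on
#' a 0-10 SUDS scale, and 3 repetitions per sitting.
#'
#' @param tick_seconds cue granularity in seconds (default 15).
#' @param decision_interval_seconds time between decision points (default 45);
#'   must be a multiple of the tick.
#' @param n_decision_points total decision points including the initial
#'   selection (default 9).
#' @param habituation_interval_seconds continuous-exposure time per 1-point
#'   SUDS drop (default 120); must be a multiple of the tick.
#' @param suds_min,suds_max SUDS bounds (defaults 0 and 10).
#' @param band_low_max largest SUDS counted as "low" distress (default 3).
#' @param band_high_min smallest SUDS counted as "high" distress (default 8);
#'   values strictly between the two edges are "moderate".
#' @param repetitions scenario repetitions per trainee sitting (default 3).
#' @param elicitation function mapping a task position to the SUDS level it
#'   evokes on entry; the default is the identity (task 6 evokes SUDS 6),
#'   clamped to the SUDS bounds.
#' @return A validated list of class `session_config`.
#' @export
session_config <- function(tick_seconds = 15L,
                           decision_interval_seconds = 45L,
                           n_decision_points = 9L,
                           habituation_interval_seconds = 120L,
                           suds_min = 0L, suds_max = 10L,
                           band_low_max = 3L, band_high_min = 8L,
                           repetitions = 3L,
                           elicitation = NULL) {
  cfg <- list(
    tick_seconds = as.integer(tick_seconds),
    decision_interval_seconds = as.integer(decision_interval_seconds),
    n_decision_points = as.integer(n_decision_points),
    habituation_interval_seconds = as.integer(habituation_interval_seconds),
    suds_min = as.integer(suds_min), suds_max = as.integer(suds_max),
    band_low_max = as.integer(band_low_max),
    band_high_min = as.integer(band_high_min),
    repetitions = as.integer(repetitions))
  with(cfg, {
    stopifnot(tick_seconds >= 1L, n_decision_points >= 1L, repetitions >= 1L)
    if (decision_interval_seconds %% tick_seconds != 0L) {
      stop("decision interval must be a multiple of the tick")
    }
    if (habituation_interval_seconds %% tick_seconds != 0L) {
      stop("habituation interval must be a multiple of the tick")
    }
    if (suds_min >= suds_max) stop("suds_min must be below suds_max")
    if (!(suds_min <= band_low_max && band_low_max < band_high_min &&
          band_high_min <= suds_max)) {
      stop("distress band edges must be strictly increasing within SUDS bounds")
    }
  })
  cfg$elicitation <- if (is.null(elicitation)) function(p) p else elicitation
  structure(cfg, class = "session_config")
}

clamp_suds <- function(x, cfg) {
  as.integer(min(max(x, cfg$suds_min), cfg$suds_max))
}

#' Distress band for a SUDS value
#'
#' Coarse categorization of distress driving the virtual patient's
#' state-keyed cues: `"low"` (SUDS at or below the low edge), `"high"` (at or
#' above the high edge), `"moderate"` otherwise.
#'
#' @param suds integer SUDS value or an active `exposure_session`.
#' @param cfg a [session_config()]; ignored when `suds` is a session.
#' @export
distress_band <- function(suds, cfg = session_config()) {
  if (inherits(suds, "exposure_session")) {
    cfg <- suds$cfg
    suds <- suds$suds
  }
  if (suds < cfg$suds_min || suds > cfg$suds_max) {
    stop("SUDS value outside configured bounds")
  }
  if (suds <= cfg$band_low_max) "low"
  else if (suds >= cfg$band_high_min) "high"
  else "moderate"
}

emit <- function(session, kind, ...) {
  ev <- list(t = session$clock, kind = kind, payload = list(...))
  session$events[[length(session$events) + 1L]] <- ev
  invisible(ev)
}

next_session_id <- local({
  counter <- 0L
  function() {
    counter <<- counter + 1L
    sprintf("sess-%s-%04d", format(Sys.time(), "%Y%m%d%H%M%OS"), counter)
  }
})

#' Start a simulated exposure session
#'
#' Creates a fresh virtual-patient session and consumes the first decision
#' point: the initial task selection, which may come from anywhere on the
#' hierarchy.  The patient's starting SUDS is the elicitation level of the
#' chosen task (by default equal to its position, clamped to bounds).
#'
#' Sessions are mutable environment objects; [advance()], [apply_decision()],
#' [suds_check()] and [end_session()] update them in place and append to the
#' append-only event log.
#'
#' @param h an [exposure_hierarchy()].
#' @param cfg a [session_config()].
#' @param initial initial task position, in `initial_options(h)`.
#' @param session_id optional identifier; generated when `NULL`.
#' @return An environment of class `exposure_session`.
#' @export
start_session <- function(h, cfg = session_config(), initial,
                          session_id = NULL) {
  stopifnot(inherits(h, "exposure_hierarchy"), inherits(cfg, "session_config"))
  initial <- as.integer(initial)
  if (!initial %in% initial_options(h)) {
    stop("initial position ", initial, " is not on the hierarchy")
  }
  s <- new.env(parent = emptyenv())
  s$h <- h
  s$cfg <- cfg
  s$session_id <- if (is.null(session_id)) next_session_id() else session_id
  s$clock <- 0L
  s$position <- initial
  s$suds <- clamp_suds(cfg$elicitation(initial), cfg)
  s$time_on_task <- 0L
  s$decisions_made <- 1L
  s$terminated <- FALSE
  s$events <- list()
  class(s) <- "exposure_session"
  emit(s, "session_start", config_digest = config_digest(cfg),
       hierarchy_digest = hierarchy_digest(h))
  emit(s, "decision_point", index = 1L, options = initial_options(h),
       choice = initial, action = "initial_select", magnitude = 0L,
       suds_before = s$suds, suds_after = s$suds)
  emit(s, "task_select", position = initial, label = task_label(h, initial),
       suds = s$suds)
  s
}

stop_if_terminated <- function(session) {
  if (session$terminated) stop("session already terminated")
}

#' Advance simulated time
#'
#' Moves the session clock forward in tick-sized steps.  Each tick emits a
#' `verbalization_cue` event tagged with the patient's current distress band;
#' whenever continuous time on the current task crosses a multiple of the
#' habituation interval, SUDS drops one point (floored at the lower bound)
#' and a `suds_update` event is emitted.
#'
#' @param session an active `exposure_session`.
#' @param seconds positive multiple of the configured tick.
#' @return Invisibly, the list of events emitted during the advance.
#' @export
advance <- function(session, seconds) {
  stop_if_terminated(session)
  cfg <- session$cfg
  seconds <- as.integer(seconds)
  if (seconds <= 0L || seconds %% cfg$tick_seconds != 0L) {
    stop("seconds must be a positive multiple of the ", cfg$tick_seconds,
         "-second tick")
  }
  first <- length(session$events) + 1L
  for (i in seq_len(seconds %/% cfg$tick_seconds)) {
    session$clock <- session$clock + cfg$tick_seconds
    session$time_on_task <- session$time_on_task + cfg$tick_seconds
    if (session$time_on_task %% cfg$habituation_interval_seconds == 0L &&
        session$suds > cfg$suds_min) {
      session$suds <- session$suds - 1L
      emit(session, "suds_update", suds = session$suds,
           band = distress_band(session$suds, cfg))
    }
    band <- distress_band(session$suds, cfg)
    emit(session, "verbalization_cue", band = band,
         cue_id = paste0("cue_", band))
  }
  invisible(session$events[seq.int(first, length(session$events))])
}

#' Apply a therapist decision
#'
#' Consumes one decision point.  The choice must lie within the hierarchy's
#' move radius of the current task (the engine analogue of the interface
#' constraint preventing large jumps in exposure intensity).  Moving up sets
#' SUDS to the new task's elicitation level; moving down caps SUDS at the new
#' task's elicitation level without ever raising it; keeping the same task
#' leaves SUDS unchanged.  Any task change restarts the continuous-exposure
#' (habituation) clock.
#'
#' @param session an active `exposure_session` with decision points remaining.
#' @param choice chosen task position, in `allowed_moves(h, current)`.
#' @return The session, invisibly.
#' @export
apply_decision <- function(session, choice) {
  stop_if_terminated(session)
  cfg <- session$cfg
  if (session$decisions_made >= cfg$n_decision_points) {
    stop("all ", cfg$n_decision_points, " decision points already consumed")
  }
  options <- allowed_moves(session$h, session$position)
  choice <- as.integer(choice)
  if (!choice %in% options) {
    stop("choice ", choice, " is outside the allowed moves {",
         paste(options, collapse = ","), "}")
  }
  magnitude <- choice - session$position
  action <- if (magnitude > 0L) "increase"
            else if (magnitude < 0L) "decrease" else "same"
  suds_before <- session$suds
  if (magnitude > 0L) {
    session$suds <- clamp_suds(cfg$elicitation(choice), cfg)
  } else if (magnitude < 0L) {
    session$suds <- clamp_suds(min(session$suds, cfg$elicitation(choice)), cfg)
  }
  session$decisions_made <- session$decisions_made + 1L
  emit(session, "decision_point", index = session$decisions_made,
       options = options, choice = choice, action = action,
       magnitude = magnitude, suds_before = suds_before,
       suds_after = session$suds)
  if (magnitude != 0L) {
    session$position <- choice
    session$time_on_task <- 0L
    emit(session, "task_select", position = choice,
         label = task_label(session$h, choice), suds = session$suds)
  }
  invisible(session)
}

#' Sample the virtual patient's distress
#'
#' Returns the current SUDS value and records a `suds_check` event, mirroring
#' the trainee clicking the SUDS button; the session state is otherwise
#' untouched.
#'
#' @param session an active `exposure_session`.
#' @return Integer SUDS value.
#' @export
suds_check <- function(session) {
  stop_if_terminated(session)
  emit(session, "suds_check", suds = session$suds,
       band = distress_band(session$suds, session$cfg))
  session$suds
}

#' Terminate a session
#'
#' @param session an active `exposure_session`.
#' @return The session, invisibly.
#' @export
end_session <- function(session) {
  stop_if_terminated(session)
  emit(session, "session_end", suds = session$suds,
       position = session$position, decisions_made = session$decisions_made)
  session$terminated <- TRUE
  invisible(session)
}

#' @export
print.exposure_session <- function(x, ...) {
  cat(sprintf(
    "<exposure_session %s> t=%ds task=%d suds=%d decisions=%d/%d%s\n",
    x$session_id, x$clock, x$position, x$suds, x$decisions_made,
    x$cfg$n_decision_points, if (x$terminated) " [ended]" else ""))
  invisible(x)
}

#' Run one full simulated session under a policy
#'
#' Orchestrates the whole training scenario: the policy selects the initial
#' task (decision point 1), then the engine alternates a decision-interval
#' advance with a SUDS check and a policy decision until all decision points
#' are consumed, and finally advances one last decision interval before the
#' session ends.  With the defaults this yields decisions at
#' t = 0, 45, ..., 360 s and session end at t = 405 s.
#'
#' Engine dynamics are fully deterministic; `seed` only governs policy
#' randomness, so identical `(policy, seed, cfg)` give identical event
#' sequences (session id aside).
#'
#' @param h an [exposure_hierarchy()].
#' @param cfg a [session_config()].
#' @param policy an [exposure_policy()].
#' @param seed optional integer seed for policy randomness; falls back to the
#'   policy's own default seed, if any.
#' @param initial optional initial position overriding the policy's choice.
#' @param session_id optional identifier.
#' @return A `session_log` object (see [as_session_log()]).
#' @export
run_session <- function(h, cfg = session_config(), policy, seed = NULL,
                        initial = NULL, session_id = NULL) {
  stopifnot(inherits(policy, "exposure_policy"))
  if (is.null(seed)) seed <- policy$seed
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old_seed, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  if (is.null(initial)) initial <- policy$initial(h)
  s <- start_session(h, cfg, initial, session_id = session_id)
  for (k in seq.int(2L, length.out = cfg$n_decision_points - 1L)) {
    advance(s, cfg$decision_interval_seconds)
    observed <- suds_check(s)
    opts <- allowed_moves(h, s$position)
    choice <- policy$decide(observed, s$position, opts, k)
    apply_decision(s, choice)
  }
  advance(s, cfg$decision_interval_seconds)
  end_session(s)
  as_session_log(s)
}

#' Prepare a fresh session context after a completed repetition
#'
#' The training program is reset between repetitions: the virtual patient
#' carries no memory of the previous session, so only the hierarchy and
#' configuration are retained.  Resetting an incomplete session is an error.
#'
#' @param log a completed `session_log`.
#' @param cfg optional replacement [session_config()]; defaults to the log's.
#' @return A list of class `session_context` with elements `hierarchy` and
#'   `config`, suitable for starting the next repetition from scratch.
#' @export
reset_for_repetition <- function(log, cfg = NULL) {
  stopifnot(inherits(log, "session_log"))
  kinds <- vapply(log$events, `[[`, "", "kind")
  if (!"session_end" %in% kinds) {
    stop("cannot reset an active (incomplete) session")
  }
  structure(list(hierarchy = log$hierarchy,
                 config = if (is.null(cfg)) log$config else cfg),
            class = "session_context")
}
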