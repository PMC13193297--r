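#' Session logs and their JSONL serialization
#'
#' A session log is the append-only record of one simulated session: a header
#' (session id, schema version, configuration snapshot, hierarchy snapshot and
#' digest) followed by the ordered event list.  On disk a log is JSON Lines:
#' the header object on the first line, then one JSON object per event with
#' fields `t`, `kind`, `payload`.  The reader rejects unknown schema versions.
#'
#' @name session_log
NULL

LOG_SCHEMA_VERSION <- "1.0"

# FNV-1a 32-bit over a canonical string rendering; cheap content fingerprint
# used to tie logs to the hierarchy/config that produced them.
fnv1a32 <- function(txt) {
  bytes <- utf8ToInt(txt)
  hash <- 2166136261
  for (b in bytes) {
    low <- hash %% 256
    hash <- hash - low + bitwXor(low, b %% 256)
    hash <- (hash * 16777619) %% 4294967296
  }
  # split into two 16-bit halves so the value stays in integer range
  sprintf("%04x%04x", as.integer(hash %/% 65536), as.integer(hash %% 65536))
}

hierarchy_digest <- function(h) {
  fnv1a32(paste(h$position, h$task_id, h$label, attr(h, "reach"),
                sep = "|", collapse = ";"))
}

config_digest <- function(cfg) {
  scalar <- cfg[vapply(cfg, is.atomic, TRUE)]
  fnv1a32(paste(names(scalar), unlist(scalar), sep = "=", collapse = ";"))
}

#' Extract an immutable log from a session
#'
#' @param session a (normally terminated) `exposure_session`.
#' @return A list of class `session_log` with elements `session_id`,
#'   `schema_version`, `config`, `hierarchy`, `events`.
#' @export
as_session_log <- function(session) {
  stopifnot(inherits(session, "exposure_session"))
  structure(list(session_id = session$session_id,
                 schema_version = LOG_SCHEMA_VERSION,
                 config = session$cfg,
                 hierarchy = session$h,
                 events = session$events),
            class = "session_log")
}

log_event_kinds <- function(log) vapply(log$events, `[[`, "", "kind")

#' Events of a given kind from a session log
#' @param log a `session_log`.
#' @param kind event kind, e.g. `"decision_point"`.
#' @export
log_events <- function(log, kind = NULL) {
  stopifnot(inherits(log, "session_log"))
  if (is.null(kind)) return(log$events)
  log$events[log_event_kinds(log) == kind]
}

#' Validate session-log invariants
#'
#' Checks: exactly one `session_start` and (for complete logs) one
#' `session_end`; event times non-decreasing; exactly `n_decision_points`
#' decision-point events; every decision-point payload records the offered
#' option set and the choice, and the choice is in the offered set.
#'
#' @param log a `session_log`.
#' @param complete require a `session_end` event (default TRUE).
#' @return TRUE invisibly, or an error describing the violation.
#' @export
validate_session_log <- function(log, complete = TRUE) {
  stopifnot(inherits(log, "session_log"))
  kinds <- log_event_kinds(log)
  if (sum(kinds == "session_start") != 1L) stop("log needs one session_start")
  if (complete && sum(kinds == "session_end") != 1L) {
    stop("log is incomplete: missing session_end")
  }
  times <- vapply(log$events, `[[`, numeric(1), "t")
  if (is.unsorted(times)) stop("event times must be non-decreasing")
  dps <- log_events(log, "decision_point")
  if (complete && length(dps) != log$config$n_decision_points) {
    stop("expected ", log$config$n_decision_points,
         " decision_point events, found ", length(dps))
  }
  for (ev in dps) {
    p <- ev$payload
    if (is.null(p$options) || is.null(p$choice)) {
      stop("decision_point events must record options and choice")
    }
    if (!p$choice %in% p$options) stop("recorded choice outside offered options")
  }
  invisible(TRUE)
}

#' SUDS trajectory recorded in a log
#'
#' One row per SUDS-bearing event (session start, habituation updates,
#' decision points, SUDS checks, session end), giving the piecewise-constant
#' SUDS path over the session.
#'
#' @param log a `session_log`.
#' @return data.frame with columns `t`, `suds`, `kind`.
#' @export
log_suds_trajectory <- function(log) {
  stopifnot(inherits(log, "session_log"))
  rows <- lapply(log$events, function(ev) {
    suds <- switch(ev$kind,
      decision_point = ev$payload$suds_after,
      suds_update = ev$payload$suds,
      suds_check = ev$payload$suds,
      task_select = ev$payload$suds,
      session_end = ev$payload$suds,
      NULL)
    if (is.null(suds)) return(NULL)
    data.frame(t = ev$t, suds = suds, kind = ev$kind)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Write a session log as JSON Lines
#'
#' @param log a `session_log`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(log, path) {
  stopifnot(inherits(log, "session_log"))
  cfg <- log$config
  header <- list(
    type = "header",
    schema_version = log$schema_version,
    session_id = log$session_id,
    config = cfg[vapply(cfg, is.atomic, TRUE)],
    hierarchy = list(reach = attr(log$hierarchy, "reach"),
                     tasks = as.data.frame(log$hierarchy)),
    hierarchy_digest = hierarchy_digest(log$hierarchy))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA), con)
  for (ev in log$events) {
    writeLines(jsonlite::toJSON(ev, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read a JSONL session log
#'
#' @param path file written by [write_session_log()].
#' @return A `session_log`.
#' @export
read_session_log <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1L) stop("empty session log file")
  header <- jsonlite::fromJSON(lines[[1]], simplifyVector = TRUE)
  if (!identical(header$type, "header")) {
    stop("first JSONL line must be the header object")
  }
  if (!identical(header$schema_version, LOG_SCHEMA_VERSION)) {
    stop("unsupported session-log schema version: ", header$schema_version)
  }
  cfg <- do.call(session_config, header$config)
  h <- exposure_hierarchy(header$hierarchy$tasks, reach = header$hierarchy$reach)
  if (!identical(hierarchy_digest(h), header$hierarchy_digest)) {
    stop("hierarchy digest mismatch: log header is corrupt")
  }
  events <- lapply(lines[-1], function(l) {
    ev <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    ev$payload <- as.list(ev$payload)
    ev
  })
  structure(list(session_id = header$session_id,
                 schema_version = header$schema_version,
                 config = cfg, hierarchy = h, events = events),
            class = "session_log")
}

#' Replay a log's decisions through the engine
#'
#' Re-runs the logged decision sequence on a fresh session built from the
#' log's own hierarchy and configuration, and checks that the engine
#' reproduces the logged SUDS trajectory and final state.
#'
#' @param log a complete `session_log`.
#' @return The regenerated `session_log`, invisibly; errors if the replay
#'   diverges from the original.
#' @export
replay_session_log <- function(log) {
  validate_session_log(log)
  dps <- log_events(log, "decision_point")
  choices <- vapply(dps, function(ev) as.integer(ev$payload$choice), 1L)
  pol <- replay_policy(choices[-1])
  new_log <- run_session(log$hierarchy, log$config, pol, initial = choices[[1]],
                         session_id = log$session_id)
  orig <- log_suds_trajectory(log)
  redo <- log_suds_trajectory(new_log)
  same <- nrow(orig) == nrow(redo) &&
    all(orig$t == redo$t) && all(orig$suds == redo$suds)
  if (!same) stop("replay diverged from the recorded SUDS trajectory")
  invisible(new_log)
}

#' @export
print.session_log <- function(x, ...) {
  kinds <- log_event_kinds(x)
  traj <- log_suds_trajectory(x)
  cat(sprintf(
    "<session_log %s> %d events, %d decision points, SUDS %d -> %d\n",
    x$session_id, length(x$events), sum(kinds == "decision_point"),
    traj$suds[1], traj$suds[nrow(traj)]))
  invisible(x)
}
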