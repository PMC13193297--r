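#' Exposure-task hierarchies
#'
#' An exposure hierarchy is an ordered list of feared tasks, ranked from least
#' difficult (position 1) to most difficult (position N).  Graded exposure is
#' planned against this ladder: at each decision point the therapist may keep
#' the current task or move to a task within `reach` positions above or below
#' it.  The packaged default is a 10-item shoe-contamination ladder whose
#' endpoints are "look at shoe" (position 1) and "touch shoe to face"
#' (position 10); the eight intermediate labels are illustrative placeholders.
#'
#' @name hierarchy
NULL

#' Construct an exposure hierarchy
#'
#' @param tasks data.frame with columns `position` (integer difficulty rank),
#'   `task_id` (unique short identifier) and `label` (non-empty description).
#'   Positions must be exactly the consecutive integers `1..nrow(tasks)`.
#' @param reach integer move radius applied at decision points (default 2):
#'   from position p the allowed moves are the positions within `reach` of p.
#' @return An object of class `exposure_hierarchy`: the task table (sorted by
#'   position) with a `reach` attribute.
#' @examples
#' h <- exposure_hierarchy(data.frame(
#'   position = 1:3, task_id = c("a", "b", "c"),
#'   label = c("look", "approach", "touch")))
#' allowed_moves(h, 1)
#' @export
exposure_hierarchy <- function(tasks, reach = 2L) {
  stopifnot(is.data.frame(tasks))
  required <- c("position", "task_id", "label")
  missing_cols <- setdiff(required, names(tasks))
  if (length(missing_cols) > 0L) {
    stop("hierarchy table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(tasks) == 0L) stop("hierarchy must contain at least one task")
  tasks$position <- as.integer(tasks$position)
  tasks$task_id <- as.character(tasks$task_id)
  tasks$label <- as.character(tasks$label)
  n <- nrow(tasks)
  if (anyNA(tasks$position) || !setequal(tasks$position, seq_len(n)) ||
      anyDuplicated(tasks$position) > 0L) {
    stop("positions must be exactly the consecutive integers 1..", n)
  }
  if (anyDuplicated(tasks$task_id) > 0L) stop("task_id values must be unique")
  if (any(is.na(tasks$label)) || any(!nzchar(trimws(tasks$label)))) {
    stop("every task needs a non-empty label")
  }
  reach <- as.integer(reach)
  if (length(reach) != 1L || is.na(reach) || reach < 1L) {
    stop("reach must be a single integer >= 1")
  }
  tasks <- tasks[order(tasks$position), required, drop = FALSE]
  rownames(tasks) <- NULL
  structure(tasks, reach = reach, class = c("exposure_hierarchy", "data.frame"))
}

#' Load an exposure hierarchy from a file or the packaged fixture
#'
#' The file format is UTF-8 delimited text with a header row and columns
#' `position`, `task_id`, `label`.  The built-in name `"shoe"` loads the
#' default 10-task shoe-contamination ladder shipped with the package.
#'
#' @param source either the built-in fixture name `"shoe"` or a path to a
#'   readable hierarchy file.
#' @param reach move radius for decision points, default 2.
#' @param sep field delimiter, default comma.
#' @return An [exposure_hierarchy()].
#' @export
load_hierarchy <- function(source = "shoe", reach = 2L, sep = ",") {
  path <- if (identical(source, "shoe")) {
    system.file("extdata", "shoe_hierarchy.csv", package = "exposim",
                mustWork = TRUE)
  } else {
    source
  }
  if (!file.exists(path)) stop("hierarchy file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, encoding = "UTF-8",
                           colClasses = c("integer", "character", "character"))
  exposure_hierarchy(tab, reach = reach)
}

#' Number of tasks in a hierarchy
#' @param h an `exposure_hierarchy`.
#' @export
n_tasks <- function(h) {
  stopifnot(inherits(h, "exposure_hierarchy"))
  nrow(h)
}

#' Move radius of a hierarchy
#' @param h an `exposure_hierarchy`.
#' @export
hierarchy_reach <- function(h) attr(h, "reach")

#' Label of the task at a position
#' @param h an `exposure_hierarchy`.
#' @param position integer position in `1..n_tasks(h)`.
#' @export
task_label <- function(h, position) {
  stopifnot(inherits(h, "exposure_hierarchy"))
  if (!position %in% h$position) stop("no task at position ", position)
  h$label[match(position, h$position)]
}

#' Positions available for the initial task selection
#'
#' The initial exposure task may be chosen from anywhere on the hierarchy.
#'
#' @param h an `exposure_hierarchy`.
#' @return integer vector `1..N`.
#' @export
initial_options <- function(h) {
  stopifnot(inherits(h, "exposure_hierarchy"))
  seq_len(nrow(h))
}

#' Positions reachable from the current task at a decision point
#'
#' Moves are restricted to tasks within `reach` hierarchy positions above or
#' below the current task (clamped to the ladder ends); the current position
#' is always included, representing the "keep it the same" choice.
#'
#' @param h an `exposure_hierarchy`.
#' @param current the active task position.
#' @return sorted integer vector of permitted positions.
#' @export
allowed_moves <- function(h, current) {
  stopifnot(inherits(h, "exposure_hierarchy"))
  current <- as.integer(current)
  n <- nrow(h)
  if (length(current) != 1L || is.na(current) || current < 1L || current > n) {
    stop("current position must lie in 1..", n)
  }
  reach <- attr(h, "reach")
  seq.int(max(1L, current - reach), min(n, current + reach))
}

#' @export
print.exposure_hierarchy <- function(x, ...) {
  cat(sprintf("Exposure hierarchy: %d tasks, move radius %d\n",
              nrow(x), attr(x, "reach")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
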