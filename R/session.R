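# Session: emulation of the app's paged screening flow — organ-system
# pages, condition toggling, immediate multimorbid notification on the tap
# that completes a qualifying set, final result, and the plain-text
# notification payload that replaces the app's email step.
#
# Sessions are environment-backed (mutable), like connection or progress-bar
# objects: select/deselect/finish mutate in place and return the session
# invisibly.  Timestamps come from an injectable clock so tests and replays
# are fully deterministic.

#' Start a screening session
#'
#' @param catalog A `qcs_catalog`; must pass [validate_catalog()] with no
#'   error-level issues.
#' @param clock Zero-argument function returning the current time in seconds
#'   (numeric).  Defaults to the wall clock; inject a counter for
#'   deterministic replays.
#' @param show_instructions Logical; the app's "don't show instructions
#'   again" preference.  Logged only, no behavioural effect.
#' @return A `qcs_session` environment with fields `status`
#'   (`"in_progress"`, `"multimorbid"` or `"completed_not_multimorbid"`),
#'   `selected`, `page_order`, `event_log` and `triggering_set`.
#' @export
start_session <- function(catalog, clock = function() as.numeric(Sys.time()),
                          show_instructions = TRUE) {
  stopifnot(inherits(catalog, "qcs_catalog"))
  issues <- validate_catalog(catalog)
  if (any(issues$level == "error")) {
    stop("refusing to start a session on an invalid catalog:\n  ",
         paste(issues$message[issues$level == "error"], collapse = "\n  "),
         call. = FALSE)
  }
  s <- new.env(parent = emptyenv())
  s$catalog <- catalog
  s$pages <- conditions_by_system(catalog)
  s$page_order <- names(s$pages)
  s$selected <- character()
  s$status <- "in_progress"
  s$match_state <- new_match_state(catalog)
  s$triggering_set <- NULL
  s$clock <- clock
  s$event_log <- list()
  s$started_at <- clock()
  s$finished_at <- NA_real_
  class(s) <- "qcs_session"
  log_event(s, "session_started",
            paste0("pages=", length(s$page_order),
                   " show_instructions=", show_instructions))
  s
}

log_event <- function(session, action, detail = "") {
  session$event_log[[length(session$event_log) + 1L]] <-
    list(t = session$clock(), action = action, detail = detail)
  invisible(session)
}

#' Select a condition in a screening session
#'
#' Delegates to the incremental matcher.  On the selection that completes a
#' qualifying set the session status flips to `"multimorbid"`, the
#' triggering set is recorded, and — mirroring the app's early termination —
#' any further selection is rejected.  Re-selecting an already selected
#' condition is a no-op with a logged warning.
#'
#' @param session A `qcs_session` with status `"in_progress"`.
#' @param id Condition id.
#' @return The session, invisibly.
#' @export
select_condition <- function(session, id) {
  stopifnot(inherits(session, "qcs_session"))
  if (session$status != "in_progress") {
    stop("session is terminated (status '", session$status,
         "'); no further selections are accepted", call. = FALSE)
  }
  if (id %in% session$selected) {
    log_event(session, "duplicate_selection_ignored", id)
    warning("condition '", id, "' is already selected; ignoring",
            call. = FALSE)
    return(invisible(session))
  }
  res <- add_condition(session$match_state, id)
  session$match_state <- res$state
  session$selected <- c(session$selected, id)
  log_event(session, "condition_selected", id)
  if (!is.null(res$event)) {
    session$status <- "multimorbid"
    session$triggering_set <- res$event$triggering_set
    log_event(session, "multimorbid_notified",
              paste(res$event$triggering_set, collapse = "+"))
  }
  invisible(session)
}

#' Deselect a condition in a screening session
#'
#' After `select(x); deselect(x)` the internal match state is identical to a
#' fresh session replayed without `x` (only the event log remembers the
#' toggle).
#'
#' @param session A `qcs_session` with status `"in_progress"`.
#' @param id Currently selected condition id.
#' @return The session, invisibly.
#' @export
deselect_condition <- function(session, id) {
  stopifnot(inherits(session, "qcs_session"))
  if (session$status != "in_progress") {
    stop("session is terminated (status '", session$status, "')",
         call. = FALSE)
  }
  if (!id %in% session$selected) {
    stop("condition '", id, "' is not selected", call. = FALSE)
  }
  session$match_state <- remove_condition(session$match_state, id)
  session$selected <- setdiff(session$selected, id)
  log_event(session, "condition_deselected", id)
  invisible(session)
}

#' Finish a screening session
#'
#' An in-progress session with no triggering set completes as not
#' multimorbid (the app's far-right results page); a triggered session keeps
#' its multimorbid status.  Finishing twice is an error.
#'
#' @param session A `qcs_session`.
#' @return A `qcs_session_result` list: `status`, `selected`,
#'   `triggering_set` and `elapsed_s` (finish time minus start time, from
#'   the injected clock).
#' @export
finish_session <- function(session) {
  stopifnot(inherits(session, "qcs_session"))
  if (session$status == "completed_not_multimorbid" ||
      !is.na(session$finished_at)) {
    stop("session is already finished", call. = FALSE)
  }
  if (session$status == "in_progress") {
    session$status <- "completed_not_multimorbid"
  }
  session$finished_at <- session$clock()
  log_event(session, "session_finished", session$status)
  structure(
    list(status = session$status,
         selected = session$selected,
         triggering_set = session$triggering_set,
         elapsed_s = session$finished_at - session$started_at),
    class = "qcs_session_result"
  )
}

#' Build the notification payload for a finished session
#'
#' A deterministic plain-text summary standing in for the app's automatic
#' email to the study team: status, selected conditions and (when
#' multimorbid) the triggering set.  No patient identifiers are included
#' beyond the optional `subject` label supplied by the caller.
#'
#' @param result A `qcs_session_result` from [finish_session()].
#' @param subject Optional label for the screened patient; the caller is
#'   responsible for its de-identification.
#' @return A single string (byte-identical across calls on equal input).
#' @export
build_notification_payload <- function(result, subject = NULL) {
  stopifnot(inherits(result, "qcs_session_result"))
  lines <- c(
    "QCS screening result",
    if (!is.null(subject)) paste0("subject: ", subject),
    paste0("status: ", result$status),
    paste0("selected conditions (", length(result$selected), "): ",
           paste(result$selected, collapse = ", ")),
    if (identical(result$status, "multimorbid"))
      paste0("triggering set: {",
             paste(result$triggering_set, collapse = ", "), "}")
  )
  paste(lines, collapse = "\n")
}

#' @export
print.qcs_session <- function(x, ...) {
  cat("<qcs_session> status:", x$status,
      "| selected:", length(x$selected),
      "| events:", length(x$event_log), "\n")
  invisible(x)
}
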