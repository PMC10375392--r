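# Matcher: is a condition profile multimorbid, i.e. does it contain any
# Qualifying Comorbidity Set as a subset?  Batch form reports all matched
# sets; the incremental form mirrors the app's tap-by-tap early termination.

assert_profile <- function(profile, catalog) {
  profile <- unique(as.character(profile))
  missing <- setdiff(profile, names(catalog$conditions))
  if (length(missing)) {
    stop("unresolvable condition id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  profile
}

# Deterministic set ordering: by size, then lexicographically on the
# canonical (sorted) member ids.
order_sets <- function(sets) {
  if (!length(sets)) return(integer())
  order(lengths(sets), vapply(sets, set_key, character(1)))
}

#' Classify a condition profile
#'
#' A profile is multimorbid when at least one qualifying set of the catalog
#' is wholly contained in it.  All matched sets are reported (research users
#' want the full witness list) in a deterministic order — ascending size,
#' ties broken lexicographically on member ids — and `first_triggering_set`
#' is the first of them, matching what the app would have announced.
#'
#' @param profile Character vector of condition ids (duplicates ignored).
#' @param catalog A `qcs_catalog`.
#' @return A `qcs_result` list: `is_multimorbid`, `matched_sets` (list of
#'   character vectors) and `first_triggering_set` (or `NULL`).
#' @examples
#' cat <- builtin_toy_catalog()
#' evaluate_profile(c("pneumonia", "substance_abuse"), cat)$is_multimorbid
#' @export
evaluate_profile <- function(profile, catalog) {
  stopifnot(inherits(catalog, "qcs_catalog"))
  profile <- assert_profile(profile, catalog)
  hit <- vapply(catalog$sets, function(s) all(s %in% profile), logical(1))
  matched <- catalog$sets[hit]
  matched <- matched[order_sets(matched)]
  structure(
    list(is_multimorbid = length(matched) > 0L,
         matched_sets = matched,
         first_triggering_set = if (length(matched)) matched[[1]] else NULL),
    class = "qcs_result"
  )
}

#' @export
print.qcs_result <- function(x, ...) {
  cat("<qcs_result> multimorbid:", x$is_multimorbid, "\n")
  if (x$is_multimorbid) {
    cat("  first triggering set: {",
        paste(x$first_triggering_set, collapse = ", "), "}\n",
        "  matched sets: ", length(x$matched_sets), "\n", sep = "")
  }
  invisible(x)
}

#' Initialise incremental match state
#'
#' The incremental matcher keeps, per qualifying set, a countdown of members
#' not yet selected, plus an inverted index from condition id to the sets
#' containing it; each addition touches only the sets containing that
#' condition.  The trigger event fires on the first addition that completes
#' any set and the state stays triggered thereafter.
#'
#' @param catalog A `qcs_catalog`.
#' @return A `qcs_match_state` list.
#' @seealso [add_condition()], [remove_condition()]
#' @export
new_match_state <- function(catalog) {
  stopifnot(inherits(catalog, "qcs_catalog"))
  index <- lapply(names(catalog$conditions), function(id) {
    which(vapply(catalog$sets, function(s) id %in% s, logical(1)))
  })
  names(index) <- names(catalog$conditions)
  structure(
    list(catalog = catalog,
         index = index,
         remaining = lengths(catalog$sets),
         selected = character(),
         triggered = FALSE,
         triggering_set = NULL),
    class = "qcs_match_state"
  )
}

#' Add a condition to the incremental match state
#'
#' @param state A `qcs_match_state`.
#' @param id Condition id to add; must resolve in the catalog.  Adding an
#'   already-present id is a no-op.
#' @return List with `state` (updated) and `event`: `NULL`, or on the first
#'   addition that completes a qualifying set, a list with `triggering_set`
#'   (ties broken by the [evaluate_profile()] ordering).
#' @export
add_condition <- function(state, id) {
  stopifnot(inherits(state, "qcs_match_state"))
  id <- assert_profile(id, state$catalog)
  if (id %in% state$selected) return(list(state = state, event = NULL))
  state$selected <- c(state$selected, id)
  touched <- state$index[[id]]
  state$remaining[touched] <- state$remaining[touched] - 1L
  event <- NULL
  if (!state$triggered) {
    done <- touched[state$remaining[touched] == 0L]
    if (length(done)) {
      completed <- state$catalog$sets[done]
      winner <- completed[[order_sets(completed)[1]]]
      state$triggered <- TRUE
      state$triggering_set <- winner
      event <- list(triggering_set = winner)
    }
  }
  list(state = state, event = event)
}

#' Remove a condition from the incremental match state
#'
#' Supports deselection in the screening UI: after `add(x); remove(x)` the
#' state is indistinguishable from never having added `x`.  Removal is only
#' meaningful before the multimorbid trigger (the session layer enforces
#' this); removing from a triggered state is an error.
#'
#' @param state A `qcs_match_state`.
#' @param id Currently selected condition id.
#' @return The updated state.
#' @export
remove_condition <- function(state, id) {
  stopifnot(inherits(state, "qcs_match_state"))
  if (state$triggered) {
    stop("cannot remove a condition after the multimorbid trigger",
         call. = FALSE)
  }
  if (!id %in% state$selected) {
    stop("condition '", id, "' is not selected", call. = FALSE)
  }
  state$selected <- setdiff(state$selected, id)
  touched <- state$index[[id]]
  state$remaining[touched] <- state$remaining[touched] + 1L
  state
}

#' Brute-force multimorbidity oracle
#'
#' A deliberately naive reference: a literal loop over every qualifying set
#' testing subset inclusion.  Used in tests as an independent check of
#' [evaluate_profile()] and of the incremental matcher; not intended for
#' production use.
#'
#' @param profile Character vector of condition ids.
#' @param catalog A `qcs_catalog`.
#' @return Logical scalar.
#' @export
brute_force_multimorbid <- function(profile, catalog) {
  profile <- unique(as.character(profile))
  for (s in catalog$sets) {
    contained <- TRUE
    for (m in s) {
      if (!(m %in% profile)) {
        contained <- FALSE
        break
      }
    }
    if (contained) return(TRUE)
  }
  FALSE
}
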