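# Mapper: translate coded claims records (system + code string) into
# condition profiles using the catalog's code lists.

#' Map one coded diagnosis to catalog conditions
#'
#' A condition matches when the normalised input code equals one of its
#' exact codes in the same system, or starts with one of its prefix codes in
#' that system.  Dotted and undotted dialects of the same code are
#' equivalent.  A code may legitimately name several conditions (no priority
#' ranking is applied); persistent collisions are catalog defects that
#' [validate_catalog()] warns about.
#'
#' @param code Raw code string (e.g. `"I50.9"`).
#' @param system Code-system label, one of [code_systems()].
#' @param catalog A `qcs_catalog`.
#' @return Character vector of matching condition ids (possibly empty).
#' @export
map_code <- function(code, system, catalog) {
  stopifnot(inherits(catalog, "qcs_catalog"))
  norm <- normalize_code(code, system)
  hits <- character()
  for (cond in catalog$conditions) {
    for (ce in cond$codes) {
      if (ce$system != system) next
      ok <- if (ce$match_kind == "exact") {
        norm == ce$normalized
      } else {
        startsWith(norm, ce$normalized)
      }
      if (ok) {
        hits <- c(hits, cond$id)
        break  # one hit per condition even if several entries match
      }
    }
  }
  unique(hits)
}

# Best match kind for a (condition, code) pair: exact dominates prefix.
match_kind_for <- function(cond, system, norm) {
  kinds <- character()
  for (ce in cond$codes) {
    if (ce$system != system) next
    if (ce$match_kind == "exact" && norm == ce$normalized) return("exact")
    if (ce$match_kind == "prefix" && startsWith(norm, ce$normalized)) {
      kinds <- "prefix"
    }
  }
  if (length(kinds)) kinds else NA_character_
}

#' Map a batch of coded diagnoses to a condition profile
#'
#' The profile is the union of the per-code matches.  Duplicate input codes
#' collapse in the profile but each input row is preserved: every input
#' index appears in `hits` or in `unmapped` (in `hits` more than once only
#' when one code names several conditions).  Unmapped codes are reported,
#' never fatal: claims feeds carry many codes irrelevant to the rule base.
#'
#' @param diagnoses Data frame with columns `system` and `code` (one row per
#'   coded diagnosis), or a list of `list(system=, code=)` pairs.
#' @param catalog A `qcs_catalog`.
#' @return A `qcs_mapping` list: `profile` (character vector of condition
#'   ids), `hits` (data frame `input_index`, `system`, `code`,
#'   `condition_id`, `match_kind`) and `unmapped` (data frame `input_index`,
#'   `system`, `code`).
#' @export
map_record <- function(diagnoses, catalog) {
  stopifnot(inherits(catalog, "qcs_catalog"))
  if (is.data.frame(diagnoses)) {
    diagnoses <- lapply(seq_len(nrow(diagnoses)), function(i) {
      list(system = diagnoses$system[[i]], code = diagnoses$code[[i]])
    })
  }
  hits <- list()
  unmapped <- list()
  for (i in seq_along(diagnoses)) {
    d <- diagnoses[[i]]
    if (is.null(d$system) || is.null(d$code) || !nzchar(d$code)) {
      stop("diagnosis [", i, "]: needs non-empty 'system' and 'code'",
           call. = FALSE)
    }
    ids <- tryCatch(map_code(d$code, d$system, catalog), error = function(e) {
      stop("diagnosis [", i, "]: ", conditionMessage(e), call. = FALSE)
    })
    if (length(ids)) {
      norm <- normalize_code(d$code, d$system)
      for (id in ids) {
        hits[[length(hits) + 1L]] <- data.frame(
          input_index = i, system = d$system, code = d$code,
          condition_id = id,
          match_kind = match_kind_for(catalog$conditions[[id]],
                                      d$system, norm),
          stringsAsFactors = FALSE)
      }
    } else {
      unmapped[[length(unmapped) + 1L]] <- data.frame(
        input_index = i, system = d$system, code = d$code,
        stringsAsFactors = FALSE)
    }
  }
  empty_hits <- data.frame(input_index = integer(), system = character(),
                           code = character(), condition_id = character(),
                           match_kind = character(), stringsAsFactors = FALSE)
  empty_un <- data.frame(input_index = integer(), system = character(),
                         code = character(), stringsAsFactors = FALSE)
  hits <- if (length(hits)) do.call(rbind, hits) else empty_hits
  unmapped <- if (length(unmapped)) do.call(rbind, unmapped) else empty_un
  structure(
    list(profile = unique(hits$condition_id), hits = hits,
         unmapped = unmapped),
    class = "qcs_mapping"
  )
}
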