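# Catalog: the rule base of comorbid conditions, their clinical code lists,
# and Qualifying Comorbidity Sets (QCS) of size 1-3.

#' Recognised clinical code systems
#'
#' The closed set of code-system labels accepted throughout the package:
#' ICD-9-CM and ICD-10-CM diagnosis codes, CPT procedure codes and HCPCS
#' supply codes (the latter two are used as disability / functional-status
#' indicators in the claims definition of some conditions).
#'
#' @return Character vector of valid code-system labels.
#' @export
code_systems <- function() {
  c("ICD9CM", "ICD10CM", "CPT", "HCPCS")
}

assert_code_system <- function(system) {
  if (length(system) != 1L || !is.character(system) ||
      !(system %in% code_systems())) {
    stop("unknown code system ", deparse(substitute(system)), ": '",
         paste(system, collapse = ","),
         "' (expected one of ", paste(code_systems(), collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(system)
}

#' Normalise a clinical code string
#'
#' Codes are stored de-dotted and uppercase internally so that dotted
#' ("I50.9") and undotted ("I509") dialects compare equal.  Normalisation
#' uppercases the code and strips periods and all whitespace; it is
#' idempotent.
#'
#' @param raw Code string as authored (e.g. `"I50.9"`, `"428.0 "`).
#' @param system Code-system label, one of [code_systems()].  Required so
#'   that ambiguous strings (a bare `"4280"` could be ICD-9 or a HCPCS-like
#'   token) are never silently misattributed.
#' @return The canonical code string.
#' @examples
#' normalize_code("I50.9", "ICD10CM")   # "I509"
#' normalize_code("e66.01", "ICD10CM")  # "E6601"
#' @export
normalize_code <- function(raw, system) {
  assert_code_system(system)
  if (length(raw) != 1L || !is.character(raw)) {
    stop("code must be a single character string", call. = FALSE)
  }
  out <- toupper(gsub("[.[:space:]]", "", raw))
  if (!nzchar(out)) {
    stop("invalid code: '", raw, "' is empty after normalization",
         call. = FALSE)
  }
  out
}

new_code_entry <- function(system, raw, match_kind = "exact") {
  assert_code_system(system)
  if (!match_kind %in% c("exact", "prefix")) {
    stop("match_kind must be 'exact' or 'prefix', got '", match_kind, "'",
         call. = FALSE)
  }
  list(system = system, raw = raw,
       normalized = normalize_code(raw, system),
       match_kind = match_kind)
}

#' Construct a condition record
#'
#' @param id Stable slug identifying the condition within a catalog.
#' @param display_name Human-readable label.
#' @param organ_system Grouping label used for screening pages
#'   (e.g. `"Neurologic"`, `"Cardiac"`).
#' @param clinical_definition Free-text consensus definition.
#' @param included_diagnoses,excluded_diagnoses Display-text term lists that
#'   differentiate this condition from its neighbours.  Carried for the
#'   screening UI and documentation; they are not executable rules.
#' @param codes List of code entries, each a list with `system`, `code` and
#'   optional `match_kind` (`"exact"`, the default, or `"prefix"`).
#' @return A `qcs_condition` list.
#' @export
new_condition <- function(id, display_name = id, organ_system,
                          clinical_definition = "",
                          included_diagnoses = character(),
                          excluded_diagnoses = character(),
                          codes = list()) {
  if (!nzchar(id)) stop("condition id must be non-empty", call. = FALSE)
  if (!nzchar(organ_system)) {
    stop("condition '", id, "': organ_system must be non-empty",
         call. = FALSE)
  }
  overlap <- intersect(included_diagnoses, excluded_diagnoses)
  if (length(overlap)) {
    stop("condition '", id, "': included and excluded diagnoses overlap: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  entries <- lapply(codes, function(ce) {
    kind <- if (is.null(ce$match_kind)) "exact" else ce$match_kind
    new_code_entry(ce$system, ce$code, kind)
  })
  structure(
    list(id = id, display_name = display_name, organ_system = organ_system,
         clinical_definition = clinical_definition,
         included_diagnoses = as.character(included_diagnoses),
         excluded_diagnoses = as.character(excluded_diagnoses),
         codes = entries),
    class = "qcs_condition"
  )
}

canonical_set <- function(members) {
  sort(unique(as.character(members)))
}

set_key <- function(members) paste(canonical_set(members), collapse = "+")

#' Construct a catalog
#'
#' A catalog couples a condition dictionary with a list of Qualifying
#' Comorbidity Sets: combinations of 1-3 conditions whose joint presence
#' classifies a patient as multimorbid.
#'
#' @param conditions List of `qcs_condition` objects (see [new_condition()]).
#' @param sets List of character vectors of condition ids, each of length
#'   1-3.
#' @param version Catalog version string.
#' @param set_labels Optional character vector of provenance labels, one per
#'   set (NA allowed).
#' @param non_clinical Logical flag marking catalogs (such as the bundled toy
#'   catalog) that must not be used on real claims data.
#' @return A `qcs_catalog` object.
#' @export
new_catalog <- function(conditions, sets, version = "0",
                        set_labels = NULL, non_clinical = FALSE) {
  if (!length(conditions)) {
    stop("catalog must contain at least one condition", call. = FALSE)
  }
  ids <- vapply(conditions, function(cond) cond$id, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate condition id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  names(conditions) <- ids

  sets <- lapply(sets, canonical_set)
  for (i in seq_along(sets)) {
    members <- sets[[i]]
    if (length(members) < 1L || length(members) > 3L) {
      stop("sets[", i, "]: set size ", length(members), " > 3 or < 1",
           call. = FALSE)
    }
    missing <- setdiff(members, ids)
    if (length(missing)) {
      stop("sets[", i, "]: unresolvable member(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  keys <- vapply(sets, set_key, character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate qualifying set(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = "; "),
         call. = FALSE)
  }
  if (is.null(set_labels)) set_labels <- rep(NA_character_, length(sets))

  structure(
    list(version = as.character(version), conditions = conditions,
         sets = sets, set_labels = as.character(set_labels),
         non_clinical = isTRUE(non_clinical)),
    class = "qcs_catalog"
  )
}

#' Load a catalog from a JSON document
#'
#' The on-disk format is a UTF-8 JSON object with keys `version` (string),
#' `conditions` (array of objects with `id`, `display_name`, `organ_system`,
#' `clinical_definition`, `included_diagnoses`, `excluded_diagnoses` and
#' `codes`, the latter an array of `{system, code, match_kind}` objects) and
#' `sets` (array of arrays of condition ids, sizes 1-3).  An optional
#' boolean `non_clinical` marks demonstration catalogs.  All codes are
#' normalised on load; condition iteration order is document order.
#'
#' @param source Path to a JSON file, or a JSON string.
#' @return A `qcs_catalog`.
#' @seealso [write_catalog()] for the inverse; [validate_catalog()].
#' @export
load_catalog <- function(source) {
  doc <- jsonlite::fromJSON(source, simplifyVector = FALSE)
  if (!is.list(doc)) stop("catalog document must be a JSON object",
                          call. = FALSE)
  for (key in c("version", "conditions", "sets")) {
    if (is.null(doc[[key]])) {
      stop("catalog document: missing top-level key '", key, "'",
           call. = FALSE)
    }
  }
  conditions <- lapply(seq_along(doc$conditions), function(i) {
    cd <- doc$conditions[[i]]
    if (is.null(cd$id)) {
      stop("conditions[", i, "]: missing 'id'", call. = FALSE)
    }
    codes <- lapply(cd$codes, function(ce) {
      if (is.null(ce$system) || is.null(ce$code)) {
        stop("conditions[", i, "] ('", cd$id,
             "'): each code needs 'system' and 'code'", call. = FALSE)
      }
      list(system = ce$system, code = ce$code, match_kind = ce$match_kind)
    })
    new_condition(
      id = cd$id,
      display_name = if (is.null(cd$display_name)) cd$id else cd$display_name,
      organ_system = if (is.null(cd$organ_system)) "" else cd$organ_system,
      clinical_definition =
        if (is.null(cd$clinical_definition)) "" else cd$clinical_definition,
      included_diagnoses = unlist(cd$included_diagnoses) %||% character(),
      excluded_diagnoses = unlist(cd$excluded_diagnoses) %||% character(),
      codes = codes
    )
  })
  sets <- lapply(doc$sets, function(s) unlist(s))
  new_catalog(conditions, sets,
              version = doc$version,
              non_clinical = isTRUE(doc$non_clinical))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialise a catalog back to JSON
#'
#' Round-trips with [load_catalog()]: reloading the written document yields
#' a catalog equal field-by-field to the original.
#'
#' @param catalog A `qcs_catalog`.
#' @param path Optional file path; when `NULL` the JSON text is returned.
#' @return Invisibly the JSON string (also written to `path` when given).
#' @export
write_catalog <- function(catalog, path = NULL) {
  stopifnot(inherits(catalog, "qcs_catalog"))
  doc <- list(
    version = jsonlite::unbox(catalog$version),
    non_clinical = jsonlite::unbox(catalog$non_clinical),
    conditions = lapply(unname(catalog$conditions), function(cond) {
      list(
        id = jsonlite::unbox(cond$id),
        display_name = jsonlite::unbox(cond$display_name),
        organ_system = jsonlite::unbox(cond$organ_system),
        clinical_definition = jsonlite::unbox(cond$clinical_definition),
        included_diagnoses = cond$included_diagnoses,
        excluded_diagnoses = cond$excluded_diagnoses,
        codes = lapply(cond$codes, function(ce) {
          list(system = jsonlite::unbox(ce$system),
               code = jsonlite::unbox(ce$raw),
               match_kind = jsonlite::unbox(ce$match_kind))
        })
      )
    }),
    sets = catalog$sets
  )
  txt <- jsonlite::toJSON(doc, pretty = TRUE)
  if (!is.null(path)) writeLines(txt, path)
  invisible(as.character(txt))
}

#' Validate a catalog and report issues
#'
#' Re-checks every structural invariant and adds two warning-level checks:
#' conditions never referenced by any qualifying set, and code collisions
#' (the same normalised code mapped to more than one condition within one
#' code system; the condition definitions are supposed to be mutually
#' differentiable, so a collision usually signals a catalog defect).
#'
#' @param catalog A `qcs_catalog`.
#' @return A data frame with columns `level` (`"error"`/`"warning"`),
#'   `where` and `message`; zero rows when the catalog is clean.
#' @export
validate_catalog <- function(catalog) {
  stopifnot(inherits(catalog, "qcs_catalog"))
  issues <- list()
  add <- function(level, where, message) {
    issues[[length(issues) + 1L]] <<-
      data.frame(level = level, where = where, message = message,
                 stringsAsFactors = FALSE)
  }

  ids <- names(catalog$conditions)
  for (i in seq_along(catalog$sets)) {
    members <- catalog$sets[[i]]
    if (length(members) < 1L || length(members) > 3L) {
      add("error", paste0("sets[", i, "]"),
          paste0("set size ", length(members), " outside 1-3"))
    }
    missing <- setdiff(members, ids)
    if (length(missing)) {
      add("error", paste0("sets[", i, "]"),
          paste0("unresolvable member(s): ", paste(missing, collapse = ", ")))
    }
  }
  keys <- vapply(catalog$sets, set_key, character(1))
  for (k in unique(keys[duplicated(keys)])) {
    add("error", "sets", paste0("duplicate set {", k, "}"))
  }

  used <- unique(unlist(catalog$sets))
  for (id in setdiff(ids, used)) {
    add("warning", paste0("conditions/", id),
        "condition is not a member of any qualifying set")
  }

  code_rows <- do.call(rbind, lapply(ids, function(id) {
    codes <- catalog$conditions[[id]]$codes
    if (!length(codes)) return(NULL)
    data.frame(id = id,
               system = vapply(codes, `[[`, character(1), "system"),
               normalized = vapply(codes, `[[`, character(1), "normalized"),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(code_rows)) {
    key <- paste(code_rows$system, code_rows$normalized)
    for (k in unique(key[duplicated(key)])) {
      rows <- code_rows[key == k, ]
      if (length(unique(rows$id)) > 1L) {
        add("warning", "codes",
            paste0("code ", rows$normalized[1], " (", rows$system[1],
                   ") mapped to multiple conditions: ",
                   paste(unique(rows$id), collapse = ", ")))
      }
    }
  }

  if (!length(issues)) {
    return(data.frame(level = character(), where = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

#' Group catalog conditions by organ system
#'
#' Mirrors the screening app's paged layout: conditions are grouped by organ
#' system, systems ordered by first appearance in the catalog and conditions
#' within a system kept in catalog order.  Every condition appears exactly
#' once and no empty group is produced.
#'
#' @param catalog A `qcs_catalog`.
#' @return Named list: organ system -> character vector of condition ids.
#' @export
conditions_by_system <- function(catalog) {
  stopifnot(inherits(catalog, "qcs_catalog"))
  systems <- vapply(catalog$conditions, `[[`, character(1), "organ_system")
  out <- list()
  for (i in seq_along(systems)) {
    out[[systems[[i]]]] <- c(out[[systems[[i]]]], names(systems)[[i]])
  }
  out
}

#' @export
print.qcs_catalog <- function(x, ...) {
  cat("<qcs_catalog> version ", x$version,
      if (x$non_clinical) "  [NON-CLINICAL / synthetic]" else "", "\n",
      "  conditions: ", length(x$conditions),
      "  qualifying sets: ", length(x$sets), "\n", sep = "")
  sizes <- table(factor(lengths(x$sets), levels = 1:3))
  cat("  set sizes: ", paste(names(sizes), sizes, sep = "x",
                             collapse = ", "), "\n", sep = "")
  invisible(x)
}
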