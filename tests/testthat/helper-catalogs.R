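# Shared builders: a small hand-written catalog and a randomised catalog
# generator for property-style tests.

tiny_catalog <- function() {
  conds <- list(
    new_condition("a", "Condition A", "Cardiac",
                  codes = list(list(system = "ICD10CM", code = "I50.9"))),
    new_condition("b", "Condition B", "Pulmonary",
                  codes = list(list(system = "ICD10CM", code = "J18",
                                    match_kind = "prefix"))),
    new_condition("c", "Condition C", "Cardiac",
                  codes = list(list(system = "ICD9CM", code = "428.0"))),
    new_condition("d", "Condition D", "Renal"),
    new_condition("e", "Condition E", "Renal")
  )
  new_catalog(conds, list("a", c("b", "c"), c("b", "d", "e")),
              version = "tiny-test")
}

# Random catalog: n_cond conditions (ids z01..), up to n_sets distinct sets
# of size 1-3.  Uses the current RNG stream; seed at the call site.
random_catalog <- function(n_cond = 12, n_sets = 8) {
  ids <- sprintf("z%02d", seq_len(n_cond))
  conds <- lapply(ids, function(id) {
    new_condition(id, organ_system = sample(c("Sys1", "Sys2", "Sys3"), 1))
  })
  sets <- list()
  keys <- character()
  tries <- 0
  while (length(sets) < n_sets && tries < n_sets * 20) {
    tries <- tries + 1
    members <- sort(sample(ids, sample(1:3, 1)))
    key <- paste(members, collapse = "+")
    if (!key %in% keys) {
      keys <- c(keys, key)
      sets[[length(sets) + 1]] <- members
    }
  }
  new_catalog(conds, sets, version = "random-test")
}

random_profile <- function(catalog, p = 0.4) {
  ids <- names(catalog$conditions)
  ids[stats::runif(length(ids)) < p]
}

fixed_clock <- function(start = 100, step = 1) {
  t <- start - step
  function() {
    t <<- t + step
    t
  }
}
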