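---
title: "Qualifying Comorbidity Set screening: model, fixtures and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Qualifying Comorbidity Set screening: model, fixtures and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcscreen)
```

## The model

A catalog pairs a dictionary of comorbid conditions with a list of
*qualifying sets* — combinations of one, two or three condition ids. A
condition profile \(P\) (the set of conditions attributed to one patient) is
classified multimorbid exactly when some qualifying set \(S\) satisfies
\(S \subseteq P\). That is the whole decision rule: no weights, no scores,
no interactions beyond set membership. Its epidemiological content lives
entirely in the catalog, which encodes which co-occurrences carry excess
perioperative mortality risk; the package treats the catalog as input data
and makes no attempt to re-derive it.

Two consequences of the rule shape the implementation:

* **Monotonicity.** Adding a condition can only add matched sets, so
  multimorbid status never reverts as a screen progresses. This licenses
  early termination: the first selection that completes any qualifying set
  settles the answer.
* **Witness structure.** A profile may contain several qualifying sets.
  Batch evaluation (`evaluate_profile`) reports all of them, ordered by
  size and then lexicographically by member ids, because research users
  want the full witness list; `first_triggering_set` preserves what the
  interactive screen would have announced. The incremental matcher uses an
  inverted index with per-set countdown counters, so each selection touches
  only the sets containing that condition.

## Catalog format and code handling

The catalog file is UTF-8 JSON with top-level keys `version`, `conditions`,
`sets`, and an optional `non_clinical` flag. Each condition carries a
stable id, display name, organ system (used to build screening pages),
free-text clinical definition, included/excluded diagnosis terms, and a
code list. Included/excluded diagnoses are *display text* for the
screening UI — whether the original app enforced exclusions as negative
code rules is not documented, so they are deliberately not executable here.

Codes are stored de-dotted and uppercase; dotted and undotted dialects of
the same code are equal after normalisation, which is idempotent. Every
code entry names its system explicitly (ICD9CM, ICD10CM, CPT, HCPCS) —
auto-detection is refused because a bare numeric string is ambiguous across
systems and silent misattribution is worse than a required field. Matching
is exact by default; `match_kind: "prefix"` opts a row into code-family
semantics (ICD subtrees, e.g. `J18` covering `J18.0`–`J18.9`), since
published code lists do not always say which dialect they intend. When a
code satisfies both an exact and a prefix row of the same condition, the
hit is recorded as exact. A code mapping to several conditions contributes
all of them; `validate_catalog()` warns about such collisions (and about
conditions unused by any set) because the condition definitions are meant
to be mutually differentiable.

## The screening session

`start_session()` orders pages by organ system in catalog
first-appearance order. Selections delegate to the incremental matcher;
the completing selection flips the session to `multimorbid`, records the
triggering set, and rejects further selections — mirroring the app
behaviour users singled out ("it stops once multimorbidity is
established"). Deselection fully rewinds the match state (replay
equivalence is property-tested). Timestamps come from an injected clock so
replays and tests are deterministic; the elapsed time in a
`qcs_session_result` mirrors the stopwatch measurement used in the
feasibility trial. The notification payload is a deterministic plain-text
block standing in for the app's investigator e-mail; transport is out of
scope and no patient identifiers are added beyond what the caller passes.

## Evaluation statistics

The unit of analysis is the **trial** (participant × scenario). With 10
raters and 5 scenarios of which 3 are truly multimorbid, the pooled
denominators are 30 multimorbid and 20 non-multimorbid trials — this is why
sensitivity and specificity are trial-level, not condition-level.
Selection errors per trial are set arithmetic:
`n_correct = |selected ∩ intended|`, `n_incorrect = |selected \ intended|`,
`n_missed = |intended \ selected|`, with the conservation laws
`n_correct + n_missed = |intended|` and
`n_correct + n_incorrect = |selected|` enforced by construction and tested.
Tally rows in the study report are *cumulative* ("incorrectly chose 1
comorbidity" counts trials with ≥1 incorrect selection) — the only reading
under which the published per-scenario rows fit 10 participants.

Timing uses the classic paired *t* test on per-participant differences
(df = n−1, two-sided p). It is implemented from the textbook formula and
cross-checked against `stats::t.test` in the suite; zero-variance
differences raise a degenerate-test error instead of returning a
meaningless statistic. Likert items are summarised by the arithmetic mean
and **sample** SD (n−1): the published "easy to use" row (4.8, SD 0.42) is
consistent with the sample SD of the unique compatible 10-rating multiset
(eight 5s, two 4s) and inconsistent with the population SD (0.40).

The interpretation band attached to a mean rating is configurable
(`default_likert_bands()`), because any such verbal banding is editorial.
The default is calibrated to reproduce the published interpretation
column; notably its top band starts at 4.6 so that a 4.7 mean reads
"Strongly agree", wider than the symmetric bottom band — the published
labels are not the product of a symmetric rule.

## Synthetic fixtures: what they pin and what they do not

`builtin_scenarios()` encodes the five hypothetical emergency-general-
surgery scenarios at the resolution the publication printed: truth labels
(No, Yes, Yes, No, Yes), intended-comorbidity counts (2, 4, 3, 2, 2; total
13), total-possible counts (2, 5, 4, 2, 4), and the conditions the results
narrative names. Conditions the publication does not name are synthetic
placeholders (`unnamed_*`) — their identities are unrecoverable, so tests
pin only the printed figures.

`builtin_toy_catalog()` is a NON-CLINICAL catalog over the ten
publication-named conditions plus those placeholders. Its qualifying sets
are constructed so that every scenario's truth label reproduces under
`evaluate_profile`, including the redundancy the results imply: scenario E
remains multimorbid with pneumonia dropped (six raters missed pneumonia,
yet all ten classified the scenario correctly). Its code lists are
illustrative; the catalog is flagged `non_clinical` and the CLI refuses to
classify claims with it unless `--allow-toy` is passed.

`builtin_trial_log()` reconstructs the 50-trial selection log. Three
printed figures could not be reconciled exactly, and the fixture pins only
the arithmetically self-consistent ones:

* the "missed 1 comorbidity" row sums to 20 across scenarios but its
  printed total is 19;
* scenario B's miss rows (9 missed ≥1, 3 missed ≥2 of 10 raters) admit at
  most 12 per-condition miss instances, while the narrative names 13; the
  fixture keeps the 9 protein-calorie-malnutrition and 3 depression misses
  and drops the single chronic-lung-disease miss;
* the status labels printed per scenario cannot all be regenerated by a
  deterministic matcher from any selection log satisfying the miss rows
  (scenario B's one false negative would share its selection set with two
  true positives). The fixture therefore records `predicted_multimorbid`
  as *observed data* following the printed correct counts, rather than
  recomputing it. The simulator, by contrast, always derives predictions
  from `evaluate_profile`.

One related discrepancy in the source is left unreconciled by design: the
results text prints a sensitivity denominator of 22/30 where the abstract
and the table arithmetic (9 + 10 + 10 correct over 30 multimorbid trials)
give 29/30; the package reproduces 29/30 and does not attempt to model the
22.

## Generators

`generate_patient()` draws each catalog condition independently at a given
prevalence (default 0.15, a mid-range figure for chronic-condition
prevalence in an older surgical population). Independence is a documented
simplification: qualifying sets are precisely about co-occurrence, so a
correlated-sampling model is a future extension, not something to fake
silently. `simulate_trials()` emulates the 10 × 5 design with a
per-condition rater error model: a present condition is missed with
`miss_rate`, an absent catalog condition falsely selected with
`false_select_rate`, independently — matching the per-condition error
tallies the feasibility study reports. Defaults (0.2, 0.005) were
calibrated once from the printed tallies (26 misses over 130 intended
instances; 3 false selections over ≈50 × 12 opportunities). Predicted
labels are always recomputed from the catalog, so with both rates at zero
the simulated study recovers sensitivity = specificity = 100% exactly —
a green parameter-recovery test establishes internal consistency of
generator + matcher + evaluator, *not* clinical validity of any catalog.

Everything stochastic takes an explicit seed; identical seeds give
identical trial lists and study reports end to end.

## Numerical and edge-case choices

* Percentages and means are kept at full precision internally; rounding
  (1 dp for percentages, 1–2 dp for means/SDs) is display-only.
* Zero denominators (no multimorbid trials for sensitivity, no
  non-multimorbid for specificity) raise undefined-metric errors, never 0.
* Matched-set ordering (size, then lexicographic) is a package convention;
  the decision rule itself is order-free, but tests need stable output.
* A size-1 set coexisting with a superset ({a} and {a, b}) is legal and
  both are reported.
* Duplicate selections in a session are no-op warnings; selecting after
  termination and double-finishing are errors.

## Limitations

The shipped catalog is synthetic; real use requires the full clinical
catalog (conditions, code lists and qualifying sets), which is supplementary
/ third-party material and must be supplied by the user as data. The mapper
does no ICD-9↔ICD-10 crosswalking, date or claim-type logic. Risk
quantification (e.g. mortality odds attached to a positive screen) is out of
scope, as is any reproduction of the published timing comparison: the
per-participant raw times were not published, so the timing code is
exercised on synthetic data only.
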