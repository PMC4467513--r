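---
title: "Methods: hierarchical cause assignment for child verbal autopsy data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical cause assignment for child verbal autopsy data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vacause)
```

## The problem and the model

Verbal autopsy (VA) assigns a cause of death from a structured caregiver
interview about the signs and symptoms preceding a child's death. This
package implements a fully deterministic, standardized assignment
procedure for deaths at ages 0–59 months, of the kind used to re-analyze
national VA studies in place of physician review. Its elements are:

1. **Case definitions.** Each cause has a boolean predicate tree over
   coded questionnaire items: equality tests on binary/categorical
   items, count thresholds (`item_at_least`), closed duration windows in
   whole days (`duration_in_days`), combined with `all_of` / `any_of` /
   `none_of`. Evaluation is pure and deterministic. Missing or
   "don't know" responses count as symptom-absent: a missing response
   never satisfies a leaf, so a diagnosis can only be *blocked*, never
   *created*, by non-response (negations via `none_of` are the sole
   construct missingness can satisfy, e.g. "no recent TB diagnosis").
   This is the conservative choice — it avoids spurious diagnoses at the
   cost of under-calling causes whose items went unasked.

2. **Two parallel hierarchies.** Neonates (0–27 completed days) and
   children (28 days – 59 months; months converted at 30.4375 days per
   month, so the cap is 1826 days) are screened against separate ordered
   cause lists, more specific diagnoses first. The walk stops at the
   first matching cause outside the multi-cause group; a death matching
   nothing is *unspecified*.

3. **Multi-cause group.** Measles, diarrhea and ARI/pneumonia (child
   stratum only) are assigned jointly: once one of them fires, later
   non-group causes are masked and the remaining group members are still
   screened, so a death can be provisionally measles *and* diarrhea. The
   published constraints on placement are machine-validated:
   pneumonia < meningitis < malaria < AIDS among children, no malaria or
   AIDS among neonates, neonatal sepsis after pneumonia and diarrhea.
   The full order beyond those constraints, and every definition other
   than the AIDS and diarrhea screens, is a reconstruction from WHO-style
   VA indicators; both ship as editable, schema-validated YAML rather
   than hard-coded rules, and reconstructed entries are flagged as such.

4. **Redistribution.** Multi-cause deaths are resolved in proportion to
   the pre-redistribution CSMFs of the group causes, computed from the
   singly-assigned group deaths in the same stratum with their survey
   weights. The default *fractional* mode splits the death's weight
   (deterministic, preserves totals exactly); a *sampling* mode draws a
   single cause with the same probabilities from a user seed. Both have
   the same expected CSMFs; fractional is the default because downstream
   CSMF tables are then seed-free. If all relevant pre-redistribution
   CSMFs are zero the split is equal, with a message.

## Estimation

CSMF(c) is the ratio Σ wᵢaᵢ(c)/Σ wᵢ of allocated survey weight to total
weight in the age group (neonates, children, or 0–59 months pooled over
the shared weights). Standard errors, when requested, use Taylor
linearization of this ratio estimator with with-replacement sampling of
PSUs within design strata — the standard complex-survey variance of a
weighted proportion. Strata containing a single PSU are treated as
certainty units and contribute no variance; with uniform weights and one
record per PSU the estimator reduces to p(1−p)/(n−1), which the tests
check as a closed-form limit.

Per-cause agreement with a second coder (e.g. a physician-review column)
is Cohen's κ on the cause-vs-rest binarization, with the large-sample
two-rater variance of Fleiss, Cohen and Everitt. Deaths provisionally
assigned to multiple causes before redistribution are excluded from the
agreement input, because their final single cause is an artifact of
redistribution rather than of the coder. When expected agreement is 1 —
typically a cause neither coder ever assigns — κ is reported as 0 with
SE 0 and a degeneracy flag rather than NaN. Kappa is computed unweighted:
it is an individual-level concordance measure, and weighting it would
conflate design and agreement. Internally κ and its SE are computed in
scaled-integer arithmetic (n·p₀, n²·pₑ, …), which is exact for any
realistic sample size; the proportion-scale formula loses up to ~10⁻⁸
near pₑ → 1 through the (1−pₑ)⁻⁴ amplification.

Ranking (`rank_top`) covers *single* causes only — "unspecified" and
residual "other" groups are excluded — with ties broken by hierarchy
order, then lexicographically. Population-level comparison reports
per-cause CSMF differences in percentage points, the top-k overlap count
and per-cause rank shifts.

## The synthetic-data generator

The original national microdata are not redistributable, so validation
uses a generator with known truth. A scenario fixes n, the neonatal
proportion, a true CSMF per stratum (possibly including *unspecified*),
a sensitivity, a per-item false-positive rate, a comparator error
matrix, and the survey-design shape; `scenario_from_paper()` presets the
three study populations (530 deaths / 126 neonatal; 360/121; 188/71)
with the published algorithm-derived CSMFs, renormalized within stratum,
as the true fractions.

Symptom emission is *definition-aware*: the generator enumerates the
minimal satisfying assignments of each cause's predicate tree, keeps
those under which the full hierarchy walk recovers exactly that cause
(a cause with no such assignment is rejected at scenario build time),
and samples uniformly among them. Item-independent symptom draws would
not give this guarantee: an earlier, less specific definition could mask
the true cause even with perfect reporting.

The noise model has two parts, both governed by one documented RNG
stream per scenario (stratum, true cause, age, design fields, weight,
sensitivity coin, assignment choice, false-positive coins, comparator
draw, per record in that order — so changing n perturbs subsequent
records; scenarios are compared at equal n):

* a **sensitivity** miss (probability 1 − s) emits an empty profile, so
  the death drifts to *unspecified* (or, with false positives, to a less
  specific cause);
* **false positives** flip binary items to "yes" at the per-item rate,
  under the emission contract that the resulting profile never satisfies
  a definition placed *above* the true cause's hierarchy position (such
  flips are rejected; count and duration items are never flipped).
  Noise therefore moves deaths *down* the hierarchy — mimicking
  under-reporting of specific signs — and can create genuine multi-cause
  records within the group, but never invents a more specific syndrome
  wholesale.

Because sensitivity misses are cause-neutral, their effect is a uniform
scaling of all specified-cause fractions with the lost mass appearing as
*unspecified*; the recoverable quantity under noise is therefore the
*composition over specified causes*, and that is what the recovery tests
compare (renormalized estimate vs renormalized empirical truth, within
three binomial standard errors). The unrenormalized fractions are biased
down by the factor s by construction, which is a property of the noise
model, not of the estimator.

What the generator does *not* emulate: correlated symptom reporting
beyond the definition structure, recall decay with time since death,
physician access to open narratives, or country-specific questionnaire
variants. Passing recovery tests therefore shows the pipeline is
internally consistent and statistically calibrated under this noise
model — not that the shipped case definitions are valid on real
interviews. The comparator coder is a per-stratum confusion matrix
(default: 60% exact reproduction, errors spread proportionally to the
true CSMF), a deliberately crude stand-in for physician review that
suffices to exercise the agreement machinery.

## Numerical and design choices

* **Inclusion criteria** are applied in fixed order (live birth; age
  0–59 months; complete interview; sufficient age information;
  age-appropriate questionnaire) and each exclusion is logged with the
  *first* failed criterion. "Complete interview" uses a record-level
  flag column when present, else a <50% missing-response rule;
  "sufficient age information" means age in days is derivable after unit
  conversion. Both operationalizations are package choices, flagged in
  configuration, since no standard operational rule exists.
* Stratum boundary: 27 days is a neonate, 28 days a child; exactly one
  stratum per included record.
* "More than 1 month" duration thresholds are implemented as > 30 days
  (`chronic_days_min = 31`); all duration windows are closed intervals
  in whole days. The diarrhea stool threshold (6), the AIDS respiratory
  window (3–27 days) and a symptom-only diarrhea variant (for
  data-quality probes of symptom prevalence) are tunable via
  `va_parameters()`.
* Ties in ranking cannot arise from the walk itself (the order is total);
  fraction ties are broken by hierarchy order for reproducibility.
* Config loading validates predicates against the codebook at load time,
  never at evaluation time; round-trips through YAML are lossless.

## Problem sizes used in the tests

The validation suite checks the kappa implementation against an
exhaustive cell-wise oracle over all ~14,000 2×2 tables with cell counts
0–10; kappa calibration over 1,000 replicates of independent coders
(n = 500, prevalence 0.2); walk-vs-naive-resolution equivalence on
10,000 randomized record × hierarchy evaluations; conservation over 100
random scenarios; exact recovery at n = 2,000 and noisy recovery
(s = 0.9, false-positive rate 0.02) at n = 5,000. These sizes give the
exhaustive checks full coverage and the stochastic checks tolerances
well below the effects of interest while keeping the default test run
fast.

## Known limitations

* Reconstructed definitions are plausible, not authoritative; analyses
  of real data should review and, where needed, override them via
  configuration.
* The AIDS screen is a broad disjunction with single-sign conditions;
  on real data it will have low specificity (the same concern applies to
  VA-based malaria ascertainment in low-transmission settings). The
  hierarchy mitigates this by placing both causes late, but cannot
  remove it.
* Linearized SEs assume many PSUs per stratum; single-PSU strata are
  silently treated as certainty units.
* Aggregated (category-mapped) tables drop SEs rather than propagating
  covariances between cause fractions.
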