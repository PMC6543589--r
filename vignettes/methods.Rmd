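---
title: "How vacoder assigns causes of death: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How vacoder assigns causes of death: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vacoder)
```

## The probabilistic model

Verbal autopsy interpretation here is a naive-Bayes style likelihood
propagation. A knowledge base supplies, for every binary indicator $i$ and
category $c$, the conditional probability $P(i \mid c)$ that the
*substantive* response on $i$ is observed when $c$ is the true category,
plus an unconditional prior $P_0(c)$. For one record, the posterior
likelihood is

$$L(c) \;\propto\; P_0(c) \prod_{i \in S} P(i \mid c),$$

where $S$ is the set of indicators whose recorded response equals their
substantive polarity. Three assumptions matter:

* **Conditional independence** of indicators given the category. Real VA
  items are correlated (fever and duration-of-fever bands trivially so);
  the exclusivity-group repair and the category-bank representation limit
  but do not remove this.
* **Asymmetric evidence.** Only substantive responses update the
  likelihood. A "no" on a yes-substantive item and a missing answer are
  treated identically: no factor. This makes the engine robust to
  incomplete instruments — the basis for WHO-2012/Tariff-2 harmonisation,
  where out-of-subset items are simply masked to missing — at the cost of
  ignoring potentially informative negatives.
* **Hard applicability.** A category inapplicable to the record's age band
  or sex has prior zero; a conditional grade of `N` (probability 0)
  annihilates a category outright.

The same propagation runs over three axes in the fixed order pregnancy
status → cause of death → circumstance category (COMCAT), because the
pregnancy outcome gates the maternal cause block.

## Letter grades and the probability ladder

Knowledge bases encode probabilities as letter grades `A+` … `E`, `N`. The
published knowledge base distributes its own numeric encoding in its
spreadsheet; the package therefore treats the ladder as configuration. The
default (`default_grade_map()`) is a geometric-style ladder
`A+ = 0.8, A = 0.5, A− = 0.2, B+ = 0.1, …, E = 1e−5, N = 0` — roughly
half-decade steps, strictly decreasing, validated exhaustively at load
time. Any strictly decreasing substitute can be passed to
`load_knowledge_base()`, e.g. to mirror a user-supplied published KB.
Because the engine normalises per case, only *ratios* of grades across
categories matter for ranking; the absolute scale affects the reported
likelihood magnitudes and hence the reporting thresholds.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `top_min` | 0.4 | minimum normalised likelihood for any cause to be reported |
| `ratio_min` | 0.5 | causes 2–3 must reach this fraction of the top likelihood |
| `max_causes` | 3 | reported causes per death |
| `gate_maternal` | `TRUE` | zero the `09.*` block when pregnancy status is not-pregnant/not-applicable |
| HIV / malaria level | `high` | prior multipliers 1 / 0.1 / 0.01 for high / low / very low |

The reporting thresholds follow the established lineage of this model
family; the defaults are deliberately conservative (an uninformative record
whose top cause stays below 0.4 is wholly indeterminate rather than
assigned a weak cause). Prevalence levels rescale **priors only**, for the
HIV-related (01.03) and malaria (01.05) categories; scaling selected
conditionals instead would change the meaning of the knowledge base itself,
so it is not done. Partial application keeps the other disease's current
level, which makes the operation idempotent at `high` and commutative
across the two diseases.

Whether the pregnancy likelihood should *continuously* weight the maternal
priors rather than gate them is genuinely open; gating was chosen because
it is deterministic, auditable, and matches the staged processing order.
Setting `gate_maternal = FALSE` recovers the ungated behaviour.

## Consistency checking

Two rule classes, both configurable via `va_rules()`:

* **Errors exclude**: a record whose age band or sex cannot be resolved
  from the designated demographic indicators, or is asserted
  contradictorily, cannot be classified (applicability is undefined) and is
  excluded, with the rule firing recorded per record.
* **Warnings repair**: substantive responses on sex- or age-inapplicable
  items, and multiple yes answers within a mutually exclusive category bank
  (e.g. fever-duration bands), are set to missing and the record kept. In
  an exclusivity conflict the *last* member in KB order — by convention the
  longest/most severe band — is retained: deterministic and conservative,
  and always logged.

The rule list is not claimed complete; it is an extensible set, and a
second pass over cleaned records fires nothing (idempotence is tested).

## Numerical choices

* Likelihoods accumulate in log space and are normalised by the maximum
  before exponentiation, so long products cannot underflow; agreement with
  the direct product is tested to 1e−9 and order invariance to 1e−12.
* Zero handling: zero priors stay exactly zero through normalisation; a
  conditional of exactly 0 annihilates its category. If every category
  annihilates, the posterior falls back to uniform over positive-prior
  categories and the case is flagged `fallback_uniform`.
* Argmax ties (pregnancy, COMCAT) break by KB category order, which is
  stable and documented; cause ranking ties likewise.
* Continuous-to-band conversion uses left-closed, right-open intervals, so
  a boundary value lands in the upper band.

## CSMF aggregation and comparison

Population fractions are means of *reported* likelihoods (plus the
indeterminate residual) rather than full pre-threshold posteriors, so the
population table is exactly the column-average of the per-case output rows
— the two outputs cannot disagree. Strata default to under-5 (neonate +
child, including stillbirths) versus 5-plus. Proportional redistribution
removes the indeterminate row by scaling each cause by $1/(1-p_{indet})$;
it is idempotent and conserves mass to 1e−9 through merge and broad-group
rollups (tested).

Lin's concordance correlation coefficient uses population ($n$-denominator)
moments, matching the Stata `concord` convention, with a Fisher-z interval
using Lin's variance ($n-2$ denominator); a percentile bootstrap is
available. Comparisons over two CSMF tables pair every cause present in
both tables for the stratum, *keeping* zero fractions — near-axis rare
causes are informative about disagreement and dropping them would flatter
the coefficient. For tables that tabulate an indeterminate row the row is
included as a point by default; the packaged published format-comparison
tables reproduce their reported coefficients most closely in exactly that
mode, which resolved the choice. Post-redistribution tables have no such
row, so the flag is moot there.

A transcription note on the packaged evaluation fixtures: the broad-group
rows of the PHMRC table are internally inconsistent with their own member
rows in four cells (the ≥5 infections and other-NCD cells of the
hospital-assigned column appear transposed, and the under-5 other-NCD cells
include the stillbirth fraction a second time). The acceptance tests assert
additivity where the printed rows are consistent and assert the diagnosed
structure — rather than agreement — for those four cells.

## What the synthetic generator does and does not emulate

`generate_kb()` plants a disjoint signature of indicators per cause
(grade `A+`, i.e. 0.8) on a low-grade background chosen by the
`informativeness` dial (`0.8 × (1 − informativeness)` snapped to the grade
ladder), with priors snapped from the planted CSMF, demographic indicators,
a 3-category pregnancy block and a neutral COMCAT block. `generate_cohort()`
draws each case's cause from the planted CSMF and each symptom response
independently given the cause, applies missingness, and fixes demographics
deterministically (demographics are never blanked, so synthetic records
pass consistency checking; the consistency rules are tested with
deliberately corrupted records instead).

The generator deliberately shares the engine's conditional-independence
assumption: recovery of the planted CSMF is then a *well-posed oracle
test* of the implementation — KB I/O, masking, propagation, thresholds,
aggregation and redistribution all have to be right for the planted
fractions to come back. It is **not** evidence about field performance:
real VA data have correlated symptoms, informative missingness,
interviewer effects and causes outside any signature structure, none of
which are modelled. Defaults (48 indicators, 4 causes, informativeness
0.9, missingness 0.1) give a clearly-separated regime comparable to a
well-specified instrument.

Problem sizes in the shipped tests were chosen at desk scale: the planted
recovery check runs a seeded 2000-case cohort (±0.05 per-cause tolerance
chosen from binomial sampling error at that size, concordance > 0.95),
unit tests use 40–400 cases, and the exhaustive propagation oracle
enumerates all $3^k$ response patterns for up to 5 indicators × 4
categories.

## Known limitations

* The engine ships no knowledge base; all numeric conclusions about real
  cohorts depend entirely on the KB supplied by the user.
* COMCAT categories are processed generically as a configurable category
  axis; the package takes no position on the category semantics.
* No uncertainty quantification: likelihoods are point values, and CSMFs
  carry no interval (the concordance CI quantifies only the comparison).
* Negative evidence is ignored by design (see above), so two records
  differing only in explicit "no" versus missing classify identically.
* Throughput is adequate for batch use (thousands of cases per minute on
  one core for mid-sized KBs) but the per-case loop is interpreted R; very
  large national datasets may warrant chunking.
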