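---
title: "Classifying the structure and statistic formats of clinical trial tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying the structure and statistic formats of clinical trial tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialtables)
```

## The problem

Automated data extraction from randomized controlled trial (RCT) reports has
to contend with the fact that the quantitative payload sits in tables, and
that tables communicate through two intertwined conventions:

* **Measurement context** — every printed statistic belongs to a *data
  element* (the characteristic measured), usually an *arm* (the intervention
  group), and often a *time point*. Tables allocate these three kinds of
  context to their rows and columns: a 1×1 table spends one kind on each
  axis (most commonly data elements on rows, arms on columns), a 2×1 table
  nests two kinds on the rows, a 1×2 table nests two on the columns. Fifteen
  named arrangements cover the comparative literature, with a residue of
  stratified tables and tables of purely comparative statistics.
* **Statistic formats** — each cell prints a micro-format such as
  `12.4 ± 2.3`, `14 (10-18)`, or `2/59 (3.4%)`. The same glyphs serve
  different decompositions (`30 (75)` may be mean (SD) or n (%)), so format
  identification is a classification problem of its own.

`trialtables` implements both classifiers, a tagging vocabulary for
reporting practices, corpus summaries with score intervals, and a synthetic
generator that provides exact ground truth for end-to-end testing.

## The metric grammar

A `statistic_format` is an ordered token pattern over numeric placeholders
(`MEAN`, `SD`, `MEDIAN`, `P25`, `P75`, `MIN`, `MAX`, `N`, `N_TOTAL`,
`N_REST`, `PCT`, `CI_LO`, `CI_HI`) and literal delimiters. The catalog holds
the 14 continuous, 6 dichotomous, and 2 categorical formats observed in
practice plus the explicit `n/N (%)` form, ordered by observed frequency.
Numerical and parsing choices:

* **Unicode normalization.** `+/-` and `+-` normalize to `±`; minus sign,
  en and em dashes normalize to `-`; non-breaking spaces to spaces. The
  catalog keeps printed variants (parenthesis vs bracket IQRs, comma vs
  dash vs "to" separators) as distinct identifiers with identical
  semantics, because they are distinct printed conventions even though they
  decompose identically.
* **Decimal separator** is `.` only; a comma is always a delimiter.
* **Integer discipline.** `N`-type placeholders only match digit strings,
  and a parsed `PCT` must lie in [0, 100]; both rules prune inference
  ambiguity (e.g. `30.4 (7.5)` can only be mean (SD)).
* **Rounding** is half-up at the printed number of decimals everywhere
  (`round_half_up()`), matching how percentages are printed:
  `100·2/59 = 3.389…` prints as `3.4`. Consistency checks
  (`check_consistency()`) and denominator derivation
  (`derive_denominator()`) use exactly this rule, with a `1e-9` guard
  against binary-float artifacts.
* **Ambiguity precedence.** When a cell like `30 (75)` is ambiguous, the
  resolution order is: explicit declaration (a description/footnote
  declaration outranks a header one, mirroring the lowest-wins tagging
  rule), then the declared data-element kind, then array-level inference,
  then catalog order (most common format first). Bare single numbers are
  only attributed to `n` or `Mean` when the metric kind is declared;
  undeclared single numbers are reported uninferable rather than guessed.
* **Multi-array formats** (mean and SD, or n and %, in separate arrays)
  describe two parallel arrays; their per-cell pattern covers the primary
  array and the companion placeholder is recorded on the format.

Rendering is the exact inverse of parsing at printed precision, which gives
the property the tests lean on: for every non-multi-array catalog format and
admissible tuple, `parse(render(x)) == round_half_up(x, decimals)`.

## Context detection

Per-cell detectors feed a per-level majority vote:

* **Arm sizes** — `(n=K)`, `[n=K]`, `N = K`, trailing `, n=K`; removal of
  the size expression is idempotent on labels without one.
* **Time points** — in order: an amount with a time unit
  (`6-month follow-up` → 6 months), the pre/post vocabulary, incremental
  numbering (`t_2`, `Visit 3`). For fused cells (`"Placebo, T1"`) the
  anchored incremental patterns are retried on comma segments and on the
  first token.
* **Interventions** — the control/experimental vocabulary, a configurable
  full-name lexicon, its initialisms plus an all-caps short-token heuristic
  for abbreviations, and `Group A`-style codes as alternate labels.
  "Placebo" deliberately classifies as a full name, not a
  control/experimental label; the control vocabulary is a plain-text
  lexicon (`inst/extdata/lexicons/`) so the choice is configurable.
* **Statistic-name headers** — a level whose cells are statistic names
  (`Mean | SD` sub-columns) labels statistics, not context, and is excluded
  from the axis kinds.

Nesting within one axis is recognized from (a) spanning header cells,
(b) indentation, or (c) an exact repeating label cycle of period ≥ 2 — in
that precedence. The choice of precedence among a spanned *and* indented
header is a design decision of this package, not an assertion about
authorial intent. Indented groups whose inner sequences differ across
groups are category labels of a categorical data element rather than a
nested context level; identical inner sequences are a nested level. A
subgroup-vocabulary level (sex, site, age group) flags stratified
reporting — best effort, since no printed criterion exists — and an axis of
comparative-statistic headers (`P value`, `Mean difference (95% CI)`) flags
comparative-only tables. Both classify as OTHER, alongside axes deeper than
two kinds (`unsupported_depth`).

The classifier restricted to the 15 named (row kinds, column kinds,
embedded) triples is a bijection onto the sub-layout names; the test suite
enumerates all 15.

## Tagging, queries, and intervals

Tags are slash-separated paths in a fixed hierarchy (structure, context,
and metric attributes); a child implies its parent, and `validate_tags()`
reports violations rather than raising. Structure and context tags are
assigned per table and unioned per article; metric tags are per article,
with the description/footnote location outranking the header within one
table and union semantics across tables. Boolean queries use conventional
`NOT > AND > OR` precedence with parentheses; a tag matches if it or any
descendant is present.

Proportion intervals are **Wilson score intervals without continuity
correction** — the interval `prop.test(correct = FALSE)` inverts. The
uncorrected variant is fixed deliberately: it reproduces the published
interval endpoints from their counts at printed rounding (e.g. 66/78 →
75%–91%; 4/99 → 1.6%–9.9%), whereas the continuity-corrected variant does
not. At k = 0 the lower endpoint is exactly 0 and at k = n the upper is
exactly 1. Reported percentages round half-up to the printed precision.

The high-information-density classifier conjoins five article-level
properties: baseline or outcomes in a table, arm sizes reported,
interpretable intervention labels (full name or abbreviation; droppable),
units reported when unit-relevant metrics exist (articles with no
unit-relevant data elements satisfy the clause vacuously), and statistic
format declared.

## The synthetic generator

`synthetic_spec()` defaults encode the observed reporting frequencies: the
layout distribution is proportional to the per-table counts of the 15
sub-layouts plus stratified (8) and comparative-only (7) tables out of 174;
format distributions per metric kind, arm-size placement (embedded 50 /
separate array 6 / description 1, reported at 57/77), intervention-label
(26/25/23/3) and time-point-label (24/22/6) distributions, declaration and
unit rates, and the per-article composition (baseline table with
probability 66/78; one plus a Poisson(35/72) number of outcome tables with
probability 72/78, giving ≈ 2.2 tables per article) are proportional to the
corresponding published counts. Where the joint structure is
under-determined — how many tables of each type an article has — the
tables-per-article model above is this package's modeling choice.

Choices a user should know:

* Article-level properties (arms and their labels, size placement,
  declaration and unit locations) are sampled once per article,
  independently at the configured rates, and applied across the article's
  tables; `expected_density_rate()` gives the implied analytic
  density-match probability as a product of rates.
* Statistic formats are sampled once per table per metric kind, which is
  how articles overwhelmingly behave and what makes per-article metric
  tagging meaningful. A multi-array draw makes its table single-kind (an
  all-means or all-counts table) so the statistic sub-arrays are
  structurally uniform; sub-arrays render as indented statistic rows when
  data elements own the rows and as statistic sub-columns otherwise.
* True continuous values are drawn per (data element, arm, time point)
  from uniform center/spread summaries; the generator emits summaries only.
  Dichotomous and categorical counts are binomial/multinomial draws from
  the arm size, and every printed percentage is computed by half-up
  rounding from its count and denominator, so consistency holds by
  construction. Printed precision defaults to one decimal.
* Abbreviation labels are initialisms of the sampled full intervention
  names, so the abbreviation detector sees a realistic signal.
* Category labels render indented, in-cell (`Gender M/F` with `11/9`
  counts), or unindented in the same array; the rare separate-array
  placement is recognized by the detector when the caller supplies the
  secondary array but is not emitted by the generator. In-cell categorical
  metrics print bare counts.
* Participant-level and no-breakout tables (3 of 174 observed) are tagged
  and classified by the package but not emitted by the generator; the
  generator's tables always break out by arm.

What passing round-trip tests shows — and what it does not: on noise-free
generated tables the pipeline recovers layout class, context kinds, arm
sizes, and every metric constituent exactly (500 seeded tables in the
acceptance suite; format-frequency recovery uses 1000 tables and the
density check a 78-article corpus, sizes chosen to make the binomial
3-standard-error bands meaningful). Real tables add hazards the generator
deliberately omits: OCR noise, abbreviations resolvable only from full
text, merged multi-page fragments, units and labels outside any lexicon,
and formats outside the catalog. Results on synthetic corpora are
therefore an upper bound on real-world recovery, not an estimate of it.

## Known limitations

* Lexicon-driven detection: an arm labeled with an out-of-lexicon drug name
  and no size expression falls back to the data-element kind. Supplying a
  study-specific intervention lexicon is the intended remedy.
* Inferential statistics (p-values, effect sizes with CIs beyond the
  mean-CI format) are out of scope for the metric parser; comparative-only
  tables are recognized structurally and left unparsed.
* PDF and image ingestion are out of scope; rotated/multipage are metadata
  flags supplied by the reader, and the grid readers accept CSV/TSV, HTML,
  and grid-JSON only.
* The unit vocabulary is small and flat; unit conversion is not attempted.
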