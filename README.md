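# trialtables

Tools for the tabular side of evidence synthesis. Most of the quantitative
evidence in a randomized controlled trial (RCT) report lives in its tables,
printed as descriptive-statistic micro-formats — `12.4 ± 2.3`,
`median (IQR)`, `2/59 (3.4%)` — under headers that carry the *measurement
context*: which data element is measured, in which trial arm, at which time
point. Anyone building automated data extraction for systematic reviews has
to recognize that structure before a single number can be pulled out.

`trialtables` makes that structure executable:

- **Metric grammar.** A catalog of the statistic formats observed in
  comparative clinical tables — 14 continuous (7 mean, 7 median), 6
  dichotomous, 2 categorical, plus the fully explicit `n/N (%)` form — with
  a parser/renderer pair for each (`parse_metric()`, `render_metric()`),
  declaration matching (`parse_format_declaration()`), and array-level
  inference (`infer_format()`).
- **Context detection.** Header detectors for arm sizes (`"Placebo [n=25]"`),
  intervention label kinds, and time-point conventions; axis classification
  into the 1×1 / 2×1 / 1×2 taxonomy of context dimensions with its 15 named
  sub-layouts (`assign_context_kinds()`, `classify_structure()`).
- **Corpus tagging.** A reporting-practice tag hierarchy, per-table and
  per-article taggers, Boolean tag queries, and frequency tables with Wilson
  score confidence intervals (`tag_article()`, `boolean_query()`,
  `frequency_table()`, `wilson_ci()`), plus the high-information-density
  classifier (`density_classifier()`).
- **Synthetic ground truth.** A generator of annotated RCT baseline/outcome
  tables whose layout, format, and labeling distributions default to the
  observed survey frequencies (`synthetic_spec()`, `generate_table()`,
  `generate_corpus()`), with full round-trip verification
  (`verify_ground_truth()`).
- **I/O and CLI.** CSV/TSV, HTML, and a grid-JSON interchange format, and a
  command-line front end (`tables_cli()`; `inst/cli/trialtables.R`).

The core interval is the Wilson score interval for a binomial proportion
(the score test's normal approximation, no continuity correction): with
p̂ = k/n and z the standard-normal quantile,

    center = (p̂ + z²/2n) / (1 + z²/n)
    half   = z/(1 + z²/n) · √(p̂(1−p̂)/n + z²/4n²)

## Worked example

```r
library(trialtables)

# a baseline table as it would come out of a paper
m <- rbind(c("Characteristic", "Placebo (n=25)", "Aspirin (n=30)"),
           c("Age, years",     "54.2 ± 8.1",     "55.0 ± 7.9"),
           c("Smoking",        "",               ""),
           c("  Yes",          "12 (48.0%)",     "9 (30.0%)"),
           c("  No",           "13 (52.0%)",     "21 (70.0%)"))
g <- read_grid_json(write_grid_json(trialtables:::grid_from_matrix(m, 1, 1)))

s <- classify_structure(assign_context_kinds(g))
s
#> <context_structure> ONE_BY_ONE
#>   sub-layout: de_rows_arm_cols

recover_arm_sizes(g, assign_context_kinds(g))$sizes
#> Placebo Aspirin
#>      25      30

parse_metric("2/59 (3.4%)", "n_slash_n_pct")[c("n", "n_total", "pct")]
#> $n
#> [1] 2
#> $n_total
#> [1] 59
#> $pct
#> [1] 3.4

wilson_ci(66, 78)
#> 66/78 = 0.846, 95% CI 0.750-0.910 (Wilson score)

derive_denominator(2, 3.4, decimals = 1, n_max = 1000)
#> [1] 58 59
```

The table is recognized as the most common layout (data elements on rows,
arms on columns), the embedded arm sizes are recovered, the worked
dichotomous metric decomposes into subset/total/percentage (and the
percentage checks out against half-up rounding), 66 of 78 yields the score
interval 75%–91%, and the denominators consistent with "2 events, 3.4%" are
exactly 58 and 59.

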