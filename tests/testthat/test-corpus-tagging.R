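test_that("the score interval matches prop.test without continuity correction", {
  # independent oracle: stats::prop.test inverts the same score test
  for (kn in list(c(22, 52), c(66, 78), c(4, 99), c(35, 47), c(1, 7))) {
    ci <- wilson_ci(kn[1], kn[2])
    ref <- suppressWarnings(prop.test(kn[1], kn[2],
                                      correct = FALSE))$conf.int
    expect_equal(ci$lower, ref[1], tolerance = 1e-9)
    expect_equal(ci$upper, ref[2], tolerance = 1e-9)
  }
})

test_that("score interval endpoints behave at the boundary proportions", {
  ci <- wilson_ci(0, 10)
  expect_identical(ci$lower, 0)
  expect_gt(ci$upper, 0)
  ci <- wilson_ci(10, 10)
  expect_identical(ci$upper, 1)
  expect_error(wilson_ci(1, 0), "at least 1")
  ci <- wilson_ci(66, 78)
  expect_equal(round(ci$lower, 3), 0.750)
  expect_equal(round(ci$upper, 3), 0.910)
})

test_that("interval width is non-increasing in n at fixed proportion", {
  widths <- vapply(c(10, 20, 50, 100, 400, 1000), function(n) {
    ci <- wilson_ci(n / 2, n)
    ci$upper - ci$lower
  }, 0)
  expect_true(all(diff(widths) < 0))
})

test_that("tables are tagged for structure, features, and context", {
  t <- annotated_table(
    grid = fixture_baseline_grid(rotated = TRUE),
    structure = context_structure("DATA_ELEMENT", "ARM",
                                  sublayout = "de_rows_arm_cols"),
    table_type = "baseline", arm_breakout = "arm_level",
    arm_sizes = c(Placebo = 25L, Aspirin = 30L),
    arm_size_placement = "embedded_in_arm",
    intervention_kinds = "full_name")
  tg <- tag_table(t)
  expect_true(all(c("baseline_in_table",
                    "baseline_in_table/arm_level_breakout",
                    "context_1x1", "context_1x1/de_rows_arm_cols",
                    "arm_size_reported/embedded_in_arm",
                    "intervention_labels/full_name",
                    "table_features/rotated") %in% tg$tags))
  expect_identical(validate_tags(tg), character(0))

  comp <- annotated_table(
    structure = context_structure("DATA_ELEMENT", character(),
                                  cls = "OTHER",
                                  other_reason = "comparative_only",
                                  sublayout = "comparative_only"),
    table_type = "outcome", arm_breakout = "none")
  expect_true("other_structure/comparative_only" %in% tag_table(comp)$tags)

  # a table with no descriptive statistics is not tagged
  empty <- annotated_table(table_type = NA_character_,
                           has_descriptives = FALSE)
  expect_length(tag_table(empty)$tags, 0)
})

test_that("article tags union tables and apply metric tags per article", {
  t1 <- annotated_table(
    structure = context_structure("DATA_ELEMENT", "ARM",
                                  sublayout = "de_rows_arm_cols"),
    table_type = "baseline", format_location = "in_header",
    unit_location = "in_header", format_ids = "mean_pm_sd")
  t2 <- annotated_table(
    structure = context_structure("DATA_ELEMENT", c("ARM", "TIME_POINT"),
                                  sublayout = "de_rows_tp_in_arm_cols"),
    table_type = "outcome",
    format_location = "in_description_or_footnotes",
    format_ids = c("n_pct", "median_iqr"))
  ta <- tag_article(list(t1, t2))
  # declarations in the header of one table and footnote of another: both
  expect_true(all(c("format_location/in_header",
                    "format_location/in_description_or_footnotes",
                    "baseline_in_table", "outcomes_in_table",
                    "continuous_metrics/mean_pm_sd",
                    "continuous_metrics/median_iqr",
                    "dichotomous_metrics/n_pct",
                    "units_location/in_header") %in% ta$tags))
  expect_identical(validate_tags(ta), character(0))
  # no categorical data elements: no category-label classification
  expect_false(any(startsWith(ta$tags, "category_labels")))

  # not_relevant only wins when no table has unit-relevant elements
  t3 <- annotated_table(structure = t1$structure, table_type = "baseline",
                        unit_location = "not_relevant")
  expect_true("units_location/not_relevant" %in% tag_article(list(t3))$tags)
  expect_false("units_location/not_relevant" %in%
                 tag_article(list(t1, t3))$tags)
})

test_that("Boolean queries respect precedence, parentheses, and hierarchy", {
  corpus <- list(
    tagged_article("a1", c("outcomes_in_table",
                           "continuous_metrics",
                           "continuous_metrics/mean_pm_sd")),
    tagged_article("a2", c("outcomes_in_table", "baseline_in_table")),
    tagged_article("a3", c("baseline_in_table",
                           "baseline_in_table/arm_level_breakout")))
  expect_equal(boolean_query("outcomes_in_table AND mean_pm_sd", corpus),
               "a1")
  # parent tag matches when any descendant is present
  expect_equal(boolean_query("baseline_in_table", corpus), c("a2", "a3"))
  expect_equal(boolean_query("NOT outcomes_in_table", corpus), "a3")
  expect_equal(
    boolean_query("baseline_in_table AND NOT outcomes_in_table OR mean_pm_sd",
                  corpus), c("a1", "a3"))
  expect_equal(boolean_query("NOT x", list()), character(0))
  expect_error(boolean_query("a AND", corpus), "syntax error")
  expect_error(boolean_query("(a OR b", corpus), "expected \\)")
  expect_error(boolean_query("a ! b", corpus), "position")
})

test_that("random queries agree with a truth-table oracle", {
  set.seed(314)
  vars <- c("tag_a", "tag_b", "tag_c", "tag_d")
  rand_expr <- function(depth = 0) {
    if (depth > 2 || runif(1) < 0.35) return(sample(vars, 1))
    op <- sample(c("AND", "OR", "NOT"), 1)
    if (op == "NOT") paste0("NOT (", rand_expr(depth + 1), ")")
    else paste0("(", rand_expr(depth + 1), " ", op, " ",
                rand_expr(depth + 1), ")")
  }
  eval_oracle <- function(expr, tags) {
    # brute force: rewrite into an R logical expression and evaluate
    e <- expr
    for (v in vars)
      e <- gsub(paste0("\\b", v, "\\b"),
                if (v %in% tags) "TRUE" else "FALSE", e)
    e <- gsub("\\bAND\\b", "&&", e)
    e <- gsub("\\bOR\\b", "||", e)
    e <- gsub("\\bNOT\\b", "!", e)
    eval(parse(text = e))
  }
  for (i in 1:120) {
    expr <- rand_expr()
    tags <- sample(vars, sample(0:4, 1))
    corpus <- list(tagged_article("x", tags))
    got <- length(boolean_query(expr, corpus)) == 1
    expect_identical(got, eval_oracle(expr, tags), info = expr)
  }
})

test_that("frequency tables count by rule and attach score intervals", {
  corpus <- c(
    lapply(1:66, function(i)
      tagged_article(paste0("b", i), c("baseline_in_table",
                                       "outcomes_in_table"))),
    lapply(1:12, function(i) tagged_article(paste0("o", i), character())))
  f <- frequency_table(corpus, "baseline_in_table", "per_article")
  expect_equal(f$k, 66)
  expect_equal(f$n, 78)
  expect_equal(round(f$proportion, 2), 0.85)
  expect_equal(round(f$ci_lower, 2), 0.75)
  expect_equal(round(f$ci_upper, 2), 0.91)

  f1 <- frequency_table(list(tagged_article("s", "baseline_in_table")),
                        "baseline_in_table", "per_article")
  expect_equal(f1$proportion, 1)

  # per-relevant-article: denominator restricted to parent holders
  corpus2 <- list(
    tagged_article("r1", c("arm_size_reported",
                           "arm_size_reported/embedded_in_arm")),
    tagged_article("r2", c("arm_size_reported",
                           "arm_size_reported/separate_array")),
    tagged_article("r3", "baseline_in_table"))
  f2 <- frequency_table(corpus2, "arm_size_reported/embedded_in_arm",
                        "per_relevant_article")
  expect_equal(f2$k, 1)
  expect_equal(f2$n, 2)
  expect_warning(
    frequency_table(list(tagged_article("e", character())),
                    "arm_size_reported/embedded_in_arm",
                    "per_relevant_article"),
    "empty denominator")
})

test_that("per-table counts come from table-level assignments", {
  a <- article_record(
    "m1",
    tables = list(tag_assignment(c("baseline_in_table", "context_1x1"),
                                 "per_table"),
                  tag_assignment(c("outcomes_in_table", "context_1x1"),
                                 "per_table")),
    article_tags = tag_assignment(c("baseline_in_table", "outcomes_in_table",
                                    "context_1x1"), "per_article"))
  f <- frequency_table(list(a), c("context_1x1", "baseline_in_table"),
                       "per_table")
  expect_equal(f$n, c(2, 2))
  expect_equal(f$k, c(2, 1))
  # per-article numerators never exceed per-table numerators here
  fa <- frequency_table(list(a), "context_1x1", "per_article")
  expect_lte(fa$k, f$k[1])
})

test_that("the density classifier requires all five reporting properties", {
  full <- c("baseline_in_table", "arm_size_reported",
            "arm_size_reported/embedded_in_arm",
            "intervention_labels", "intervention_labels/full_name",
            "units_location", "units_location/in_header",
            "format_location", "format_location/in_header")
  expect_true(density_classifier(tag_assignment(full, "per_article")))
  no_size <- setdiff(full, c("arm_size_reported",
                             "arm_size_reported/embedded_in_arm"))
  expect_false(density_classifier(tag_assignment(no_size, "per_article")))
  # alternate labels fail the clause unless the clause is dropped
  alt <- c(setdiff(full, c("intervention_labels/full_name")),
           "intervention_labels/alternate")
  expect_false(density_classifier(tag_assignment(alt, "per_article")))
  expect_true(density_classifier(tag_assignment(alt, "per_article"),
                                 require_intervention_labels = FALSE))
  # articles without unit-relevant elements satisfy the unit clause
  nr <- c(setdiff(full, "units_location/in_header"),
          "units_location/not_relevant")
  expect_true(density_classifier(tag_assignment(nr, "per_article")))
})
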