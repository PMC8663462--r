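lex <- default_lexicons()

test_that("arm sizes are detected in every printed convention", {
  expect_equal(detect_arm_size("Placebo [n=25]"),
               list(label = "Placebo", size = 25L))
  expect_equal(detect_arm_size("HFNC (n=40)"),
               list(label = "HFNC", size = 40L))
  expect_equal(detect_arm_size("Usual care, n = 31"),
               list(label = "Usual care", size = 31L))
  expect_equal(detect_arm_size("Arm A ( N=12 )")$size, 12L)
  expect_equal(detect_arm_size("Control"),
               list(label = "Control", size = NULL))
})

test_that("a label without a size expression is never altered (idempotence)", {
  labels <- c("Control", "High flow nasal cannula", "Group A", "BMI, kg/m2")
  for (lb in labels) {
    d <- detect_arm_size(lb)
    expect_null(d$size)
    expect_identical(d$label, lb)
    # compose with re-rendering: detect(render(detect(x))) is stable
    d2 <- detect_arm_size(sprintf("%s (n=10)", d$label))
    expect_identical(d2$label, lb)
    expect_equal(d2$size, 10L)
  }
})

test_that("intervention labels classify into the four label kinds", {
  expect_equal(classify_intervention_label("Control"), "control_experimental")
  expect_equal(classify_intervention_label("Treatment"),
               "control_experimental")
  expect_equal(classify_intervention_label("HFNC"), "abbreviation")
  expect_equal(classify_intervention_label("Group A"), "alternate")
  expect_equal(classify_intervention_label("Placebo"), "full_name")
  expect_equal(classify_intervention_label("High flow nasal cannula"),
               "full_name")
  # size expressions are removed before classification
  expect_equal(classify_intervention_label("Placebo [n=25]"), "full_name")
})

test_that("time point labels classify with amount and unit extraction", {
  r <- classify_timepoint_label("6-month follow-up")
  expect_equal(r, list(label_kind = "unit_of_time", amount = 6,
                       unit = "month"))
  expect_equal(classify_timepoint_label("24 weeks")$unit, "week")
  r <- classify_timepoint_label("t_2")
  expect_equal(r$label_kind, "incremental")
  expect_equal(r$amount, 2)
  expect_equal(classify_timepoint_label("Visit 3")$label_kind, "incremental")
  expect_equal(classify_timepoint_label("Baseline")$label_kind, "pre_post")
  expect_equal(classify_timepoint_label("Follow-up")$label_kind, "pre_post")
  expect_null(classify_timepoint_label("Age"))
  expect_null(classify_timepoint_label("Serum creatinine, mmol/l"))
})

test_that("category structure detection groups, splits, and defaults", {
  r <- detect_category_structure(c("Smoking", "  Yes", "  No"))
  expect_length(r, 1)
  expect_equal(r[[1]]$name, "Smoking")
  expect_equal(r[[1]]$categories, c("Yes", "No"))
  expect_equal(r[[1]]$placement, "same_array_indented")

  r <- detect_category_structure("Gender M/F")
  expect_equal(r[[1]]$name, "Gender")
  expect_equal(r[[1]]$categories, c("M", "F"))
  expect_equal(r[[1]]$placement, "in_cell")

  r <- detect_category_structure(c("Age", "BMI"))
  expect_length(r, 2)
  expect_true(all(vapply(r, function(e) is.null(e$placement), TRUE)))

  # a unit suffix with a slash is not an in-cell category list
  r <- detect_category_structure("BMI, kg/m2")
  expect_null(r[[1]]$placement)

  r <- detect_category_structure(c("Severity", "", ""),
                                 secondary = c("Mild", "Moderate", "Severe"))
  expect_equal(r[[1]]$placement, "separate_array")
  expect_equal(r[[1]]$categories, c("Mild", "Moderate", "Severe"))
})

test_that("context kinds are recovered from rows and columns of real shapes", {
  a <- assign_context_kinds(fixture_baseline_grid(), lex)
  expect_equal(a$row_kinds, "DATA_ELEMENT")
  expect_equal(a$col_kinds, "ARM")
  expect_false(a$embedded)

  a <- assign_context_kinds(fixture_nested_col_grid(), lex)
  expect_equal(a$row_kinds, "DATA_ELEMENT")
  expect_equal(a$col_kinds, c("ARM", "TIME_POINT"))

  # embedded: one header cell carrying two context kinds
  m <- rbind(c("", "Placebo", "Aspirin"),
             c("Baseline BMI", "27.1 ± 3.2", "26.8 ± 3.0"),
             c("Follow-up BMI", "26.5 ± 3.1", "25.9 ± 2.9"))
  a <- assign_context_kinds(trialtables:::grid_from_matrix(m, 1, 1), lex)
  expect_true(a$embedded)
  expect_equal(a$row_kinds, c("DATA_ELEMENT", "TIME_POINT"))

  g <- fixture_baseline_grid()
  g$n_header_rows <- 0L
  g$n_header_cols <- 0L
  expect_error(assign_context_kinds(g, lex), "headerless")
})

test_that("statistic-name header levels label statistics, not context", {
  m <- rbind(c("", "Control", "Control", "Treatment", "Treatment"),
             c("", "Mean", "SD", "Mean", "SD"),
             c("Age", "54.2", "8.1", "55.0", "7.9"),
             c("BMI", "27.1", "3.2", "26.8", "3.0"))
  a <- assign_context_kinds(trialtables:::grid_from_matrix(m, 2, 1), lex)
  expect_equal(a$col_kinds, "ARM")
  expect_equal(a$row_kinds, "DATA_ELEMENT")
})

test_that("a repeating label cycle on one axis is recognized as nesting", {
  m <- rbind(c("", "Baseline", "Follow-up"),
             c("Pain score", "", ""),
             c("  Placebo", "4.1 ± 1.0", "3.0 ± 1.1"),
             c("  Aspirin", "4.0 ± 0.9", "2.1 ± 0.8"),
             c("Fatigue score", "", ""),
             c("  Placebo", "5.5 ± 1.2", "5.0 ± 1.0"),
             c("  Aspirin", "5.4 ± 1.3", "4.2 ± 1.1"))
  a <- assign_context_kinds(trialtables:::grid_from_matrix(m, 1, 1), lex)
  expect_equal(a$row_kinds, c("DATA_ELEMENT", "ARM"))
  expect_equal(a$col_kinds, "TIME_POINT")

  # same nesting without indentation: exact repeating cycle of period >= 2
  m2 <- m
  m2[, 1] <- c("", "Pain score", "Placebo", "Aspirin", "Fatigue score",
               "Placebo", "Aspirin")
  a2 <- assign_context_kinds(trialtables:::grid_from_matrix(m2, 1, 1), lex)
  expect_equal(a2$row_kinds, c("DATA_ELEMENT", "ARM"))
})

test_that("the 15 named layouts map one-to-one onto classes and back", {
  lay <- layout_table()
  named <- lay[lay$group != "other", ]
  expect_equal(nrow(named), 15)
  seen <- character()
  for (i in seq_len(nrow(named))) {
    a <- fixture_assignment(named$row_kinds[[i]], named$col_kinds[[i]],
                            embedded = named$embedded[i])
    s <- classify_structure(a)
    expect_equal(s$cls, switch(named$group[i], "1x1" = "ONE_BY_ONE",
                               "2x1" = "TWO_BY_ONE", "1x2" = "ONE_BY_TWO"),
                 info = named$id[i])
    expect_equal(s$sublayout, named$id[i])
    seen <- c(seen, s$sublayout)
  }
  expect_equal(sort(seen), sort(named$id))  # bijection: all 15, no repeats
})

test_that("stratified and comparative-only tables classify as OTHER", {
  a <- fixture_assignment("DATA_ELEMENT", "ARM")
  s <- classify_structure(a, only_comparative = TRUE)
  expect_equal(s$cls, "OTHER")
  expect_equal(s$other_reason, "comparative_only")

  s <- classify_structure(a, stratified = TRUE)
  expect_equal(s$other_reason, "stratified")

  deep <- fixture_assignment(c("DATA_ELEMENT", "ARM", "TIME_POINT"), "ARM")
  s <- classify_structure(deep)
  expect_equal(s$other_reason, "unsupported_depth")

  # subgroup header level triggers stratified detection on its own
  m <- rbind(c("", "Male", "Male", "Female", "Female"),
             c("", "Control", "Treatment", "Control", "Treatment"),
             c("Age", "54.2 ± 8.1", "55.0 ± 7.9", "52.9 ± 7.2", "53.8 ± 8.0"))
  a <- assign_context_kinds(trialtables:::grid_from_matrix(m, 2, 1), lex)
  expect_true(a$stratified)
  expect_equal(classify_structure(a)$other_reason, "stratified")
})

test_that("arm sizes are recovered from all three reporting placements", {
  g <- fixture_baseline_grid()
  a <- assign_context_kinds(g, lex)
  r <- recover_arm_sizes(g, a)
  expect_equal(r$placement, "embedded_in_arm")
  expect_equal(r$sizes, c(Placebo = 25L, Aspirin = 30L))

  m <- rbind(c("", "Placebo", "Aspirin"),
             c("No. of participants", "25", "30"),
             c("Age, years", "54.2 ± 8.1", "55.0 ± 7.9"))
  g2 <- trialtables:::grid_from_matrix(m, 1, 1)
  r2 <- recover_arm_sizes(g2, assign_context_kinds(g2, lex))
  expect_equal(r2$placement, "separate_array")
  expect_equal(r2$sizes, c(Placebo = 25L, Aspirin = 30L))

  m3 <- rbind(c("", "Placebo", "Aspirin"),
              c("Age, years", "54.2 ± 8.1", "55.0 ± 7.9"))
  g3 <- trialtables:::grid_from_matrix(
    m3, 1, 1, caption = "Arm sizes: Placebo, n=25; Aspirin, n=30.")
  r3 <- recover_arm_sizes(g3, assign_context_kinds(g3, lex))
  expect_equal(r3$placement, "in_description")
  expect_equal(unname(r3$sizes), c(25L, 30L))
})
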