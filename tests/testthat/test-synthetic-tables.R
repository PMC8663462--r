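spec <- synthetic_spec()
lex <- default_lexicons()

test_that("spec distributions must sum to one", {
  expect_error(synthetic_spec(de_kind_dist = c(continuous = 0.5,
                                               dichotomous = 0.2,
                                               categorical = 0.2)),
               "summing to 1")
  expect_silent(synthetic_spec())
})

test_that("every layout renders and survives the full recovery round-trip", {
  set.seed(2024)
  lay <- layout_table()
  for (id in lay$id) {
    for (rep in 1:3) {
      g <- generate_table(spec, layout_id = id, lexicons = lex)
      expect_s3_class(g$grid, "table_grid")
      v <- verify_ground_truth(g, lex)
      expect_true(v$ok, info = paste(id, paste(v$failures, collapse = "; ")))
    }
  }
})

test_that("forced layout and format round-trip recovers the spec exactly", {
  set.seed(9)
  spec1 <- synthetic_spec(
    mean_format_dist = c(mean_pm_sd = 1),
    de_kind_dist = c(continuous = 1, dichotomous = 0, categorical = 0),
    p_median = 0)
  g <- generate_table(spec1, layout_id = "de_rows_arm_cols", lexicons = lex)
  s <- classify_structure(assign_context_kinds(g$grid, lex))
  expect_equal(s$sublayout, "de_rows_arm_cols")
  expect_true(all(vapply(g$truth$metrics, function(r)
    r$format_id == "mean_pm_sd", TRUE)))
  expect_true(verify_ground_truth(g, lex)$ok)
})

test_that("rendered dichotomous percentages are consistent by construction", {
  set.seed(10)
  spec2 <- synthetic_spec(
    dichotomous_format_dist = c(n_pct = 1),
    de_kind_dist = c(continuous = 0, dichotomous = 1, categorical = 0))
  g <- generate_table(spec2, layout_id = "de_rows_arm_cols", lexicons = lex)
  expect_gt(length(g$truth$metrics), 0)
  sizes <- stats::setNames(g$truth$arms$size, g$truth$arms$label)
  for (rec in g$truth$metrics) {
    d <- dichotomous_stats(rec$values[["N"]], sizes[[rec$arm]],
                           rec$values[["PCT"]])
    expect_true(check_consistency(d, 1))
  }
})

test_that("generation is deterministic under a fixed seed", {
  c1 <- generate_corpus(spec, 6, seed = 123)
  c2 <- generate_corpus(spec, 6, seed = 123)
  expect_identical(c1, c2)
  c3 <- generate_corpus(spec, 6, seed = 124)
  expect_false(identical(c1, c3))
})

test_that("article composition and tags line up with the sampled properties", {
  corpus <- generate_corpus(spec, 60, seed = 31)
  expect_length(corpus, 60)
  for (a in corpus) {
    expect_s3_class(a, "article_record")
    expect_identical(validate_tags(a$article_tags), character(0))
  }
  n_tables <- sum(vapply(corpus, function(a) length(a$tables), 0L))
  # about 2.2 tables per article at the default composition
  expect_gt(n_tables / 60, 1.4)
  expect_lt(n_tables / 60, 3.2)
})

test_that("noise controls blank cells without touching headers", {
  set.seed(77)
  noisy <- synthetic_spec(noise = list(missing_cell_prob = 0.5,
                                       unicode_variant_prob = 0,
                                       rounding_decimals = 1L))
  g <- generate_table(noisy, layout_id = "de_rows_arm_cols", lexicons = lex)
  m <- grid_matrix(g$grid)
  expect_true(any(m[-1, -1] == ""))           # some metrics dropped
  expect_true(all(nzchar(m[1, -1])))          # headers intact
  a <- assign_context_kinds(g$grid, lex)      # context still classifiable
  expect_equal(a$col_kinds, "ARM")
})

test_that("the analytic density rate matches its clause-by-clause product", {
  p <- expected_density_rate(spec)
  comp <- spec$article_composition
  manual <- (1 - (1 - comp$p_baseline) * (1 - comp$p_outcomes)) *
    spec$p_arm_size_reported *
    (spec$intervention_label_dist[["acronym_abbreviation"]] +
       spec$intervention_label_dist[["full_name"]]) *
    ((1 - spec$p_units_relevant) +
       spec$p_units_relevant * (1 - spec$units_location_dist[["missing"]])) *
    spec$p_format_declared
  expect_equal(p, manual)
  expect_gt(expected_density_rate(spec, require_intervention_labels = FALSE),
            p)
})
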