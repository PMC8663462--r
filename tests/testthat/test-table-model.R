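test_that("span expansion replicates spanned text into every covered position", {
  cells <- list(tt_cell("", 0, 0),
                tt_cell("Arm A", 0, 1, col_span = 2),
                tt_cell("x", 1, 0), tt_cell("1", 1, 1), tt_cell("2", 1, 2))
  g <- table_grid(cells, 2, 3, n_header_rows = 1, n_header_cols = 1)
  m <- grid_matrix(g)
  expect_equal(m[1, 2], "Arm A")
  expect_equal(m[1, 3], "Arm A")
})

test_that("expanding a grid with no spans is the identity on the matrix view", {
  g <- fixture_baseline_grid()
  expect_identical(grid_matrix(g), grid_matrix(expand_spans(g)))
})

test_that("span coverage marks every position exactly once (enumeration oracle)", {
  cells <- list(tt_cell("a", 0, 0, row_span = 2), tt_cell("b", 0, 1),
                tt_cell("c", 0, 2), tt_cell("d", 1, 1), tt_cell("e", 1, 2),
                tt_cell("f", 2, 0), tt_cell("g", 2, 1), tt_cell("h", 2, 2))
  g <- table_grid(cells, 3, 3, n_header_rows = 1, n_header_cols = 1)
  # independent oracle: enumerate covered positions cell by cell
  cover <- matrix(0L, 3, 3)
  for (cl in cells) {
    for (r in cl$row + seq_len(cl$row_span) - 1L)
      for (co in cl$col + seq_len(cl$col_span) - 1L)
        cover[r + 1, co + 1] <- cover[r + 1, co + 1] + 1L
  }
  expect_true(all(cover == 1L))
  m <- grid_matrix(g)
  expect_equal(m[2, 1], "a")  # row_span carries text down
  ge <- expand_spans(g)
  expect_identical(grid_matrix(ge), grid_matrix(expand_spans(ge)))
})

test_that("overlapping spans raise a structural error naming coordinates", {
  cells <- list(tt_cell("a", 0, 0, col_span = 2), tt_cell("b", 0, 1))
  g <- table_grid(cells, 2, 2, n_header_rows = 1, n_header_cols = 1)
  expect_error(expand_spans(g), "overlapping spans at cell \\(0,1\\)")
})

test_that("indentation is derived deterministically from leading whitespace", {
  expect_equal(tt_cell("Age", 0, 0)$indent_level, 0L)
  expect_equal(tt_cell("  Yes", 0, 0)$indent_level, 1L)
  expect_equal(tt_cell("\tYes", 0, 0)$indent_level, 1L)
  expect_equal(tt_cell("    deep", 0, 0)$indent_level, 2L)
  expect_equal(tt_cell("  No", 0, 0)$indent_level, 1L)
})

test_that("grid-JSON round-trip is the identity on all fields", {
  g <- fixture_nested_col_grid()
  g$footnotes <- c("Values are mean ± SD.")
  path <- withr::local_tempfile(fileext = ".json")
  write_grid_json(g, path)
  g2 <- read_grid_json(path)
  expect_identical(grid_matrix(g), grid_matrix(g2))
  expect_identical(g$caption, g2$caption)
  expect_identical(g$footnotes, g2$footnotes)
  expect_identical(g$flags, g2$flags)
  expect_identical(g$n_header_rows, g2$n_header_rows)
  expect_identical(g$n_header_cols, g2$n_header_cols)
})

test_that("header prefix must leave at least one body row and column", {
  cells <- list(tt_cell("a", 0, 0), tt_cell("b", 0, 1),
                tt_cell("c", 1, 0), tt_cell("d", 1, 1))
  expect_error(table_grid(cells, 2, 2, n_header_rows = 2, n_header_cols = 1))
  expect_silent(table_grid(cells, 2, 2, n_header_rows = 1, n_header_cols = 1))
})

test_that("tag validation flags unknown tags and broken parent implication", {
  expect_identical(validate_tags(c("baseline_in_table",
                                   "baseline_in_table/arm_level_breakout")),
                   character(0))
  v <- validate_tags("baseline_in_table/arm_level_breakout")
  expect_length(v, 1)
  expect_match(v, "without its parent baseline_in_table")
  expect_match(validate_tags("made_up_tag"), "unknown tag: made_up_tag")
})

test_that("random tag sets validate exactly as a brute-force rule check", {
  h <- tag_hierarchy()
  set.seed(402)
  for (i in 1:40) {
    tags <- c(random_tag_set(h, sample(1:8, 1)),
              if (runif(1) < 0.3) "no_such_tag")
    got <- validate_tags(tags, h)
    # oracle: evaluate both rules independently per tag
    expected <- 0L
    for (tg in unique(sort(tags))) {
      i_h <- match(tg, h$id)
      if (is.na(i_h)) { expected <- expected + 1L; next }
      p <- h$parent[i_h]
      if (nzchar(p) && !(p %in% tags)) expected <- expected + 1L
    }
    expect_length(got, expected)
  }
})
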