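catalog <- format_catalog()

test_that("the catalog covers every printed format family", {
  kinds <- vapply(catalog, `[[`, "", "metric_kind")
  expect_equal(sum(kinds == "continuous_mean"), 7)
  expect_equal(sum(kinds == "continuous_median"), 7)
  # six dichotomous formats plus the n/N (%) extension
  expect_equal(sum(kinds == "dichotomous"), 7)
  expect_equal(sum(kinds == "categorical"), 2)
  expect_false(anyDuplicated(names(catalog)) > 0)
})

test_that("worked metric strings parse to their constituent statistics", {
  d <- parse_metric("2/59 (3.4%)", "n_slash_n_pct")
  expect_equal(d$n, 2L)
  expect_equal(d$n_total, 59L)
  expect_equal(d$pct, 3.4)

  c1 <- parse_metric("12.4 ± 2.3", "mean_pm_sd")
  expect_equal(c1$mean, 12.4)
  expect_equal(c1$sd, 2.3)

  c2 <- parse_metric("14 (10-18)", "median_range")
  expect_equal(c2$median, 14)
  expect_equal(c2$min, 10)
  expect_equal(c2$max, 18)

  cat_ <- parse_metric("11/9", "cat_n", categories = c("M", "F"),
                       label_placement = "in_cell")
  expect_equal(cat_$entries$category, c("M", "F"))
  expect_equal(cat_$entries$n, c(11L, 9L))
})

test_that("unicode variants of the separators parse identically", {
  for (s in c("12.4 ± 2.3", "12.4 +/- 2.3", "12.4±2.3")) {
    st <- parse_metric(s, "mean_pm_sd")
    expect_equal(st$mean, 12.4)
    expect_equal(st$sd, 2.3)
  }
  # en dash and minus sign in an interval
  st <- parse_metric("14 (10–18)", "median_iqr")
  expect_equal(st$p75, 18)
  st <- parse_metric("14 (10−18)", "median_iqr")
  expect_equal(st$p75, 18)
})

test_that("a mismatching metric fails with the furthest-match position", {
  err <- tryCatch(parse_metric("12.4 ± x", "mean_pm_sd"), error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "matched up to character 6")
  expect_error(parse_metric("  ", "mean_pm_sd"), "empty metric text")
  # partial match must never return a partial result
  expect_error(parse_metric("12.4 ± 2.3 extra", "mean_pm_sd"))
})

test_that("constituent order invariants are enforced", {
  expect_error(continuous_stats("median", median = 5, p25 = 6, p75 = 7),
               "p25")
  expect_error(continuous_stats("mean", min = 9, max = 3), "min")
  expect_error(dichotomous_stats(10, 5), "exceeds total")
  expect_error(dichotomous_stats(30, 40, 10), "rounding tolerance")
})

test_that("format declarations resolve case- and punctuation-insensitively", {
  expect_equal(parse_format_declaration("mean ± SD")$id, "mean_pm_sd")
  expect_equal(parse_format_declaration("Mean±SD")$id, "mean_pm_sd")
  expect_equal(parse_format_declaration("mean (SD)")$id, "mean_sd_paren")
  expect_equal(parse_format_declaration("Median (IQR)")$id,
               "median_iqr_unspecified")
  expect_equal(parse_format_declaration("n (%)")$id, "n_pct")
  expect_null(parse_format_declaration("flux capacitance"))
  # trailing declaration inside a longer header
  expect_equal(parse_format_declaration("Age, years, mean ± SD")$id,
               "mean_pm_sd")
})

test_that("format inference scores arrays and breaks ties by catalog order", {
  r <- infer_format(c("12.4 ± 2.3", "8.1 ± 1.9"))
  expect_equal(r$format$id, "mean_pm_sd")
  expect_equal(r$score, 1)

  r <- infer_format(c("30 (75)", "3 (8)"))
  expect_setequal(r$ties, c("n_pct", "mean_sd_paren"))
  expect_equal(r$format$id, "n_pct")  # catalog order: most frequent first

  # two numbers in parentheses exclude mean (SD)
  r <- infer_format("14 (10-18)")
  expect_equal(r$format$metric_kind, "continuous_median")
  expect_false("mean_sd_paren" %in% r$ties)

  # undeclared single numbers are uninferable
  expect_null(infer_format(c("12", "15"))$format)
  # ... unless the metric kind is declared
  expect_equal(infer_format(c("12", "15"), kind = "dichotomous")$format$id,
               "n_bare")
  expect_null(infer_format("not a number")$format)
})

test_that("render/parse round-trip recovers every format's tuple at printed precision", {
  set.seed(71)
  admissible <- function(fmt) {
    v <- c()
    c0 <- runif(1, 20, 80); s <- runif(1, 2, 12)
    n <- sample(0:40, 1); N <- n + sample(10:60, 1)
    vals <- c(MEAN = c0, SD = s, MEDIAN = c0, P25 = c0 - s, P75 = c0 + s,
              MIN = c0 - 2 * s, MAX = c0 + 2 * s, CI_LO = c0 - s,
              CI_HI = c0 + s, N = n, N_TOTAL = N, N_REST = N - n,
              PCT = round_half_up(100 * n / N, 1))
    vals[intersect(fmt$pattern, c("MEAN", "SD", "MEDIAN", "P25", "P75",
                                  "MIN", "MAX", "CI_LO", "CI_HI", "N",
                                  "N_TOTAL", "N_REST", "PCT"))]
  }
  for (fmt in catalog) {
    if (fmt$multi_array) next
    for (rep in 1:5) {
      vals <- admissible(fmt)
      txt <- render_metric(vals, fmt)
      mm <- trialtables:::match_format(txt, fmt)
      expect_true(mm$ok, info = paste(fmt$id, txt))
      printed <- ifelse(names(vals) %in% c("N", "N_TOTAL", "N_REST"),
                        vals, round_half_up(vals, 1))
      expect_equal(unname(mm$values[names(vals)]), unname(printed),
                   info = fmt$id)
    }
  }
})

test_that("percentage consistency follows half-up rounding at printed decimals", {
  expect_true(check_consistency(dichotomous_stats(2, 59, 3.4), 1))
  expect_true(check_consistency(dichotomous_stats(0, 10, 0.0), 1))
  d <- dichotomous_stats(30, 40, 75.0)
  expect_true(check_consistency(d, 1))
  d$pct <- 74.9  # bypass constructor: tests the checker itself
  expect_false(check_consistency(d, 1))
  expect_error(check_consistency(dichotomous_stats(3, 10), 1),
               "must all be present")
})

test_that("denominator derivation enumerates exactly the consistent totals", {
  expect_equal(derive_denominator(2, 3.4, 1, 1000), c(58L, 59L))
  expect_equal(derive_denominator(5, 50.0, 1, 100), 10L)
  # exact integer-arithmetic oracle for half-up rounding at one decimal:
  # round(1000*n/N) half-up == (2000n + N) %/% (2N)
  for (n in c(1, 3, 17)) {
    for (pct in c(0.5, 12.5, 33.3, 66.7)) {
      got <- derive_denominator(n, pct, 1, 1000)
      Ns <- max(n, 1):1000
      oracle <- Ns[(2000 * n + Ns) %/% (2 * Ns) == round(pct * 10)]
      expect_equal(got, oracle, info = paste(n, pct))
    }
  }
})

test_that("the derived set always contains the generating denominator", {
  set.seed(90)
  for (i in 1:200) {
    N <- sample(2:800, 1)
    n <- sample(0:N, 1)
    if (n == 0) next
    pct <- round_half_up(100 * n / N, 1)
    if (pct == 0) next
    expect_true(N %in% derive_denominator(n, pct, 1, 1000))
  }
})

test_that("inference on noise-free rendered arrays returns the source format or a textual twin", {
  set.seed(55)
  twins <- list(median_iqr = c("median_range", "median_iqr_unspecified"),
                median_range = c("median_iqr", "median_iqr_unspecified"),
                median_iqr_unspecified = c("median_iqr", "median_range"),
                mean_ci = c("median_iqr", "median_range",
                            "median_iqr_unspecified"),
                n_pct = c("mean_sd_paren", "cat_n_pct"),
                cat_n_pct = c("n_pct", "mean_sd_paren"),
                mean_sd_paren = c("n_pct", "cat_n_pct"))
  for (fmt in catalog) {
    if (fmt$multi_array ||
        length(intersect(fmt$pattern, trialtables:::PLACEHOLDERS)) < 2)
      next
    cells <- vapply(1:4, function(i) {
      c0 <- runif(1, 30, 70); s <- runif(1, 2, 9)
      n <- sample(1:30, 1); N <- n + sample(20:50, 1)
      vals <- c(MEAN = c0, SD = s, MEDIAN = c0, P25 = c0 - s, P75 = c0 + s,
                MIN = c0 - 2 * s, MAX = c0 + 2 * s, CI_LO = c0 - s,
                CI_HI = c0 + s, N = n, N_TOTAL = N, N_REST = N - n,
                PCT = round_half_up(100 * n / N, 1))
      render_metric(vals[intersect(fmt$pattern, trialtables:::PLACEHOLDERS)],
                    fmt)
    }, "")
    r <- infer_format(cells)
    ok_ids <- c(fmt$id, twins[[fmt$id]])
    expect_true(r$format$id %in% ok_ids,
                info = paste(fmt$id, "->", r$format$id))
  }
})
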