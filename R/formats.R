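# ---- statistic format objects ----------------------------------------------
#
# A statistic format is an ordered token pattern over numeric placeholders and
# literal delimiters. Placeholders:
#   MEAN SD MEDIAN P25 P75 MIN MAX CI_LO CI_HI   (decimal numbers)
#   N N_TOTAL N_REST                             (non-negative integers)
#   PCT                                          (decimal in [0,100])
# A literal token ending in "?" is optional (the "%" sign after a percentage).
# N_REST is the complement count in the "n/(N-n)" convention; the total is
# reconstructed as n + n_rest.

PLACEHOLDERS <- c("MEAN", "SD", "MEDIAN", "P25", "P75", "MIN", "MAX",
                  "N", "N_TOTAL", "N_REST", "PCT", "CI_LO", "CI_HI")
INT_PLACEHOLDERS <- c("N", "N_TOTAL", "N_REST")

#' Define a statistic format
#'
#' @param id unique identifier, e.g. `"mean_pm_sd"`.
#' @param name the format as printed in tables, e.g. `"Mean ± SD"`.
#' @param metric_kind one of `"continuous_mean"`, `"continuous_median"`,
#'   `"dichotomous"`, `"categorical"`.
#' @param pattern character vector of tokens: placeholder names and literal
#'   delimiters, in print order.
#' @param multi_array `TRUE` when the format spreads constituents over two
#'   parallel arrays (e.g. mean and SD in separate columns); the per-cell
#'   pattern then covers the primary array only.
#' @param companion placeholder carried by the companion array of a
#'   multi-array format.
#' @param aliases canonical-key aliases recognized by
#'   [parse_format_declaration()] in addition to `name`.
#' @param count observed frequency (articles) used to order the catalog.
#' @return a `statistic_format` object.
#' @export
statistic_format <- function(id, name, metric_kind, pattern,
                             multi_array = FALSE, companion = NULL,
                             aliases = character(), count = 0L) {
  metric_kind <- match.arg(metric_kind, c("continuous_mean",
                                          "continuous_median",
                                          "dichotomous", "categorical"))
  stopifnot(length(pattern) >= 1)
  ph <- pattern[pattern %in% PLACEHOLDERS]
  if (anyDuplicated(ph)) stop("duplicate placeholder in pattern", call. = FALSE)
  if (!length(ph)) stop("pattern has no placeholder", call. = FALSE)
  structure(list(id = id, name = name, metric_kind = metric_kind,
                 pattern = pattern, multi_array = isTRUE(multi_array),
                 companion = companion, aliases = aliases,
                 count = as.integer(count)),
            class = "statistic_format")
}

#' @export
print.statistic_format <- function(x, ...) {
  cat(sprintf("<statistic_format> %s [%s]: %s\n", x$id, x$metric_kind,
              paste(x$pattern, collapse = " ")))
  invisible(x)
}

#' The catalog of descriptive-statistic formats
#'
#' All 14 continuous formats (7 for means, 7 for medians), the 6 dichotomous
#' and 2 categorical formats observed in the reporting-practice survey, plus
#' the `n/N (%)` extension format in which the subset, total, and percentage
#' are all printed. The catalog is ordered by observed frequency (most common
#' first); that order is the deterministic tie-break when inference cannot
#' distinguish textually identical patterns.
#'
#' @return list of [statistic_format()] objects, most frequent first.
#' @export
format_catalog <- function() {
  f <- statistic_format
  cat <- list(
    f("mean_pm_sd", "Mean ± SD", "continuous_mean",
      c("MEAN", "±", "SD"), aliases = c("mean±sd", "mean(±sd)"), count = 41),
    f("cat_n_pct", "n (%)", "categorical",
      c("N", "(", "PCT", "%?", ")"), count = 40),
    f("n_pct", "n (%)", "dichotomous",
      c("N", "(", "PCT", "%?", ")"), aliases = c("n(%)", "no.(%)", "n(percent)"),
      count = 30),
    f("mean_sd_paren", "Mean (SD)", "continuous_mean",
      c("MEAN", "(", "SD", ")"), aliases = "mean(sd)", count = 25),
    f("median_iqr", "Median (IQR; 25th percentile-75th percentile)",
      "continuous_median", c("MEDIAN", "(", "P25", "-", "P75", ")"),
      aliases = c("median(iqr;25thpercentile-75thpercentile)",
                  "median(25thpercentile-75thpercentile)",
                  "median(p25-p75)", "median(q1-q3)"), count = 11),
    f("cat_n", "n", "categorical", "N", count = 8),
    f("median_range", "Median (range, min-max)", "continuous_median",
      c("MEDIAN", "(", "MIN", "-", "MAX", ")"),
      aliases = c("median(range,min-max)", "median(range)", "median(min-max)"),
      count = 4),
    f("median_iqr_bracket", "Median [IQR; 25th percentile-75th percentile]",
      "continuous_median", c("MEDIAN", "[", "P25", "-", "P75", "]"),
      aliases = c("median[iqr;25thpercentile-75thpercentile]", "median[iqr]"),
      count = 3),
    f("n_bare", "n", "dichotomous", "N", aliases = c("n", "no."), count = 3),
    f("n_over_rest", "n/(N-n)", "dichotomous", c("N", "/", "N_REST"),
      aliases = "n/(n-n)", count = 3),
    f("pct_bare", "%", "dichotomous", c("PCT", "%?"),
      aliases = c("%", "percent"), count = 3),
    f("mean_sd_separate", "Mean and SD in separate arrays", "continuous_mean",
      "MEAN", multi_array = TRUE, companion = "SD",
      aliases = "meanandsdinseparatearrays", count = 2),
    f("mean_bare", "Mean", "continuous_mean", "MEAN", aliases = "mean",
      count = 2),
    f("n_comma_pct", "n, %", "dichotomous", c("N", ",", "PCT", "%?"),
      aliases = "n,%", count = 2),
    f("median_iqr_bracket_comma",
      "Median [IQR; 25th percentile, 75th percentile]", "continuous_median",
      c("MEDIAN", "[", "P25", ",", "P75", "]"),
      aliases = "median[iqr;25thpercentile,75thpercentile]", count = 1),
    f("median_iqr_to", "Median (IQR; 25th percentile to 75th percentile)",
      "continuous_median", c("MEDIAN", "(", "P25", "to", "P75", ")"),
      aliases = "median(iqr;25thpercentileto75thpercentile)", count = 1),
    f("median_iqr_unspecified", "Median (IQR)", "continuous_median",
      c("MEDIAN", "(", "P25", "-", "P75", ")"),
      aliases = "median(iqr)", count = 1),
    f("min_max_median", "Min-Max (median)", "continuous_median",
      c("MIN", "-", "MAX", "(", "MEDIAN", ")"),
      aliases = "min-max(median)", count = 1),
    f("mean_sd_space", "Mean SD", "continuous_mean", c("MEAN", "SD"),
      aliases = "meansd", count = 1),
    f("mean_ci", "Mean (CI; lower-higher)", "continuous_mean",
      c("MEAN", "(", "CI_LO", "-", "CI_HI", ")"),
      aliases = c("mean(ci;lower-higher)", "mean(ci)", "mean(95%ci)"),
      count = 1),
    f("mean_pm_sd_range", "Mean ± SD (range; min-max)", "continuous_mean",
      c("MEAN", "±", "SD", "(", "MIN", "-", "MAX", ")"),
      aliases = c("mean±sd(range;min-max)", "mean±sd(range)"), count = 1),
    f("n_pct_separate", "n and % in separate arrays", "dichotomous",
      "N", multi_array = TRUE, companion = "PCT",
      aliases = "nand%inseparatearrays", count = 1),
    f("n_slash_n_pct", "n/N (%)", "dichotomous",
      c("N", "/", "N_TOTAL", "(", "PCT", "%?", ")"),
      aliases = c("n/n(%)", "n/n,%"), count = 0)
  )
  names(cat) <- vapply(cat, `[[`, "", "id")
  cat
}

#' Look up one catalog format by id
#'
#' @param id format identifier.
#' @param catalog a format catalog; defaults to [format_catalog()].
#' @return a [statistic_format()].
#' @export
get_format <- function(id, catalog = format_catalog()) {
  fmt <- catalog[[id]]
  if (is.null(fmt)) stop("unknown format id: ", id, call. = FALSE)
  fmt
}
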