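`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero at a fixed number of decimals
#'
#' Unlike [base::round()] (banker's rounding), ties are rounded up, which is
#' how percentages in clinical tables are conventionally printed (e.g.
#' 100 * 2/59 = 3.389... prints as 3.4, and 0.25 at one decimal prints 0.3).
#'
#' @param x numeric vector.
#' @param digits non-negative integer, decimals to keep.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(2.5, 0)   # 3, not 2
#' round_half_up(100 * 2/59, 1)  # 3.4
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), digits >= 0)
  p <- 10^digits
  # small epsilon guards against 0.0499999... artefacts of binary floats
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Normalize unicode variants in a metric string
#'
#' Maps the printed variants of plus-minus (`+/-`, `+-`), minus (U+2212),
#' en/em dashes, and non-breaking spaces onto canonical ASCII-adjacent forms
#' so that one grammar matches all print conventions.
#'
#' @param x character vector.
#' @return character vector with canonical separators.
#' @export
normalize_metric_text <- function(x) {
  x <- gsub(" ", " ", x, fixed = TRUE)
  x <- gsub("+/-", "±", x, fixed = TRUE)
  x <- gsub("(?<![0-9.])\\+-", "±", x, perl = TRUE)
  x <- gsub("[−–—]", "-", x)
  x <- gsub("[ \t]+", " ", x)
  x
}

# leading-whitespace depth: one tab, two spaces, or one NBSP pair = one level
indent_of <- function(text) {
  lead <- sub("^([\t  ]*).*$", "\\1", text)
  if (!nzchar(lead)) return(0L)
  chars <- strsplit(lead, "")[[1]]
  units <- sum(ifelse(chars == "\t", 2L, 1L))
  as.integer(units %/% 2L)
}

strip_ws <- function(x) gsub("^[\t  ]+|[\t  ]+$", "", x)

is_blank <- function(x) !nzchar(strip_ws(x))
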