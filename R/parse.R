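# ---- constituent-statistic containers --------------------------------------

#' Constituent statistics of a continuous metric
#'
#' @param central_kind `"mean"` or `"median"`.
#' @param mean,sd,median,p25,p75,min,max,ci_lo,ci_hi optional numbers; order
#'   constraints (p25 <= median <= p75, min <= max, ci_lo <= ci_hi) are
#'   enforced when the relevant constituents are present.
#' @return a `continuous_stats` object.
#' @export
continuous_stats <- function(central_kind, mean = NULL, sd = NULL,
                             median = NULL, p25 = NULL, p75 = NULL,
                             min = NULL, max = NULL, ci_lo = NULL,
                             ci_hi = NULL) {
  central_kind <- match.arg(central_kind, c("mean", "median"))
  chk <- function(a, b, la, lb) {
    if (!is.null(a) && !is.null(b) && a > b + 1e-9)
      stop(sprintf("%s (%g) exceeds %s (%g)", la, a, lb, b), call. = FALSE)
  }
  chk(p25, median, "p25", "median"); chk(median, p75, "median", "p75")
  chk(p25, p75, "p25", "p75"); chk(min, max, "min", "max")
  chk(ci_lo, ci_hi, "ci_lo", "ci_hi")
  structure(list(central_kind = central_kind, mean = mean, sd = sd,
                 median = median, p25 = p25, p75 = p75, min = min, max = max,
                 ci_lo = ci_lo, ci_hi = ci_hi),
            class = c("continuous_stats", "parsed_stats"))
}

#' Constituent statistics of a dichotomous metric
#'
#' @param n subset count (non-negative integer); `NA` when the format prints
#'   only a percentage.
#' @param n_total total population (positive integer), when reported.
#' @param pct percentage in \[0, 100\], when reported. When `n`, `n_total`,
#'   and `pct` are all present, `pct` must lie within half an integer
#'   percentage point of `100 * n / n_total` (printed rounding tolerance).
#' @return a `dichotomous_stats` object.
#' @export
dichotomous_stats <- function(n = NA, n_total = NULL, pct = NULL) {
  if (!is.na(n)) stopifnot(n >= 0, n == floor(n))
  if (!is.null(n_total)) {
    stopifnot(n_total >= 1, n_total == floor(n_total))
    if (!is.na(n) && n > n_total)
      stop(sprintf("subset n (%d) exceeds total N (%d)", n, n_total),
           call. = FALSE)
  }
  if (!is.null(pct)) {
    if (pct < 0 || pct > 100)
      stop("pct must lie in [0, 100], got ", pct, call. = FALSE)
    if (!is.na(n) && !is.null(n_total) &&
        abs(pct - 100 * n / n_total) > 0.5 + 1e-9)
      stop(sprintf("pct %g is not within rounding tolerance of 100*%d/%d",
                   pct, n, n_total), call. = FALSE)
  }
  structure(list(n = as.integer(n),
                 n_total = if (!is.null(n_total)) as.integer(n_total),
                 pct = pct),
            class = c("dichotomous_stats", "parsed_stats"))
}

#' Constituent statistics of a categorical metric
#'
#' @param entries data.frame with columns `category`, `n`, and optionally
#'   `pct`; category labels must be distinct.
#' @param label_placement how category labels are reported: one of
#'   `"separate_array"`, `"same_array"`, `"same_array_indented"`, `"in_cell"`.
#' @return a `categorical_stats` object.
#' @export
categorical_stats <- function(entries,
                              label_placement = c("same_array_indented",
                                                  "separate_array",
                                                  "same_array", "in_cell")) {
  label_placement <- match.arg(label_placement)
  stopifnot(is.data.frame(entries), nrow(entries) >= 1,
            all(c("category", "n") %in% names(entries)))
  if (anyDuplicated(entries$category))
    stop("category labels must be distinct", call. = FALSE)
  structure(list(entries = entries, label_placement = label_placement),
            class = c("categorical_stats", "parsed_stats"))
}

# ---- pattern matching -------------------------------------------------------

NUM_RE <- "[+-]?(?:\\d+\\.\\d+|\\d+|\\.\\d+)"
INT_RE <- "\\d+"

# compile the first `k` tokens of a pattern into an anchored-prefix regex;
# returns list(re, placeholders in capture order)
compile_pattern <- function(pattern, k = length(pattern)) {
  parts <- character()
  ph <- character()
  prev_ph <- FALSE
  for (tok in pattern[seq_len(k)]) {
    if (tok %in% PLACEHOLDERS) {
      re <- if (tok %in% INT_PLACEHOLDERS) INT_RE else NUM_RE
      gap <- if (prev_ph) "[ \t]+" else "[ \t]*"
      parts <- c(parts, paste0(gap, "(", re, ")"))
      ph <- c(ph, tok)
      prev_ph <- TRUE
    } else {
      optional <- endsWith(tok, "?")
      lit <- if (optional) substr(tok, 1, nchar(tok) - 1L) else tok
      lit_re <- gsub("([][{}()*+?.\\^$|-])", "\\\\\\1", lit)
      if (grepl("^[a-zA-Z]", lit)) lit_re <- paste0("\\b", lit_re)
      if (grepl("[a-zA-Z]$", lit)) lit_re <- paste0(lit_re, "\\b")
      piece <- paste0("[ \t]*", lit_re)
      if (optional) piece <- paste0("(?:", piece, ")?")
      parts <- c(parts, piece)
      prev_ph <- FALSE
    }
  }
  list(re = paste0("^[ \t]*", paste(parts, collapse = "")), ph = ph)
}

# attempt to bind a cell's text to a format pattern.
# returns list(ok, values = named numeric, fail_pos = furthest matched char)
match_format <- function(text, fmt) {
  text <- normalize_metric_text(text)
  cp <- compile_pattern(fmt$pattern)
  m <- regmatches(text, regexec(paste0(cp$re, "[ \t]*$"), text, perl = TRUE))[[1]]
  if (length(m)) {
    vals <- as.numeric(m[-1])
    names(vals) <- cp$ph
    if ("PCT" %in% cp$ph && (vals[["PCT"]] < 0 || vals[["PCT"]] > 100))
      return(list(ok = FALSE, fail_pos = nchar(text)))
    return(list(ok = TRUE, values = vals))
  }
  # locate the furthest point reached by any pattern prefix
  fail_pos <- 0L
  for (k in seq_along(fmt$pattern)) {
    pm <- regmatches(text, regexpr(compile_pattern(fmt$pattern, k)$re, text,
                                   perl = TRUE))
    if (!length(pm) || is.na(pm[1])) break
    fail_pos <- nchar(pm[1])
  }
  list(ok = FALSE, fail_pos = fail_pos)
}

# ---- parsing ----------------------------------------------------------------

#' Parse a metric string against a statistic format
#'
#' Binds every placeholder of the format's pattern to a number parsed from
#' the text, in order, and returns the constituent statistics. Unicode
#' variants of the separators are normalized first. Any unmatched text is an
#' error carrying the furthest-match position, never a partial result.
#'
#' @param text the metric string, e.g. `"2/59 (3.4%)"`.
#' @param fmt a [statistic_format()] or a format id.
#' @param categories category labels, required to interpret in-cell
#'   categorical metrics such as `"11/9"` for `"Gender M/F"`.
#' @param label_placement category-label placement recorded on categorical
#'   results.
#' @param catalog format catalog used to resolve `fmt` by id.
#' @return a [continuous_stats()], [dichotomous_stats()], or
#'   [categorical_stats()] object, with the format id in attribute
#'   `"format_id"`.
#' @export
#' @examples
#' parse_metric("2/59 (3.4%)", "n_slash_n_pct")
#' parse_metric("12.4 ± 2.3", "mean_pm_sd")
#' parse_metric("11/9", "cat_n", categories = c("M", "F"),
#'               label_placement = "in_cell")
parse_metric <- function(text, fmt, categories = NULL,
                         label_placement = "same_array_indented",
                         catalog = format_catalog()) {
  if (is.character(fmt)) fmt <- get_format(fmt, catalog)
  if (is_blank(text)) stop("empty metric text", call. = FALSE)

  if (fmt$metric_kind == "categorical" && !is.null(categories) &&
      length(categories) > 1) {
    # in-cell reporting: one number (or number pair) per category, "/"-joined
    parts <- strsplit(normalize_metric_text(strip_ws(text)), "/")[[1]]
    if (length(parts) != length(categories))
      stop(sprintf("in-cell metric \"%s\" has %d parts for %d categories",
                   text, length(parts), length(categories)), call. = FALSE)
    ns <- numeric(length(parts)); pcts <- rep(NA_real_, length(parts))
    for (i in seq_along(parts)) {
      mm <- match_format(parts[i], fmt)
      if (!mm$ok)
        stop(sprintf("cannot parse in-cell part \"%s\" as %s", parts[i],
                     fmt$id), call. = FALSE)
      ns[i] <- mm$values[["N"]]
      if ("PCT" %in% names(mm$values)) pcts[i] <- mm$values[["PCT"]]
    }
    entries <- data.frame(category = categories, n = as.integer(ns),
                          pct = pcts, stringsAsFactors = FALSE)
    out <- categorical_stats(entries, "in_cell")
    attr(out, "format_id") <- fmt$id
    return(out)
  }

  mm <- match_format(text, fmt)
  if (!mm$ok)
    stop(sprintf("metric \"%s\" does not match format %s (matched up to character %d)",
                 text, fmt$id, mm$fail_pos), call. = FALSE)
  v <- as.list(mm$values)
  out <- switch(
    fmt$metric_kind,
    continuous_mean = continuous_stats(
      "mean", mean = v$MEAN, sd = v$SD, min = v$MIN, max = v$MAX,
      ci_lo = v$CI_LO, ci_hi = v$CI_HI),
    continuous_median = continuous_stats(
      "median", median = v$MEDIAN, p25 = v$P25, p75 = v$P75,
      min = v$MIN, max = v$MAX),
    dichotomous = dichotomous_stats(
      n = v$N %||% NA_integer_,
      n_total = v$N_TOTAL %||% (if (!is.null(v$N_REST)) v$N + v$N_REST),
      pct = v$PCT),
    categorical = {
      entries <- data.frame(category = categories %||% NA_character_,
                            n = as.integer(v$N),
                            pct = v$PCT %||% NA_real_,
                            stringsAsFactors = FALSE)
      categorical_stats(entries, label_placement)
    })
  attr(out, "format_id") <- fmt$id
  out
}

#' Render constituent statistics in a statistic format
#'
#' The inverse of [parse_metric()]: prints the numeric constituents with the
#' format's delimiters at a fixed number of decimals (integers for counts).
#' Rendering then re-parsing recovers the values at printed precision.
#'
#' @param values named list/vector of placeholder values (`MEAN`, `SD`, `N`,
#'   `PCT`, ...).
#' @param fmt a [statistic_format()] or format id.
#' @param decimals printed decimals for non-integer constituents.
#' @param catalog catalog used to resolve `fmt` by id.
#' @return the rendered metric string.
#' @export
#' @examples
#' render_metric(c(MEAN = 12.38, SD = 2.31), "mean_pm_sd")  # "12.4 ± 2.3"
render_metric <- function(values, fmt, decimals = 1, catalog = format_catalog()) {
  if (is.character(fmt)) fmt <- get_format(fmt, catalog)
  values <- as.list(values)
  fmt_num <- function(tok) {
    x <- values[[tok]]
    if (is.null(x) || is.na(x)) stop("missing value for ", tok, call. = FALSE)
    if (tok %in% INT_PLACEHOLDERS) sprintf("%d", as.integer(x))
    else formatC(round_half_up(x, decimals), format = "f", digits = decimals)
  }
  out <- ""
  prev_ph <- FALSE
  for (tok in fmt$pattern) {
    if (tok %in% PLACEHOLDERS) {
      piece <- fmt_num(tok)
      sep <- if (prev_ph) " " else ""
      out <- paste0(out, sep, piece)
      prev_ph <- TRUE
    } else {
      lit <- sub("\\?$", "", tok)
      piece <- switch(lit,
                      "±" = " ± ", "(" = " (", ")" = ")", "[" = " [", "]" = "]",
                      "," = ", ", "to" = " to ", "/" = "/", "-" = "-",
                      "%" = "%", lit)
      out <- paste0(out, piece)
      prev_ph <- FALSE
    }
  }
  strip_ws(out)
}

# ---- format declarations and inference --------------------------------------

canonical_key <- function(x) {
  x <- normalize_metric_text(tolower(x))
  x <- gsub("standard deviation", "sd", x, fixed = TRUE)
  x <- gsub("interquartile range", "iqr", x, fixed = TRUE)
  gsub("[ \t.]", "", x)
}

#' Resolve a declared statistic format from header/footnote text
#'
#' Matches the text (case-insensitively, tolerant of punctuation and unicode
#' variants) against the canonical names and aliases of the catalog formats;
#' `"mean (SD)"`, `"Mean±SD"`, and `"n (%)"` all resolve. Declarations are
#' also recognized as a trailing `", <format>"` segment of a longer header.
#'
#' @param text header, caption, or footnote text.
#' @param catalog format catalog.
#' @return the matching [statistic_format()], or `NULL` (invisibly, class
#'   `"undeclared"` attribute-free) when no catalog format matches.
#' @export
parse_format_declaration <- function(text, catalog = format_catalog()) {
  keys <- lapply(catalog, function(f) unique(c(canonical_key(f$name), f$aliases)))
  # "n (%)" is printed for both dichotomous and categorical metrics; a bare
  # declaration resolves to the dichotomous reading unless context says more
  ordering <- order(vapply(catalog, function(f)
    f$metric_kind == "categorical", TRUE))
  try_key <- function(k) {
    if (!nzchar(k)) return(NULL)
    for (f in catalog[ordering]) if (k %in% keys[[f$id]]) return(f)
    NULL
  }
  hit <- try_key(canonical_key(text))
  if (!is.null(hit)) return(hit)
  # trailing ", mean ± SD" style declaration inside a longer header
  parts <- strsplit(text, ",")[[1]]
  if (length(parts) > 1) {
    hit <- try_key(canonical_key(parts[length(parts)]))
    if (!is.null(hit)) return(hit)
  }
  invisible(NULL)
}

#' Infer the statistic format of an array of metric strings
#'
#' Scores every catalog format by the fraction of non-empty cells its pattern
#' matches and returns the best, with deterministic tie-breaking by catalog
#' order (most common format first). Multi-array formats are not inferable
#' from a single array and categorical formats are textually identical to
#' their dichotomous counterparts, so both are excluded unless `kind` says
#' otherwise; bare single-number cells are only attributed to a
#' single-placeholder format when `kind` is declared, otherwise they are
#' uninferable.
#'
#' @param cells character vector of metric strings (the array).
#' @param kind optional declared metric kind, one of the catalog's
#'   `metric_kind` values; restricts the candidate formats.
#' @param catalog format catalog.
#' @return list with `format` (a [statistic_format()] or `NULL` when
#'   uninferable), `score` (fraction of cells matched), and `ties` (ids of
#'   formats with the same score).
#' @export
infer_format <- function(cells, kind = NULL, catalog = format_catalog()) {
  cells <- cells[!vapply(cells, is_blank, TRUE)]
  if (!length(cells)) stop("no non-empty cells to infer from", call. = FALSE)
  candidates <- Filter(function(f) {
    if (f$multi_array) return(FALSE)
    if (!is.null(kind)) return(f$metric_kind == kind)
    if (f$metric_kind == "categorical") return(FALSE)
    length(intersect(f$pattern, PLACEHOLDERS)) >= 2
  }, catalog)
  if (!length(candidates))
    return(list(format = NULL, score = 0, ties = character()))
  scores <- vapply(candidates, function(f)
    mean(vapply(cells, function(tx) match_format(tx, f)$ok, TRUE)), 0)
  best <- max(scores)
  if (best == 0) return(list(format = NULL, score = 0, ties = character()))
  tied <- names(candidates)[scores == best]
  list(format = candidates[[tied[1]]], score = best, ties = tied)
}

# ---- consistency and denominator derivation ---------------------------------

#' Check n/N/% consistency of a dichotomous metric
#'
#' @param d a [dichotomous_stats()] with `n`, `n_total`, and `pct` present.
#' @param decimals decimals at which the percentage was printed.
#' @return `TRUE` iff `pct` equals `100 * n / n_total` rounded half-up at
#'   `decimals`.
#' @export
#' @examples
#' check_consistency(dichotomous_stats(2, 59, 3.4), decimals = 1)  # TRUE
check_consistency <- function(d, decimals = 1) {
  stopifnot(inherits(d, "dichotomous_stats"))
  if (is.null(d$n_total) || is.null(d$pct))
    stop("n, n_total, and pct must all be present", call. = FALSE)
  abs(round_half_up(100 * d$n / d$n_total, decimals) - d$pct) < 1e-7
}

#' Derive candidate denominators from a count and a printed percentage
#'
#' Enumerates every total `N` in `[max(n, 1), n_max]` for which
#' `100 * n / N`, rounded half-up at `decimals`, reproduces the printed
#' percentage — the arithmetic route to recovering arm sizes that were not
#' reported directly.
#'
#' @param n subset count.
#' @param pct printed percentage, in `(0, 100]`.
#' @param decimals decimals at which `pct` was printed.
#' @param n_max largest denominator to consider.
#' @return integer vector of candidate denominators (possibly empty).
#' @export
#' @examples
#' derive_denominator(2, 3.4, decimals = 1, n_max = 1000)  # 58 59
derive_denominator <- function(n, pct, decimals = 1, n_max = 1000) {
  stopifnot(n >= 0, pct > 0, pct <= 100, n_max >= 1)
  Ns <- seq.int(max(n, 1L), n_max)
  Ns[abs(round_half_up(100 * n / Ns, decimals) - pct) < 1e-7]
}
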