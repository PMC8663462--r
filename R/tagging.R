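# ---- Wilson score interval --------------------------------------------------

#' Wilson score confidence interval for a binomial proportion
#'
#' The score interval without continuity correction — the normal
#' approximation that `prop.test(..., correct = FALSE)` inverts:
#' center `(p + z^2/2n) / (1 + z^2/n)`, half-width
#' `z / (1 + z^2/n) * sqrt(p(1-p)/n + z^2/4n^2)`. At `p = 0` the lower
#' endpoint is exactly 0; at `p = 1` the upper endpoint is exactly 1.
#'
#' @param k number of successes, `0 <= k <= n`.
#' @param n number of trials, `n >= 1`.
#' @param conf confidence level in (0, 1).
#' @return a `proportion_ci` object with `k`, `n`, `conf`, `z`, `p_hat`,
#'   `lower`, `upper`.
#' @export
#' @examples
#' wilson_ci(66, 78)  # 0.750 - 0.910
wilson_ci <- function(k, n, conf = 0.95) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  stopifnot(k >= 0, k <= n, conf > 0, conf < 1)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z / denom * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  structure(list(k = as.integer(k), n = as.integer(n), conf = conf, z = z,
                 p_hat = p,
                 lower = if (k == 0) 0 else max(0, center - half),
                 upper = if (k == n) 1 else min(1, center + half)),
            class = "proportion_ci")
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(sprintf("%d/%d = %.3f, %d%% CI %.3f-%.3f (Wilson score)\n",
              x$k, x$n, x$p_hat, round(100 * x$conf), x$lower, x$upper))
  invisible(x)
}

# ---- annotated tables and articles ------------------------------------------

#' Construct an annotated table record
#'
#' The unit that [tag_table()] consumes: a classified table together with
#' everything the detectors (or a synthetic generator's ground truth)
#' establish about it.
#'
#' @param grid optional [table_grid()].
#' @param structure a [context_structure()], or `NULL` for untagged tables.
#' @param table_type `"baseline"`, `"outcome"`, or `NA` when the table
#'   reports no patient descriptive statistics.
#' @param arm_breakout `"arm_level"`, `"participant_level"`, or `"none"`.
#' @param secondary_only outcome table covering secondary outcomes only.
#' @param arm_sizes named integer vector of per-arm sizes, or `NULL`.
#' @param arm_size_placement `"embedded_in_arm"`, `"separate_array"`,
#'   `"in_description"`, or `NULL` when sizes are not reported.
#' @param intervention_kinds intervention label kinds present
#'   (`"control_experimental"`, `"abbreviation"`, `"full_name"`,
#'   `"alternate"`).
#' @param timepoint_kinds time-point label kinds present (`"unit_of_time"`,
#'   `"pre_post"`, `"incremental"`).
#' @param format_location where the statistic format is declared in this
#'   table: `"in_header"`, `"in_description_or_footnotes"`, or `NULL`; when
#'   both occur the description/footnote classification wins.
#' @param unit_location where units of continuous data elements appear:
#'   `"in_header"`, `"in_description_or_footnotes"`, `"not_relevant"`, or
#'   `NULL` (units missing).
#' @param format_ids catalog ids of the statistic formats observed.
#' @param category_placements category-label placements observed.
#' @param metrics optional list of parsed metrics.
#' @param has_descriptives `FALSE` for tables with no descriptive statistics
#'   (such tables are not tagged).
#' @return an `annotated_table`.
#' @export
annotated_table <- function(grid = NULL, structure = NULL,
                            table_type = NA_character_,
                            arm_breakout = "arm_level",
                            secondary_only = FALSE, arm_sizes = NULL,
                            arm_size_placement = NULL,
                            intervention_kinds = character(),
                            timepoint_kinds = character(),
                            format_location = NULL, unit_location = NULL,
                            format_ids = character(),
                            category_placements = character(),
                            metrics = list(), has_descriptives = TRUE) {
  structure(list(grid = grid, structure = structure, table_type = table_type,
                 arm_breakout = arm_breakout,
                 secondary_only = isTRUE(secondary_only),
                 arm_sizes = arm_sizes,
                 arm_size_placement = arm_size_placement,
                 intervention_kinds = intervention_kinds,
                 timepoint_kinds = timepoint_kinds,
                 format_location = format_location,
                 unit_location = unit_location,
                 format_ids = format_ids,
                 category_placements = category_placements,
                 metrics = metrics,
                 has_descriptives = isTRUE(has_descriptives)),
            class = "annotated_table")
}

#' Construct an article record
#'
#' @param article_id identifier string.
#' @param tables list of [annotated_table()] records.
#' @param article_tags a per-article [tag_assignment()]; computed with
#'   [tag_article()] when `NULL`.
#' @return an `article_record`.
#' @export
article_record <- function(article_id, tables = list(), article_tags = NULL) {
  rec <- structure(list(article_id = article_id, tables = tables,
                        article_tags = NULL),
                   class = "article_record")
  rec$article_tags <- article_tags %||% tag_article(rec)
  stopifnot(rec$article_tags$scope == "per_article")
  rec
}

# close a tag set under parent implication
add_parents <- function(tags, hierarchy = tag_hierarchy()) {
  out <- unique(tags)
  repeat {
    parents <- hierarchy$parent[match(out, hierarchy$id)]
    parents <- parents[!is.na(parents) & nzchar(parents)]
    new <- setdiff(parents, out)
    if (!length(new)) break
    out <- c(out, new)
  }
  sort(out)
}

intervention_kind_tag <- function(kind) {
  switch(kind,
         abbreviation = "intervention_labels/acronym_abbreviation",
         acronym_abbreviation = "intervention_labels/acronym_abbreviation",
         paste0("intervention_labels/", kind))
}

# ---- tagging ----------------------------------------------------------------

#' Tag one table
#'
#' Emits the per-table structure tags (baseline/outcome with breakout
#' level), feature tags (rotated, multipage), and context tags (context
#' class with named sub-layout, embedded context, arm-size placement,
#' intervention and time-point label kinds). A table with no descriptive
#' statistics receives an empty assignment.
#'
#' @param t an [annotated_table()].
#' @param hierarchy tag vocabulary used to close the set under parents.
#' @return a per-table [tag_assignment()].
#' @export
tag_table <- function(t, hierarchy = tag_hierarchy()) {
  stopifnot(inherits(t, "annotated_table"))
  if (!t$has_descriptives || is.na(t$table_type))
    return(tag_assignment(character(), "per_table"))
  tags <- character()
  root <- if (t$table_type == "baseline") "baseline_in_table"
          else "outcomes_in_table"
  tags <- c(tags, root)
  if (t$table_type == "outcome" && t$secondary_only) {
    tags <- c(tags, "outcomes_in_table/secondary_only")
  } else if (t$arm_breakout == "arm_level") {
    tags <- c(tags, paste0(root, "/arm_level_breakout"))
  } else if (t$arm_breakout == "participant_level") {
    tags <- c(tags, paste0(root, "/participant_level"))
  } else if (t$table_type == "baseline") {
    tags <- c(tags, "baseline_in_table/no_arm_level_breakout")
  }
  if (!is.null(t$grid)) {
    if (t$grid$flags$rotated) tags <- c(tags, "table_features/rotated")
    if (t$grid$flags$multipage) tags <- c(tags, "table_features/multipage")
  }
  s <- t$structure
  if (!is.null(s)) {
    cls_tag <- switch(s$cls, ONE_BY_ONE = "context_1x1",
                      TWO_BY_ONE = "context_2x1", ONE_BY_TWO = "context_1x2",
                      OTHER = "other_structure")
    tags <- c(tags, cls_tag)
    if (s$cls == "OTHER" &&
        s$other_reason %in% c("stratified", "comparative_only")) {
      tags <- c(tags, paste0("other_structure/", s$other_reason))
    } else if (!is.null(s$sublayout) &&
               s$sublayout %in% layout_table()$id[layout_table()$group != "other"]) {
      tags <- c(tags, paste0(cls_tag, "/", s$sublayout))
    }
    if (s$embedded) tags <- c(tags, "context_embedded")
  }
  if (!is.null(t$arm_size_placement))
    tags <- c(tags, paste0("arm_size_reported/", t$arm_size_placement))
  tags <- c(tags, vapply(as.character(t$intervention_kinds),
                         intervention_kind_tag, ""))
  tags <- c(tags, paste0("timepoint_labels/",
                         as.character(t$timepoint_kinds), recycle0 = TRUE))
  tag_assignment(add_parents(tags, hierarchy), "per_table")
}

#' Per-table tags of any table representation
#'
#' @param t an [annotated_table()], a [tag_assignment()], or a character
#'   vector of tag ids.
#' @param hierarchy tag vocabulary.
#' @return a per-table [tag_assignment()].
#' @export
table_tags <- function(t, hierarchy = tag_hierarchy()) {
  if (inherits(t, "annotated_table")) tag_table(t, hierarchy)
  else if (inherits(t, "tag_assignment")) t
  else tag_assignment(as.character(t), "per_table")
}

#' Tag an article from its tagged tables
#'
#' Structural and context tags are the union over the article's tables.
#' Metric tags are applied per article: statistic-format location (within a
#' table the description/footnote classification outranks the header; the
#' article carries the union over tables), unit location (`not_relevant`
#' only when no table has unit-relevant continuous data elements), the
#' statistic formats observed per metric kind, and the category-label
#' placements observed (absent when no categorical data elements are
#' reported).
#'
#' @param a an [article_record()], or a list of [annotated_table()].
#' @param hierarchy tag vocabulary.
#' @return a per-article [tag_assignment()].
#' @export
tag_article <- function(a, hierarchy = tag_hierarchy()) {
  tables <- if (inherits(a, "article_record")) a$tables else a
  tags <- character()
  fmt_kinds <- vapply(format_catalog(), `[[`, "", "metric_kind")
  kind_parent <- c(continuous_mean = "continuous_metrics",
                   continuous_median = "continuous_metrics",
                   dichotomous = "dichotomous_metrics",
                   categorical = "categorical_metrics")
  unit_locs <- character()
  for (t in tables) {
    tt <- table_tags(t, hierarchy)
    tags <- c(tags, tt$tags)
    if (!inherits(t, "annotated_table")) next
    if (!t$has_descriptives || is.na(t$table_type)) next
    if (!is.null(t$format_location))
      tags <- c(tags, paste0("format_location/", t$format_location))
    if (!is.null(t$unit_location)) unit_locs <- c(unit_locs, t$unit_location)
    for (id in as.character(t$format_ids))
      tags <- c(tags, paste0(kind_parent[[fmt_kinds[[id]]]], "/", id))
    tags <- c(tags, paste0("category_labels/",
                           as.character(t$category_placements),
                           recycle0 = TRUE))
  }
  real_units <- setdiff(unit_locs, "not_relevant")
  if (length(real_units)) {
    tags <- c(tags, paste0("units_location/", unique(real_units)))
  } else if (length(unit_locs)) {
    tags <- c(tags, "units_location/not_relevant")
  }
  tag_assignment(add_parents(tags, hierarchy), "per_article")
}

# ---- Boolean tag queries ----------------------------------------------------

tokenize_query <- function(expr) {
  toks <- list()
  i <- 1L
  n <- nchar(expr)
  while (i <= n) {
    ch <- substr(expr, i, i)
    if (grepl("\\s", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- list(type = ch, pos = i)
      i <- i + 1L
      next
    }
    m <- regexpr("^[A-Za-z0-9_./-]+", substr(expr, i, n))
    if (m[1] == -1L)
      stop(sprintf("query syntax error at position %d: unexpected \"%s\"",
                   i, ch), call. = FALSE)
    word <- regmatches(substr(expr, i, n), m)
    up <- toupper(word)
    toks[[length(toks) + 1L]] <-
      if (up %in% c("AND", "OR", "NOT")) list(type = up, pos = i)
      else list(type = "IDENT", value = word, pos = i)
    i <- i + attr(m, "match.length")
  }
  toks
}

#' Run a Boolean query over a tagged corpus
#'
#' Expressions combine tag identifiers with `AND`, `OR`, `NOT`, and
#' parentheses (precedence `NOT > AND > OR`). An article matches a tag if
#' the tag or any of its descendants is present in the article's tag set.
#'
#' @param expr query string, e.g.
#'   `"outcomes_in_table AND mean_pm_sd"` — tag identifiers may be full
#'   paths or any path suffix resolvable in the hierarchy.
#' @param corpus list of [article_record()] objects.
#' @param hierarchy tag vocabulary for resolving bare tag names.
#' @return character vector of matching article ids, in corpus order.
#' @export
boolean_query <- function(expr, corpus, hierarchy = tag_hierarchy()) {
  toks <- tokenize_query(expr)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { tk <- toks[[pos]]; pos <<- pos + 1L; tk }
  expect <- function(type) {
    tk <- peek()
    if (is.null(tk) || tk$type != type)
      stop(sprintf("query syntax error at position %d: expected %s",
                   if (is.null(tk)) nchar(expr) + 1L else tk$pos, type),
           call. = FALSE)
    advance()
  }
  parse_primary <- function() {
    tk <- peek()
    if (is.null(tk))
      stop("query syntax error: unexpected end of expression", call. = FALSE)
    if (tk$type == "(") {
      advance()
      node <- parse_or()
      expect(")")
      return(node)
    }
    if (tk$type == "IDENT") {
      advance()
      return(list(op = "tag", id = tk$value))
    }
    if (tk$type == "NOT") {
      advance()
      return(list(op = "not", x = parse_primary()))
    }
    stop(sprintf("query syntax error at position %d", tk$pos), call. = FALSE)
  }
  parse_and <- function() {
    node <- parse_primary()
    while (!is.null(peek()) && peek()$type == "AND") {
      advance()
      node <- list(op = "and", x = node, y = parse_primary())
    }
    node
  }
  parse_or <- function() {
    node <- parse_and()
    while (!is.null(peek()) && peek()$type == "OR") {
      advance()
      node <- list(op = "or", x = node, y = parse_and())
    }
    node
  }
  ast <- parse_or()
  if (!is.null(peek()))
    stop(sprintf("query syntax error at position %d: trailing input",
                 peek()$pos), call. = FALSE)

  resolve_id <- function(id) {
    if (id %in% hierarchy$id) return(id)
    suffix <- hierarchy$id[endsWith(hierarchy$id, paste0("/", id))]
    if (length(suffix) == 1L) return(suffix)
    id  # unknown or ambiguous: matched literally against tag sets
  }
  eval_node <- function(node, tags) {
    switch(node$op,
           tag = holds_tag(tags, resolve_id(node$id)),
           not = !eval_node(node$x, tags),
           and = eval_node(node$x, tags) && eval_node(node$y, tags),
           or = eval_node(node$x, tags) || eval_node(node$y, tags))
  }
  ids <- vapply(corpus, `[[`, "", "article_id")
  hit <- vapply(corpus, function(a) eval_node(ast, a$article_tags$tags), TRUE)
  ids[hit]
}

# ---- frequency tables -------------------------------------------------------

#' Tag frequencies over a corpus, with Wilson score intervals
#'
#' @param corpus list of [article_record()] objects.
#' @param tags character vector of tag ids to summarize.
#' @param denominator_rule `"per_article"` (all articles), `"per_table"`
#'   (all tagged tables), or `"per_relevant_article"` (articles holding the
#'   tag's parent; for top-level tags, articles with at least one tagged
#'   table).
#' @param conf confidence level for the score intervals.
#' @param hierarchy tag vocabulary.
#' @return data.frame with columns `tag`, `k`, `n`, `proportion`,
#'   `ci_lower`, `ci_upper`, `rule`; rows with an empty denominator class
#'   are omitted with a warning.
#' @export
frequency_table <- function(corpus, tags,
                            denominator_rule = c("per_article", "per_table",
                                                 "per_relevant_article"),
                            conf = 0.95, hierarchy = tag_hierarchy()) {
  denominator_rule <- match.arg(denominator_rule)
  art_tags <- lapply(corpus, function(a) a$article_tags$tags)
  tbl_tags <- unlist(lapply(corpus, function(a)
    lapply(a$tables, function(t) table_tags(t, hierarchy)$tags)),
    recursive = FALSE) %||% list()
  tbl_tags <- Filter(length, tbl_tags)
  rows <- list()
  for (tag in tags) {
    if (denominator_rule == "per_table") {
      n <- length(tbl_tags)
      k <- sum(vapply(tbl_tags, holds_tag, TRUE, tag = tag))
    } else if (denominator_rule == "per_article") {
      n <- length(art_tags)
      k <- sum(vapply(art_tags, holds_tag, TRUE, tag = tag))
    } else {
      parent <- hierarchy$parent[match(tag, hierarchy$id)]
      rel <- if (!is.na(parent) && nzchar(parent)) {
        Filter(function(ts) holds_tag(ts, parent), art_tags)
      } else {
        Filter(length, art_tags)
      }
      n <- length(rel)
      k <- sum(vapply(rel, holds_tag, TRUE, tag = tag))
    }
    if (n == 0L) {
      warning("empty denominator class for tag ", tag, "; row omitted",
              call. = FALSE)
      next
    }
    ci <- wilson_ci(k, n, conf)
    rows[[length(rows) + 1L]] <- data.frame(
      tag = tag, k = k, n = n, proportion = k / n,
      ci_lower = ci$lower, ci_upper = ci$upper, rule = denominator_rule,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows) %||%
    data.frame(tag = character(), k = integer(), n = integer(),
               proportion = numeric(), ci_lower = numeric(),
               ci_upper = numeric(), rule = character())
}

#' Write a frequency report as CSV or JSON
#'
#' @param freq a data.frame from [frequency_table()].
#' @param path output file; format chosen by extension (`.csv` or `.json`).
#' @return `path` invisibly.
#' @export
write_frequency_report <- function(freq, path) {
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(freq, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.csv(freq, path, row.names = FALSE)
  }
  invisible(path)
}

# ---- high information density -----------------------------------------------

#' Classify an article as high information density
#'
#' True when the article holds all of: baseline or outcomes reported in
#' table; arm size reported; intervention labels given as full names or
#' acronyms/abbreviations; units of measurement reported for unit-relevant
#' metrics (articles without unit-relevant data elements satisfy this
#' vacuously); and statistic format reported. With
#' `require_intervention_labels = FALSE` the intervention-label clause is
#' dropped.
#'
#' @param a an [article_record()] or a per-article [tag_assignment()].
#' @param require_intervention_labels drop the label clause when `FALSE`.
#' @return logical.
#' @export
density_classifier <- function(a, require_intervention_labels = TRUE) {
  tags <- if (inherits(a, "article_record")) a$article_tags$tags
          else if (inherits(a, "tag_assignment")) a$tags
          else as.character(a)
  in_table <- holds_tag(tags, "baseline_in_table") ||
    holds_tag(tags, "outcomes_in_table")
  arm_size <- holds_tag(tags, "arm_size_reported")
  labels_ok <- !require_intervention_labels ||
    holds_tag(tags, "intervention_labels/full_name") ||
    holds_tag(tags, "intervention_labels/acronym_abbreviation")
  units_ok <- holds_tag(tags, "units_location")
  format_ok <- holds_tag(tags, "format_location")
  in_table && arm_size && labels_ok && units_ok && format_ok
}
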