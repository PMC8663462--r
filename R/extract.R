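# ---- full extraction pipeline ----------------------------------------------

# try a declaration on cleaned footnote/caption text
scan_format_declarations <- function(texts, catalog = format_catalog()) {
  hits <- list()
  for (tx in texts) {
    segs <- strsplit(tx, ";|\\band\\b|\\.", perl = TRUE)[[1]]
    for (sg in segs) {
      sg <- strip_ws(gsub(
        "(?i)\\b(data|values|results|variables?|continuous|dichotomous|categorical|are|presented|reported|as|is)\\b",
        " ", sg, perl = TRUE))
      if (!nzchar(sg)) next
      f <- parse_format_declaration(sg, catalog)
      if (!is.null(f)) hits[[length(hits) + 1L]] <- f
    }
  }
  hits
}

#' Extract structure, context, and parsed metrics from a table grid
#'
#' The end-to-end pipeline: expands spans, assigns context kinds to each
#' axis, classifies the layout, annotates headers (arm sizes and label
#' kinds, time-point kinds, units, category structure), resolves the
#' statistic format of every metric array — an explicit declaration
#' (footnote/description outranking header) beats array-level inference,
#' which beats catalog order — and parses every non-empty body cell.
#'
#' @param grid a [table_grid()].
#' @param lexicons detector lexicons.
#' @param catalog statistic-format catalog.
#' @return an `extraction_result`: list with `structure`
#'   (a [context_structure()]), `assignment`, `arm_sizes`, `arm_labels`,
#'   `header_annotations`, `metrics` (per parsed cell: `row`, `col`,
#'   `text`, `format_id`, `provenance` = `"declared"` or `"inferred"`,
#'   `stats`), and `warnings` (stable-code strings).
#' @export
extract_table <- function(grid, lexicons = default_lexicons(),
                          catalog = format_catalog()) {
  warnings <- character()
  a <- assign_context_kinds(grid, lexicons)
  s <- classify_structure(a)
  arm_rec <- recover_arm_sizes(grid, a)

  # header annotations per level
  ann <- list()
  for (axis in c("row", "col")) {
    for (lv in a$levels[[axis]]) {
      kind <- lv$verdict
      entries <- lapply(lv$labels, function(lab) {
        det <- detect_arm_size(lab)
        list(label = lab,
             arm_size = det$size,
             intervention_kind = if (grepl("ARM", kind))
               classify_intervention_label(lab, lexicons),
             timepoint = if (grepl("TIME_POINT", kind))
               classify_timepoint_label(lab, lexicons),
             unit = detect_unit(lab, lexicons))
      })
      ann[[length(ann) + 1L]] <- list(axis = axis, verdict = kind,
                                      cells = entries)
    }
  }

  # metric arrays run along the data-element axis when one exists
  m <- grid_matrix(grid)
  nhr <- grid$n_header_rows; nhc <- grid$n_header_cols
  body_r <- (nhr + 1L):nrow(m); body_c <- (nhc + 1L):ncol(m)
  de_on_rows <- "DATA_ELEMENT" %in% a$row_kinds ||
    (!length(a$row_kinds) && length(a$col_kinds))
  foot_decl <- scan_format_declarations(c(grid$footnotes, grid$caption),
                                        catalog)

  resolve_fmt <- function(label, cells) {
    # description/footnote declarations outrank header declarations
    if (length(foot_decl)) {
      for (f in foot_decl)
        if (all(vapply(cells, function(tx)
          is_blank(tx) || match_format(tx, f)$ok, TRUE)))
          return(list(fmt = f, provenance = "declared"))
    }
    decl <- parse_format_declaration(label, catalog)
    if (!is.null(decl)) return(list(fmt = decl, provenance = "declared"))
    inf <- infer_format(cells, catalog = catalog)
    if (!is.null(inf$format)) return(list(fmt = inf$format,
                                          provenance = "inferred"))
    list(fmt = NULL, provenance = NA_character_)
  }

  metrics <- list()
  arrays <- if (de_on_rows) body_r else body_c
  for (idx in arrays) {
    if (de_on_rows) {
      label <- m[idx, nhc]
      cells <- m[idx, body_c]
    } else {
      label <- m[nhr, idx]
      cells <- m[body_r, idx]
    }
    nonblank <- cells[!vapply(cells, is_blank, TRUE)]
    if (!length(nonblank)) next
    res <- resolve_fmt(label, nonblank)
    if (is.null(res$fmt)) {
      warnings <- c(warnings,
                    sprintf("W_UNINFERABLE_ARRAY: no format for array \"%s\"",
                            strip_ws(label)))
      next
    }
    for (j in seq_along(cells)) {
      if (is_blank(cells[j])) next
      pos <- if (de_on_rows) c(idx - 1L, nhc + j - 1L)
             else c(nhr + j - 1L, idx - 1L)
      st <- tryCatch(parse_metric(cells[j], res$fmt, catalog = catalog),
                     error = function(e) e)
      if (inherits(st, "error")) {
        warnings <- c(warnings,
                      sprintf("W_PARSE_FAIL: cell (%d,%d) \"%s\" as %s",
                              pos[1], pos[2], cells[j], res$fmt$id))
      } else {
        metrics[[length(metrics) + 1L]] <-
          list(row = pos[1], col = pos[2], text = cells[j],
               format_id = res$fmt$id, provenance = res$provenance,
               stats = st)
      }
    }
  }

  structure(list(structure = s, assignment = a,
                 arm_sizes = arm_rec$sizes,
                 arm_size_placement = arm_rec$placement,
                 header_annotations = ann, metrics = metrics,
                 warnings = warnings),
            class = "extraction_result")
}

#' @export
print.extraction_result <- function(x, ...) {
  print(x$structure)
  cat(sprintf("  %d parsed metric(s), %d warning(s)\n",
              length(x$metrics), length(x$warnings)))
  invisible(x)
}

#' Build an annotated table record from a raw grid
#'
#' Runs [extract_table()] and condenses the result into the
#' [annotated_table()] form that [tag_table()] consumes: the table type is
#' read from the caption vocabulary (baseline/demographic vs outcome), the
#' breakout level from the presence of an arm axis, and label kinds, sizes,
#' units, and format locations from the header annotations.
#'
#' @param grid a [table_grid()].
#' @param lexicons detector lexicons.
#' @param catalog statistic-format catalog.
#' @return an [annotated_table()].
#' @export
annotate_grid <- function(grid, lexicons = default_lexicons(),
                          catalog = format_catalog()) {
  ex <- extract_table(grid, lexicons, catalog)
  cap <- tolower(grid$caption)
  table_type <- if (grepl("baseline|demographic|characteristic", cap))
    "baseline"
  else if (grepl("outcome|result|efficacy|response", cap)) "outcome"
  else if (length(ex$metrics)) "baseline" else NA_character_
  has_arm <- "ARM" %in% c(ex$assignment$row_kinds, ex$assignment$col_kinds) ||
    isTRUE(ex$structure$other_reason == "stratified")
  arm_labels <- character()
  interv <- character()
  tps <- character()
  units <- character()
  for (lv in ex$header_annotations) {
    if (grepl("ARM", lv$verdict))
      interv <- c(interv, vapply(lv$cells, function(e)
        e$intervention_kind %||% NA_character_, ""))
    if (grepl("TIME_POINT", lv$verdict))
      tps <- c(tps, vapply(lv$cells, function(e)
        if (!is.null(e$timepoint)) e$timepoint$label_kind else NA_character_,
        ""))
    units <- c(units, unlist(lapply(lv$cells, `[[`, "unit")))
  }
  fmt_ids <- unique(vapply(ex$metrics, `[[`, "", "format_id"))
  declared <- any(vapply(ex$metrics, function(mm)
    identical(mm$provenance, "declared"), TRUE))
  fmt_kind <- vapply(catalog, `[[`, "", "metric_kind")
  has_cont <- any(fmt_kind[fmt_ids] %in% c("continuous_mean",
                                           "continuous_median"))
  annotated_table(
    grid = grid, structure = ex$structure, table_type = table_type,
    arm_breakout = if (has_arm) "arm_level" else "none",
    arm_sizes = ex$arm_sizes, arm_size_placement = ex$arm_size_placement,
    intervention_kinds = unique(stats::na.omit(interv)),
    timepoint_kinds = unique(stats::na.omit(tps)),
    format_location = if (declared) "in_header",
    unit_location = if (!has_cont) NULL
      else if (length(units)) "in_header" else NULL,
    format_ids = fmt_ids,
    metrics = ex$metrics,
    has_descriptives = length(ex$metrics) > 0 ||
      isTRUE(ex$structure$other_reason == "comparative_only"))
}
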