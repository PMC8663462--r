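#' The named sub-layouts of measurement-context reporting
#'
#' The 15 arrangements of context kinds over rows and columns observed in
#' comparative clinical tables, grouped into the 1x1 / 2x1 / 1x2 classes,
#' plus the two "other structure" modes (stratified reporting and tables of
#' comparative statistics only). The `count` column carries each layout's
#' observed per-table frequency (of 174 tables), which the synthetic
#' generator uses as its default layout distribution.
#'
#' @return data.frame with columns `id`, `name`, `group` (`"1x1"`, `"2x1"`,
#'   `"1x2"`, `"other"`), `row_kinds`, `col_kinds` (list columns of context
#'   kinds, outermost first), `embedded`, `count`.
#' @export
layout_table <- function() {
  DE <- "DATA_ELEMENT"; ARM <- "ARM"; TP <- "TIME_POINT"
  L <- function(id, name, group, rk, ck, emb, count)
    list(id = id, name = name, group = group, row_kinds = list(rk),
         col_kinds = list(ck), embedded = emb, count = count)
  rows <- list(
    L("de_rows_arm_cols", "DEs on rows, arms on columns", "1x1",
      DE, ARM, FALSE, 90),
    L("arm_rows_de_cols", "Arms on rows, DEs on columns", "1x1",
      ARM, DE, FALSE, 5),
    L("arm_rows_tp_cols", "Arm on rows, TP on columns", "1x1",
      ARM, TP, FALSE, 2),
    L("tp_rows_arm_cols", "TPs on rows, arms on columns", "1x1",
      TP, ARM, FALSE, 2),
    L("tp_in_de_rows_arm_cols",
      "TPs nested in DEs on rows, arms on columns", "2x1",
      c(DE, TP), ARM, FALSE, 18),
    L("arm_in_de_rows_tp_cols",
      "Arms nested in DEs on rows, TPs on columns", "2x1",
      c(DE, ARM), TP, FALSE, 8),
    L("de_in_arm_rows_tp_cols",
      "DEs nested in arms on rows, TPs on columns", "2x1",
      c(ARM, DE), TP, FALSE, 2),
    L("arm_in_tp_rows_de_cols",
      "Arms nested in TPs on rows, DEs on columns", "2x1",
      c(TP, ARM), DE, FALSE, 2),
    L("de_tp_embedded_rows_arm_cols",
      "DEs and TPs embedded in rows, arms on columns", "2x1",
      c(DE, TP), ARM, TRUE, 2),
    L("tp_in_arm_rows_de_cols",
      "TPs nested in arms on rows, DEs on columns", "2x1",
      c(ARM, TP), DE, FALSE, 1),
    L("de_in_tp_rows_arm_cols",
      "DEs nested in TPs on rows, arms on columns", "2x1",
      c(TP, DE), ARM, FALSE, 1),
    L("de_rows_tp_in_arm_cols",
      "DEs on rows, TPs nested in arms on columns", "1x2",
      DE, c(ARM, TP), FALSE, 16),
    L("de_rows_arm_in_tp_cols",
      "DEs on rows, arms nested in TPs on columns", "1x2",
      DE, c(TP, ARM), FALSE, 5),
    L("arm_rows_tp_in_de_cols",
      "Arms on rows, TPs nested in DEs on columns", "1x2",
      ARM, c(DE, TP), FALSE, 3),
    L("de_rows_arm_tp_embedded_cols",
      "DEs on rows, arms and TPs embedded on columns", "1x2",
      DE, c(ARM, TP), TRUE, 2),
    L("stratified", "Stratified reporting", "other",
      character(), character(), FALSE, 8),
    L("comparative_only", "Only reports comparative statistics", "other",
      character(), character(), FALSE, 7)
  )
  df <- data.frame(
    id = vapply(rows, `[[`, "", "id"),
    name = vapply(rows, `[[`, "", "name"),
    group = vapply(rows, `[[`, "", "group"),
    embedded = vapply(rows, `[[`, TRUE, "embedded"),
    count = vapply(rows, function(r) as.integer(r$count), 1L),
    stringsAsFactors = FALSE)
  df$row_kinds <- lapply(rows, function(r) r$row_kinds[[1]])
  df$col_kinds <- lapply(rows, function(r) r$col_kinds[[1]])
  df
}

#' Construct a measurement-context structure
#'
#' @param row_kinds,col_kinds ordered context kinds (outermost first) on each
#'   axis; members of `DATA_ELEMENT`, `ARM`, `TIME_POINT`.
#' @param embedded `TRUE` when two kinds are fused in single header cells.
#' @param cls context class; derived from the kind counts when `NULL`.
#' @param other_reason required iff `cls` is `"OTHER"`.
#' @param sublayout named sub-layout id, when one matches.
#' @return a `context_structure` object.
#' @export
context_structure <- function(row_kinds, col_kinds, embedded = FALSE,
                              cls = NULL, other_reason = NULL,
                              sublayout = NULL) {
  kinds <- c("DATA_ELEMENT", "ARM", "TIME_POINT")
  stopifnot(all(row_kinds %in% kinds), all(col_kinds %in% kinds))
  derived <- if (length(row_kinds) == 1 && length(col_kinds) == 1) "ONE_BY_ONE"
    else if (length(row_kinds) == 2 && length(col_kinds) == 1) "TWO_BY_ONE"
    else if (length(row_kinds) == 1 && length(col_kinds) == 2) "ONE_BY_TWO"
    else "OTHER"
  cls <- cls %||% derived
  if (cls != "OTHER" && cls != derived)
    stop(sprintf("cls %s inconsistent with %d row and %d column kinds",
                 cls, length(row_kinds), length(col_kinds)), call. = FALSE)
  if (xor(cls == "OTHER", !is.null(other_reason)))
    stop("other_reason must be set iff cls is OTHER", call. = FALSE)
  structure(list(row_kinds = row_kinds, col_kinds = col_kinds,
                 embedded = isTRUE(embedded), cls = cls,
                 other_reason = other_reason, sublayout = sublayout),
            class = "context_structure")
}

#' @export
print.context_structure <- function(x, ...) {
  cat(sprintf("<context_structure> %s%s\n", x$cls,
              if (!is.null(x$other_reason)) paste0(" (", x$other_reason, ")")
              else ""))
  if (!is.null(x$sublayout)) cat("  sub-layout:", x$sublayout, "\n")
  invisible(x)
}

#' Classify a context assignment into the layout taxonomy
#'
#' Maps the number of context kinds per axis onto the 1x1 / 2x1 / 1x2
#' classes; stratified or comparative-only tables (detected or flagged by
#' the caller) classify as OTHER with the reason recorded, as does an axis
#' carrying more than two kinds (`"unsupported_depth"`). When the
#' (row kinds, col kinds, embedded) triple matches one of the 15 named
#' sub-layouts, the sub-layout id is reported; otherwise the kinds are kept
#' verbatim.
#'
#' @param assignment a `context_assignment` from [assign_context_kinds()].
#' @param has_arm_level_data unused placeholder flag for callers that track
#'   breakout separately; kept for interface stability.
#' @param only_comparative,stratified caller-supplied overrides, OR-ed with
#'   the assignment's own detection.
#' @return a [context_structure()].
#' @export
classify_structure <- function(assignment, has_arm_level_data = NA,
                               only_comparative = FALSE, stratified = FALSE) {
  stopifnot(inherits(assignment, "context_assignment"))
  rk <- assignment$row_kinds
  ck <- assignment$col_kinds
  stratified <- stratified || isTRUE(assignment$stratified)
  only_comparative <- only_comparative || isTRUE(assignment$only_comparative)
  if (only_comparative)
    return(context_structure(rk[seq_len(min(1, length(rk)))],
                             character(), cls = "OTHER",
                             other_reason = "comparative_only",
                             sublayout = "comparative_only"))
  if (stratified)
    return(context_structure(rk, ck, embedded = assignment$embedded,
                             cls = "OTHER", other_reason = "stratified",
                             sublayout = "stratified"))
  if (length(rk) > 2 || length(ck) > 2 ||
      (length(rk) == 2 && length(ck) == 2) ||
      length(rk) == 0 || length(ck) == 0)
    return(context_structure(character(), character(), cls = "OTHER",
                             other_reason = "unsupported_depth"))
  lay <- layout_table()
  hit <- which(vapply(seq_len(nrow(lay)), function(i)
    identical(lay$row_kinds[[i]], rk) && identical(lay$col_kinds[[i]], ck) &&
      lay$embedded[i] == assignment$embedded, TRUE))
  context_structure(rk, ck, embedded = assignment$embedded,
                    sublayout = if (length(hit)) lay$id[hit[1]])
}
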