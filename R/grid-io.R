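#' Write a grid to the grid-JSON interchange format
#'
#' The interchange object carries `n_rows`, `n_cols`, `n_header_rows`,
#' `n_header_cols`, `caption`, `footnotes[]`, `flags{rotated,multipage}`, and
#' `cells[]` each with `{text,row,col,row_span,col_span}`. Text is preserved
#' exactly, including leading whitespace (which encodes category nesting).
#'
#' @param grid a [table_grid()].
#' @param path file path; when `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
write_grid_json <- function(grid, path = NULL) {
  stopifnot(inherits(grid, "table_grid"))
  cells <- lapply(grid$cells, function(cl)
    list(text = cl$text, row = cl$row, col = cl$col,
         row_span = cl$row_span, col_span = cl$col_span))
  obj <- list(n_rows = grid$n_rows, n_cols = grid$n_cols,
              n_header_rows = grid$n_header_rows,
              n_header_cols = grid$n_header_cols,
              caption = grid$caption,
              footnotes = as.list(grid$footnotes),
              flags = grid$flags,
              cells = cells)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read a grid from grid-JSON
#'
#' @param path file path or a JSON string.
#' @return a [table_grid()].
#' @export
read_grid_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  need <- c("n_rows", "n_cols", "cells")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("grid-JSON missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cells <- lapply(obj$cells, function(cl)
    tt_cell(cl$text, cl$row, cl$col, cl$row_span %||% 1L, cl$col_span %||% 1L))
  table_grid(cells, obj$n_rows, obj$n_cols,
             obj$n_header_rows %||% 1L, obj$n_header_cols %||% 1L,
             obj$caption %||% "",
             unlist(obj$footnotes) %||% character(),
             isTRUE(obj$flags$rotated), isTRUE(obj$flags$multipage))
}

#' Read a table file into a grid
#'
#' Supported formats: `csv`/`tsv` (RFC-style quoting; leading whitespace
#' inside fields is significant, as it encodes category indentation), `html`
#' (`rowspan`/`colspan` honored; `thead` rows become header rows), and
#' `grid-json`. CSV/TSV cannot express header extents, so
#' `n_header_rows`/`n_header_cols` come from the options.
#'
#' @param path input file.
#' @param format one of `"csv"`, `"tsv"`, `"html"`, `"grid-json"`; default
#'   guessed from the file extension.
#' @param n_header_rows,n_header_cols header prefix for formats that cannot
#'   express it (and override for HTML without `thead`).
#' @param caption,footnotes optional metadata for CSV/TSV input.
#' @param rotated,multipage feature flags supplied by the caller.
#' @return a [table_grid()].
#' @export
read_table_file <- function(path, format = NULL, n_header_rows = 1L,
                            n_header_cols = 1L, caption = "",
                            footnotes = character(), rotated = FALSE,
                            multipage = FALSE) {
  if (!file.exists(path))
    stop("input file does not exist: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", tsv = "tsv", html = "html", htm = "html",
                     json = "grid-json",
                     stop("cannot guess format from extension: ", path,
                          call. = FALSE))
  }
  switch(format,
    "grid-json" = read_grid_json(path),
    "csv" = read_delim_grid(path, ",", n_header_rows, n_header_cols,
                            caption, footnotes, rotated, multipage),
    "tsv" = read_delim_grid(path, "\t", n_header_rows, n_header_cols,
                            caption, footnotes, rotated, multipage),
    "html" = read_html_grid(path, n_header_rows, n_header_cols,
                            rotated, multipage),
    stop("unknown format: ", format, call. = FALSE))
}

read_delim_grid <- function(path, sep, n_header_rows, n_header_cols,
                            caption, footnotes, rotated, multipage) {
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = FALSE,
                      colClasses = "character", quote = "\"",
                      strip.white = FALSE, blank.lines.skip = FALSE,
                      fill = FALSE, comment.char = "", encoding = "UTF-8"),
    error = function(e) stop("malformed/ragged delimited input in ", path,
                             ": ", conditionMessage(e), call. = FALSE))
  grid_from_matrix(as.matrix(df), n_header_rows, n_header_cols,
                   caption, footnotes, rotated, multipage)
}

read_html_grid <- function(path, n_header_rows, n_header_cols,
                           rotated, multipage) {
  doc <- tryCatch(xml2::read_html(path, encoding = "UTF-8"),
                  error = function(e) stop("malformed HTML in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  tab <- xml2::xml_find_first(doc, ".//table")
  if (inherits(tab, "xml_missing"))
    stop("no <table> element found in ", path, call. = FALSE)
  cap <- xml2::xml_find_first(tab, ".//caption")
  caption <- if (inherits(cap, "xml_missing")) "" else
    strip_ws(xml2::xml_text(cap))
  head_rows <- xml2::xml_find_all(tab, ".//thead/tr")
  body_rows <- xml2::xml_find_all(
    tab, ".//tr[not(ancestor::thead) and not(ancestor::tfoot)]")
  rows <- c(head_rows, body_rows)
  if (!length(rows)) stop("HTML table has no rows in ", path, call. = FALSE)
  n_head <- if (length(head_rows)) length(head_rows) else n_header_rows

  # sweep rows, placing each td/th at the first free column, honoring spans
  occupied <- list()  # per absolute row index, integer cols taken (1-based)
  cells <- list()
  n_cols <- 0L
  for (r in seq_along(rows)) {
    tds <- xml2::xml_find_all(rows[[r]], "./td|./th")
    col <- 1L
    for (td in tds) {
      while (col %in% (occupied[[as.character(r)]] %||% integer())) col <- col + 1L
      rs <- as.integer(xml2::xml_attr(td, "rowspan") %||% NA)
      cs <- as.integer(xml2::xml_attr(td, "colspan") %||% NA)
      rs <- if (is.na(rs)) 1L else max(rs, 1L)
      cs <- if (is.na(cs)) 1L else max(cs, 1L)
      txt <- xml2::xml_text(td)
      cells[[length(cells) + 1L]] <-
        tt_cell(txt, r - 1L, col - 1L, rs, cs)
      for (rr in r + seq_len(rs) - 1L) {
        key <- as.character(rr)
        occupied[[key]] <- c(occupied[[key]] %||% integer(),
                             col + seq_len(cs) - 1L)
      }
      n_cols <- max(n_cols, col + cs - 1L)
      col <- col + cs
    }
  }
  foot <- xml2::xml_find_all(tab, ".//tfoot//td|.//tfoot//th")
  footnotes <- strip_ws(vapply(foot, xml2::xml_text, character(1)))
  footnotes <- footnotes[nzchar(footnotes)]
  table_grid(cells, length(rows), n_cols, n_head, n_header_cols,
             caption, footnotes, rotated, multipage)
}

#' Write a grid as CSV (UTF-8, RFC quoting, whitespace preserved)
#'
#' @param grid a [table_grid()].
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  m <- grid_matrix(grid)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(m, con, sep = ",", qmethod = "double",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a grid as an HTML table
#'
#' Nested header levels are emitted with `rowspan`/`colspan` by merging
#' adjacent header cells of equal text; the header prefix goes into `thead`.
#'
#' @param grid a [table_grid()].
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_grid_html <- function(grid, path) {
  m <- grid_matrix(grid)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  row_html <- function(r, tag) {
    out <- character()
    co <- 1L
    while (co <= ncol(m)) {
      span <- 1L
      # merge equal, non-empty adjacent header cells into a colspan
      if (r <= grid$n_header_rows && nzchar(m[r, co])) {
        while (co + span <= ncol(m) && identical(m[r, co + span], m[r, co]))
          span <- span + 1L
      }
      attr_ <- if (span > 1L) sprintf(" colspan=\"%d\"", span) else ""
      out <- c(out, sprintf("<%s%s>%s</%s>", tag, attr_, esc(m[r, co]), tag))
      co <- co + span
    }
    paste0("<tr>", paste(out, collapse = ""), "</tr>")
  }
  head_idx <- seq_len(grid$n_header_rows)
  body_idx <- setdiff(seq_len(nrow(m)), head_idx)
  lines <- c("<table>",
             if (nzchar(grid$caption))
               paste0("<caption>", esc(grid$caption), "</caption>"),
             "<thead>", vapply(head_idx, row_html, "", tag = "th"), "</thead>",
             "<tbody>", vapply(body_idx, row_html, "", tag = "td"), "</tbody>",
             if (length(grid$footnotes))
               c("<tfoot>",
                 sprintf("<tr><td colspan=\"%d\">%s</td></tr>", ncol(m),
                         esc(grid$footnotes)),
                 "</tfoot>"),
             "</table>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
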