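#' Construct a table cell
#'
#' Cells are addressed 0-based, row-major. The indentation level is derived
#' deterministically from the text's leading whitespace (one tab, two spaces,
#' or one pair of non-breaking spaces per level); it carries the nesting of
#' category labels under their categorical data-element header.
#'
#' @param text cell text, leading whitespace preserved.
#' @param row,col 0-based position of the cell's top-left corner.
#' @param row_span,col_span extent of the cell; must be >= 1.
#' @return a `tt_cell` list.
#' @export
tt_cell <- function(text, row, col, row_span = 1L, col_span = 1L) {
  stopifnot(is.character(text), length(text) == 1L,
            row >= 0, col >= 0, row_span >= 1, col_span >= 1)
  structure(
    list(text = text, row = as.integer(row), col = as.integer(col),
         row_span = as.integer(row_span), col_span = as.integer(col_span),
         indent_level = indent_of(text)),
    class = "tt_cell"
  )
}

#' Construct a table grid
#'
#' The raw substrate for all classification: a rectangular cell grid with a
#' header prefix (first `n_header_rows` rows and `n_header_cols` columns),
#' caption, footnotes, and the orientation/pagination flags counted by the
#' reporting-practice survey (rotated 90 degrees, multipage).
#'
#' @param cells list of [tt_cell()] objects; may be sparse (cells covered by a
#'   span, or genuinely empty, may be omitted).
#' @param n_rows,n_cols grid dimensions after span expansion.
#' @param n_header_rows,n_header_cols size of the header prefix; must leave at
#'   least one body row and column.
#' @param caption table caption text.
#' @param footnotes character vector of footnote strings.
#' @param rotated,multipage feature flags supplied by the reader.
#' @return a `table_grid` object.
#' @export
table_grid <- function(cells, n_rows, n_cols, n_header_rows = 1L,
                       n_header_cols = 1L, caption = "",
                       footnotes = character(), rotated = FALSE,
                       multipage = FALSE) {
  stopifnot(n_rows >= 1, n_cols >= 1,
            n_header_rows >= 0, n_header_cols >= 0,
            n_header_rows < n_rows, n_header_cols < n_cols)
  for (cl in cells) {
    if (!inherits(cl, "tt_cell"))
      stop("all cells must be `tt_cell` objects", call. = FALSE)
    if (cl$row + cl$row_span > n_rows || cl$col + cl$col_span > n_cols)
      stop(sprintf("cell at (%d,%d) extends beyond the %dx%d grid",
                   cl$row, cl$col, n_rows, n_cols), call. = FALSE)
  }
  structure(
    list(cells = cells, n_rows = as.integer(n_rows),
         n_cols = as.integer(n_cols),
         n_header_rows = as.integer(n_header_rows),
         n_header_cols = as.integer(n_header_cols),
         caption = caption, footnotes = as.character(footnotes),
         flags = list(rotated = isTRUE(rotated), multipage = isTRUE(multipage))),
    class = "table_grid"
  )
}

#' @export
print.table_grid <- function(x, ...) {
  cat(sprintf("<table_grid> %d x %d (header %d row(s), %d col(s))\n",
              x$n_rows, x$n_cols, x$n_header_rows, x$n_header_cols))
  if (nzchar(x$caption)) cat("caption: ", x$caption, "\n", sep = "")
  m <- grid_matrix(x)
  w <- pmin(apply(nchar(m), 2, max), 24L)
  for (i in seq_len(nrow(m))) {
    cat(paste(formatC(substr(m[i, ], 1, 24), width = w, flag = "-"),
              collapse = " | "), "\n")
  }
  if (length(x$footnotes))
    cat(paste0("[", seq_along(x$footnotes), "] ", x$footnotes, collapse = "\n"), "\n")
  invisible(x)
}

#' Expand spanned cells into every covered grid position
#'
#' Replicates each cell's text into all positions its row/col spans cover,
#' producing a fully rectangular grid (positions covered by no cell become
#' empty cells). Overlapping spans are a structural error. Expansion is
#' idempotent.
#'
#' @param grid a [table_grid()].
#' @return a `table_grid` with one span-1 cell per position.
#' @export
expand_spans <- function(grid) {
  stopifnot(inherits(grid, "table_grid"))
  nr <- grid$n_rows; nc <- grid$n_cols
  txt <- matrix(NA_character_, nr, nc)
  for (cl in grid$cells) {
    rows <- cl$row + seq_len(cl$row_span) - 1L
    cols <- cl$col + seq_len(cl$col_span) - 1L
    for (r in rows) for (co in cols) {
      if (!is.na(txt[r + 1L, co + 1L]))
        stop(sprintf("overlapping spans at cell (%d,%d)", r, co), call. = FALSE)
      txt[r + 1L, co + 1L] <- cl$text
    }
  }
  txt[is.na(txt)] <- ""
  cells <- vector("list", nr * nc)
  k <- 1L
  for (r in seq_len(nr) - 1L) for (co in seq_len(nc) - 1L) {
    cells[[k]] <- tt_cell(txt[r + 1L, co + 1L], r, co)
    k <- k + 1L
  }
  out <- grid
  out$cells <- cells
  out
}

#' Character matrix view of a grid (after span expansion)
#'
#' @param grid a [table_grid()].
#' @return character matrix of dimension `n_rows` x `n_cols`.
#' @export
grid_matrix <- function(grid) {
  g <- expand_spans(grid)
  m <- matrix("", g$n_rows, g$n_cols)
  for (cl in g$cells) m[cl$row + 1L, cl$col + 1L] <- cl$text
  m
}

# build a grid from a character matrix (span-1 cells); NA -> ""
grid_from_matrix <- function(m, n_header_rows = 1L, n_header_cols = 1L,
                             caption = "", footnotes = character(),
                             rotated = FALSE, multipage = FALSE) {
  m[is.na(m)] <- ""
  cells <- list()
  k <- 1L
  for (r in seq_len(nrow(m)) - 1L) for (co in seq_len(ncol(m)) - 1L) {
    cells[[k]] <- tt_cell(m[r + 1L, co + 1L], r, co)
    k <- k + 1L
  }
  table_grid(cells, nrow(m), ncol(m), n_header_rows, n_header_cols,
             caption, footnotes, rotated, multipage)
}
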