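# small hand-built grids used across tests

fixture_baseline_grid <- function(rotated = FALSE, multipage = FALSE) {
  m <- rbind(
    c("Characteristic", "Placebo (n=25)", "Aspirin (n=30)"),
    c("Age, years", "54.2 ± 8.1", "55.0 ± 7.9"),
    c("Smoking", "", ""),
    c("  Yes", "12 (48.0%)", "9 (30.0%)"),
    c("  No", "13 (52.0%)", "21 (70.0%)"))
  trialtables:::grid_from_matrix(
    m, 1, 1, caption = "Table 1. Baseline characteristics.",
    rotated = rotated, multipage = multipage)
}

fixture_nested_col_grid <- function() {
  # arms spanning time points on columns, data elements on rows
  cells <- list(
    tt_cell("", 0, 0, row_span = 2),
    tt_cell("Control", 0, 1, col_span = 2),
    tt_cell("Treatment", 0, 3, col_span = 2),
    tt_cell("Baseline", 1, 1), tt_cell("Follow-up", 1, 2),
    tt_cell("Baseline", 1, 3), tt_cell("Follow-up", 1, 4),
    tt_cell("Pain score", 2, 0),
    tt_cell("5.1 ± 1.0", 2, 1), tt_cell("4.0 ± 1.1", 2, 2),
    tt_cell("5.2 ± 0.9", 2, 3), tt_cell("2.1 ± 0.8", 2, 4))
  table_grid(cells, n_rows = 3, n_cols = 5, n_header_rows = 2,
             n_header_cols = 1, caption = "Table 2. Outcomes.")
}

# assignment stub for classifier tests, bypassing header detection
fixture_assignment <- function(row_kinds, col_kinds, embedded = FALSE,
                               stratified = FALSE, only_comparative = FALSE) {
  structure(list(row_kinds = row_kinds, col_kinds = col_kinds,
                 embedded = embedded, stratified = stratified,
                 only_comparative = only_comparative,
                 levels = list(row = list(), col = list())),
            class = "context_assignment")
}

random_tag_set <- function(hierarchy, n = 5) {
  sample(hierarchy$id, n)
}

# article record carrying an explicit per-article tag set
tagged_article <- function(id, tags) {
  article_record(id, tables = list(),
                 article_tags = tag_assignment(tags, "per_article"))
}
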