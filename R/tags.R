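#' The tagging hierarchy for table reporting practices
#'
#' Returns the fixed vocabulary used to tag tables and articles: structural
#' attributes (baseline/outcome reporting and breakout level, orientation and
#' pagination), measurement-context attributes (context-dimension class with
#' its named sub-layouts, arm-size placement, intervention and time-point
#' label kinds), and metric attributes (statistic-format and unit locations,
#' the observed statistic formats per metric kind, and category-label
#' placement). Tag identifiers are slash-separated paths; a child tag implies
#' its parent.
#'
#' @return data.frame with columns `id`, `parent`, `label`, `scope`
#'   (`"table"`, `"article"`, or `"both"`).
#' @export
tag_hierarchy <- function() {
  rows <- list(
    # -- table structure ---------------------------------------------------
    c("baseline_in_table", "", "Baseline characteristics reported in table", "both"),
    c("baseline_in_table/arm_level_breakout", "baseline_in_table", "Broken out by arm", "both"),
    c("baseline_in_table/participant_level", "baseline_in_table", "Reported per participant", "both"),
    c("baseline_in_table/no_arm_level_breakout", "baseline_in_table", "Whole population, no breakout", "both"),
    c("outcomes_in_table", "", "Outcomes reported in table", "both"),
    c("outcomes_in_table/arm_level_breakout", "outcomes_in_table", "Broken out by arm", "both"),
    c("outcomes_in_table/participant_level", "outcomes_in_table", "Reported per participant", "both"),
    c("outcomes_in_table/secondary_only", "outcomes_in_table", "Secondary outcomes only", "both"),
    c("table_features", "", "Other table features", "both"),
    c("table_features/rotated", "table_features", "Rotated 90 degrees", "both"),
    c("table_features/multipage", "table_features", "Multipage", "both"),
    # -- measurement context ----------------------------------------------
    c("context_1x1", "", "1x1 context dimensions", "both"),
    c("context_2x1", "", "2x1 context dimensions", "both"),
    c("context_1x2", "", "1x2 context dimensions", "both"),
    c("other_structure", "", "Other structure", "both"),
    c("other_structure/stratified", "other_structure", "Stratified reporting", "both"),
    c("other_structure/comparative_only", "other_structure", "Only comparative statistics", "both"),
    c("context_embedded", "", "Two context kinds in one header cell", "both"),
    c("arm_size_reported", "", "Arm sizes reported", "both"),
    c("arm_size_reported/embedded_in_arm", "arm_size_reported", "Embedded in arm label", "both"),
    c("arm_size_reported/separate_array", "arm_size_reported", "In separate array", "both"),
    c("arm_size_reported/in_description", "arm_size_reported", "In description", "both"),
    c("intervention_labels", "", "Intervention labels reported", "both"),
    c("intervention_labels/control_experimental", "intervention_labels", "Control/experimental", "both"),
    c("intervention_labels/acronym_abbreviation", "intervention_labels", "Acronym or abbreviation", "both"),
    c("intervention_labels/full_name", "intervention_labels", "Full name", "both"),
    c("intervention_labels/alternate", "intervention_labels", "Alternate labels", "both"),
    c("timepoint_labels", "", "Time point labels reported", "both"),
    c("timepoint_labels/unit_of_time", "timepoint_labels", "Contains unit of time", "both"),
    c("timepoint_labels/pre_post", "timepoint_labels", "Pre/post", "both"),
    c("timepoint_labels/incremental", "timepoint_labels", "Incremental numbered", "both"),
    # -- metrics (applied per article) ------------------------------------
    c("format_location", "", "Statistic format displayed", "article"),
    c("format_location/in_header", "format_location", "In header", "article"),
    c("format_location/in_description_or_footnotes", "format_location", "In description or footnotes", "article"),
    c("units_location", "", "Units of continuous data elements reported", "article"),
    c("units_location/in_header", "units_location", "In header", "article"),
    c("units_location/in_description_or_footnotes", "units_location", "In description or footnotes", "article"),
    c("units_location/not_relevant", "units_location", "No unit-relevant data elements", "article"),
    c("continuous_metrics", "", "Continuous metric formats", "article"),
    c("dichotomous_metrics", "", "Dichotomous metric formats", "article"),
    c("categorical_metrics", "", "Categorical metric formats", "article"),
    c("category_labels", "", "Category label placement", "article"),
    c("category_labels/separate_array", "category_labels", "Separate array", "article"),
    c("category_labels/same_array", "category_labels", "Same array, unindented", "article"),
    c("category_labels/same_array_indented", "category_labels", "Same array, indented", "article"),
    c("category_labels/in_cell", "category_labels", "In cell", "article")
  )
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("id", "parent", "label", "scope")

  # named sub-layouts of the three context classes
  lay <- layout_table()
  df <- rbind(df, data.frame(
    id = paste0("context_", lay$group, "/", lay$id)[lay$group != "other"],
    parent = paste0("context_", lay$group)[lay$group != "other"],
    label = lay$name[lay$group != "other"],
    scope = "both", stringsAsFactors = FALSE))

  # observed statistic formats, children of their metric-kind tag
  cat <- format_catalog()
  kind_parent <- c(continuous_mean = "continuous_metrics",
                   continuous_median = "continuous_metrics",
                   dichotomous = "dichotomous_metrics",
                   categorical = "categorical_metrics")
  fmt_ids <- vapply(cat, `[[`, "", "id")
  fmt_kinds <- vapply(cat, `[[`, "", "metric_kind")
  fmt_names <- vapply(cat, `[[`, "", "name")
  df <- rbind(df, data.frame(
    id = paste0(kind_parent[fmt_kinds], "/", fmt_ids),
    parent = unname(kind_parent[fmt_kinds]),
    label = fmt_names, scope = "article", stringsAsFactors = FALSE))
  rownames(df) <- NULL
  df
}

#' Construct a tag assignment
#'
#' @param tags character vector of tag identifiers.
#' @param scope `"per_table"` or `"per_article"`.
#' @return a `tag_assignment` object.
#' @export
tag_assignment <- function(tags = character(), scope = c("per_table", "per_article")) {
  scope <- match.arg(scope)
  structure(list(tags = sort(unique(as.character(tags))), scope = scope),
            class = "tag_assignment")
}

#' @export
print.tag_assignment <- function(x, ...) {
  cat(sprintf("<tag_assignment %s> %d tag(s)\n", x$scope, length(x$tags)))
  if (length(x$tags)) cat(paste0("  ", x$tags, collapse = "\n"), "\n")
  invisible(x)
}

#' Validate a tag assignment against the hierarchy
#'
#' Checks that every tag identifier exists in the hierarchy and that every
#' child tag is accompanied by its parent (child tags imply their parent).
#' Problems are reported as violations, never raised.
#'
#' @param tags a [tag_assignment()] or character vector of tag ids.
#' @param hierarchy the tag vocabulary; defaults to [tag_hierarchy()].
#' @return character vector of violation messages; empty when valid.
#' @export
validate_tags <- function(tags, hierarchy = tag_hierarchy()) {
  ids <- if (inherits(tags, "tag_assignment")) tags$tags else
    sort(unique(as.character(tags)))
  out <- character()
  for (id in ids) {
    i <- match(id, hierarchy$id)
    if (is.na(i)) {
      out <- c(out, sprintf("unknown tag: %s", id))
      next
    }
    parent <- hierarchy$parent[i]
    if (nzchar(parent) && !(parent %in% ids))
      out <- c(out, sprintf("tag %s present without its parent %s", id, parent))
  }
  out
}

# does a tag set hold `tag`, counting any descendant as a hit
holds_tag <- function(tags, tag) {
  any(tags == tag | startsWith(tags, paste0(tag, "/")))
}
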