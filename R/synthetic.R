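# ---- generative configuration ----------------------------------------------

norm_dist <- function(x) x / sum(x)

#' Generative configuration for synthetic trial tables
#'
#' Defaults reproduce the observed reporting-practice frequencies: the
#' layout distribution is proportional to the per-table counts of the 15
#' named sub-layouts plus stratified/comparative-only tables; the statistic
#' format distributions per metric kind, the arm-size placement,
#' intervention-label and time-point-label distributions, and the article
#' composition probabilities are proportional to the corresponding
#' per-article counts.
#'
#' @param layout_dist named probabilities over [layout_table()] ids.
#' @param mean_format_dist,median_format_dist,dichotomous_format_dist,categorical_format_dist
#'   named probabilities over catalog format ids, per metric kind.
#' @param p_median probability that a continuous data element is summarized
#'   by a median rather than a mean.
#' @param de_kind_dist distribution of data-element kinds.
#' @param cat_placement_dist distribution of category-label placements the
#'   generator renders (indented, in-cell, or unindented same-array).
#' @param p_arm_size_reported probability an article reports arm sizes.
#' @param arm_size_placement_dist placement distribution given reported.
#' @param intervention_label_dist per-article intervention label kinds.
#' @param timepoint_label_dist per-article time-point label kinds.
#' @param article_composition list with `p_baseline`, `p_outcomes`,
#'   `extra_outcome_table_rate` (Poisson rate for outcome tables beyond the
#'   first), `p_secondary_only`.
#' @param p_format_declared probability an article declares its statistic
#'   formats; `format_location_dist` splits header vs description/footnote.
#' @param format_location_dist see above.
#' @param p_units_relevant probability a continuous-reporting article has
#'   unit-relevant data elements; `units_location_dist` covers header,
#'   description/footnote, and missing.
#' @param units_location_dist see above.
#' @param p_rotated,p_multipage per-table feature flag probabilities.
#' @param n_arms_range,n_data_elements_range,n_time_points_range integer
#'   ranges sampled uniformly.
#' @param noise list with `missing_cell_prob`, `unicode_variant_prob`,
#'   `rounding_decimals`.
#' @param seed optional integer seed recorded on the spec (applied by
#'   [generate_corpus()] when no explicit seed is given).
#' @return a `synthetic_spec` object.
#' @export
synthetic_spec <- function(
    layout_dist = NULL,
    mean_format_dist = norm_dist(c(mean_pm_sd = 41, mean_sd_paren = 25,
                                   mean_sd_separate = 2, mean_bare = 2,
                                   mean_sd_space = 1, mean_ci = 1,
                                   mean_pm_sd_range = 1)),
    median_format_dist = norm_dist(c(median_iqr = 11, median_range = 4,
                                     median_iqr_bracket = 3,
                                     median_iqr_bracket_comma = 1,
                                     median_iqr_to = 1,
                                     median_iqr_unspecified = 1,
                                     min_max_median = 1)),
    dichotomous_format_dist = norm_dist(c(n_pct = 30, n_bare = 3,
                                          n_over_rest = 3, pct_bare = 3,
                                          n_comma_pct = 2, n_pct_separate = 1)),
    categorical_format_dist = norm_dist(c(cat_n_pct = 40, cat_n = 8)),
    p_median = 21 / 90,
    de_kind_dist = c(continuous = 0.60, dichotomous = 0.25,
                     categorical = 0.15),
    cat_placement_dist = norm_dist(c(same_array_indented = 35, in_cell = 7,
                                     same_array = 1)),
    p_arm_size_reported = 57 / 77,
    arm_size_placement_dist = norm_dist(c(embedded_in_arm = 50,
                                          separate_array = 6,
                                          in_description = 1)),
    intervention_label_dist = norm_dist(c(control_experimental = 26,
                                          acronym_abbreviation = 25,
                                          full_name = 23, alternate = 3)),
    timepoint_label_dist = norm_dist(c(pre_post = 24, unit_of_time = 22,
                                       incremental = 6)),
    article_composition = list(p_baseline = 66 / 78, p_outcomes = 72 / 78,
                               extra_outcome_table_rate = 35 / 72,
                               p_secondary_only = 2 / 107),
    p_format_declared = 65 / 77,
    format_location_dist = norm_dist(c(in_header = 35,
                                       in_description_or_footnotes = 30)),
    p_units_relevant = 64 / 75,
    units_location_dist = norm_dist(c(in_header = 55,
                                      in_description_or_footnotes = 5,
                                      missing = 4)),
    p_rotated = 6 / 174, p_multipage = 5 / 174,
    n_arms_range = 2:3, n_data_elements_range = 3:6,
    n_time_points_range = 2:3,
    noise = list(missing_cell_prob = 0, unicode_variant_prob = 0,
                 rounding_decimals = 1L),
    seed = NULL) {
  if (is.null(layout_dist)) {
    lay <- layout_table()
    layout_dist <- stats::setNames(norm_dist(lay$count), lay$id)
  }
  spec <- list(layout_dist = layout_dist,
               mean_format_dist = mean_format_dist,
               median_format_dist = median_format_dist,
               dichotomous_format_dist = dichotomous_format_dist,
               categorical_format_dist = categorical_format_dist,
               p_median = p_median, de_kind_dist = de_kind_dist,
               cat_placement_dist = cat_placement_dist,
               p_arm_size_reported = p_arm_size_reported,
               arm_size_placement_dist = arm_size_placement_dist,
               intervention_label_dist = intervention_label_dist,
               timepoint_label_dist = timepoint_label_dist,
               article_composition = article_composition,
               p_format_declared = p_format_declared,
               format_location_dist = format_location_dist,
               p_units_relevant = p_units_relevant,
               units_location_dist = units_location_dist,
               p_rotated = p_rotated, p_multipage = p_multipage,
               n_arms_range = n_arms_range,
               n_data_elements_range = n_data_elements_range,
               n_time_points_range = n_time_points_range,
               noise = noise, seed = seed)
  for (nm in c("layout_dist", "mean_format_dist", "median_format_dist",
               "dichotomous_format_dist", "categorical_format_dist",
               "de_kind_dist", "cat_placement_dist",
               "arm_size_placement_dist", "intervention_label_dist",
               "timepoint_label_dist", "format_location_dist",
               "units_location_dist")) {
    d <- spec[[nm]]
    if (any(d < 0) || abs(sum(d) - 1) > 1e-9)
      stop(nm, " must be a probability distribution summing to 1",
           call. = FALSE)
  }
  structure(spec, class = "synthetic_spec")
}

sample_one <- function(dist) sample(names(dist), 1L, prob = dist)

# pools of plausible trial data elements; names deliberately avoid the
# detector lexicons so a data-element level always falls through to the
# DATA_ELEMENT verdict
de_pools <- function() {
  list(
    continuous = data.frame(
      name = c("Age", "Body mass index", "Systolic blood pressure",
               "Heart rate", "Hemoglobin", "Pain score",
               "Quality of life score", "Serum creatinine"),
      unit = c("years", "kg/m2", "mmhg", "bpm", "g/dl", "points", "points",
               "mmol/l"),
      stringsAsFactors = FALSE),
    dichotomous = c("Mortality", "Hypertension", "Diabetes mellitus",
                    "Current smoker", "Adverse events", "Previous surgery",
                    "Readmission"),
    categorical = list(
      list(name = "Smoking status",
           categories = c("Never", "Former", "Current")),
      list(name = "Disease severity",
           categories = c("Mild", "Moderate", "Severe")),
      list(name = "Ambulation status",
           categories = c("Independent", "Assisted", "Dependent"))),
    in_cell = list(
      list(name = "Gender", categories = c("M", "F")),
      list(name = "ASA class", categories = c("I", "II", "III")))
  )
}

#' Sample the article-level reporting properties
#'
#' One independent draw per property, at the spec's configured rates; the
#' properties are applied consistently across an article's tables (same
#' arms, same label conventions, same declaration locations).
#'
#' @param spec a [synthetic_spec()].
#' @param lexicons lexicons supplying the intervention name pool.
#' @return list of sampled properties, including the article's arms.
#' @export
sample_article_props <- function(spec, lexicons = default_lexicons()) {
  kind <- sample_one(spec$intervention_label_dist)
  n_arms <- if (kind == "control_experimental") 2L
            else sample(spec$n_arms_range, 1L)
  cap1 <- function(x) paste0(toupper(substr(x, 1, 1)), substring(x, 2))
  multi <- lexicons$interventions[grepl(" ", lexicons$interventions)]
  labels <- switch(kind,
    control_experimental = c("Control",
                             sample(c("Treatment", "Experimental",
                                      "Intervention"), 1L)),
    full_name = cap1(sample(lexicons$interventions, n_arms)),
    acronym_abbreviation = initialism(sample(multi, n_arms)),
    alternate = paste("Group", LETTERS[seq_len(n_arms)]))
  list(
    intervention_kind = kind,
    arms = data.frame(label = labels,
                      size = sample(20:100, n_arms, replace = TRUE),
                      stringsAsFactors = FALSE),
    timepoint_kind = sample_one(spec$timepoint_label_dist),
    arm_size_reported = stats::runif(1) < spec$p_arm_size_reported,
    arm_size_placement = sample_one(spec$arm_size_placement_dist),
    format_declared = stats::runif(1) < spec$p_format_declared,
    format_location = sample_one(spec$format_location_dist),
    units_relevant = stats::runif(1) < spec$p_units_relevant,
    units_location = sample_one(spec$units_location_dist)
  )
}

make_tps <- function(kind, n_range) {
  switch(kind,
    pre_post = {
      pair <- sample(list(c("Baseline", "Follow-up"), c("Pre", "Post"),
                          c("Before", "After")), 1L)[[1]]
      pair
    },
    unit_of_time = {
      n <- sample(n_range, 1L)
      amt <- sort(sample(c(1, 2, 3, 6, 9, 12), n))
      sprintf("%d month%s", amt, ifelse(amt > 1, "s", ""))
    },
    incremental = paste0("T", seq_len(sample(n_range, 1L))))
}

# ---- table generation -------------------------------------------------------

draw_cont_values <- function() {
  c0 <- stats::runif(1, 20, 80)
  s <- stats::runif(1, 2, 15)
  c(MEAN = c0, SD = s, MEDIAN = c0, P25 = c0 - 0.7 * s, P75 = c0 + 0.7 * s,
    MIN = c0 - 2 * s, MAX = c0 + 2 * s, CI_LO = c0 - s, CI_HI = c0 + s)
}

draw_dich_values <- function(size, dec) {
  n <- stats::rbinom(1, size, stats::runif(1, 0.05, 0.6))
  c(N = n, N_TOTAL = size, N_REST = size - n,
    PCT = round_half_up(100 * n / size, dec))
}

draw_cat_values <- function(size, k, dec) {
  counts <- as.integer(stats::rmultinom(1, size, stats::runif(k, 0.5, 2)))
  list(ns = counts, pcts = round_half_up(100 * counts / size, dec))
}

# printed-precision copy of the values a format consumes
printed_values <- function(values, fmt, dec) {
  ph <- intersect(fmt$pattern, PLACEHOLDERS)
  out <- values[ph]
  dec_ph <- setdiff(ph, INT_PLACEHOLDERS)
  out[dec_ph] <- round_half_up(out[dec_ph], dec)
  out
}

#' Generate one annotated synthetic table
#'
#' Samples a layout, arms, data elements, and (when the layout calls for
#' them) time points; draws true summary values; renders every metric in
#' the sampled statistic format with the sampled label conventions; and
#' records complete ground truth: the context structure, arms and sizes,
#' the format draws, and the true constituents behind every rendered body
#' cell.
#'
#' @param spec a [synthetic_spec()].
#' @param props article-level properties from [sample_article_props()];
#'   sampled fresh when `NULL`.
#' @param table_type `"baseline"` or `"outcome"`.
#' @param layout_id force a layout; sampled from `spec$layout_dist` when
#'   `NULL`.
#' @param secondary_only render/label as a secondary-outcomes table.
#' @param lexicons detector lexicons (the generator draws intervention names
#'   from the same pool the detectors recognize).
#' @return list with `grid` (a [table_grid()]) and `truth` (ground-truth
#'   record, including the ready-made [annotated_table()]).
#' @export
generate_table <- function(spec, props = NULL,
                           table_type = c("baseline", "outcome"),
                           layout_id = NULL, secondary_only = FALSE,
                           lexicons = default_lexicons()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  table_type <- match.arg(table_type)
  props <- props %||% sample_article_props(spec, lexicons)
  layout_id <- layout_id %||% sample_one(spec$layout_dist)
  dec <- spec$noise$rounding_decimals
  lay <- layout_table()
  li <- match(layout_id, lay$id)
  if (is.na(li)) stop("unknown layout id: ", layout_id, call. = FALSE)
  rotated <- stats::runif(1) < spec$p_rotated
  multipage <- stats::runif(1) < spec$p_multipage
  caption <- if (table_type == "baseline")
    "Table 1. Baseline characteristics of the study population."
  else if (secondary_only) "Table 2. Secondary outcomes."
  else "Table 2. Clinical outcomes."

  if (layout_id == "comparative_only")
    return(generate_comparative_table(spec, props, table_type, caption,
                                      rotated, multipage, dec))

  stratified <- layout_id == "stratified"
  rk <- if (stratified) "DATA_ELEMENT" else lay$row_kinds[[li]]
  ck <- if (stratified) "ARM" else lay$col_kinds[[li]]
  emb <- lay$embedded[li]

  arms <- props$arms
  needs_tp <- "TIME_POINT" %in% c(rk, ck)
  tps <- if (needs_tp) make_tps(props$timepoint_kind,
                                spec$n_time_points_range)

  # arm-size placement realized for this table
  placement <- if (stratified || !props$arm_size_reported) NULL
    else if (props$arm_size_placement == "separate_array" &&
             layout_id != "de_rows_arm_cols") "embedded_in_arm"
    else props$arm_size_placement
  arm_display <- arms$label
  if (identical(placement, "embedded_in_arm"))
    arm_display <- sprintf("%s (n=%d)", arms$label, arms$size)

  # data elements
  de_explicit <- "DATA_ELEMENT" %in% c(rk, ck)
  allow_cat <- identical(rk, "DATA_ELEMENT") && !emb
  pools <- de_pools()
  n_de <- if (de_explicit) sample(spec$n_data_elements_range, 1L) else 1L
  kinds <- sample(names(spec$de_kind_dist), n_de, replace = TRUE,
                  prob = spec$de_kind_dist)
  if (!allow_cat) kinds[kinds == "categorical"] <- "dichotomous"

  # table-level statistic formats; record every draw made
  format_draws <- list()
  central <- ifelse(kinds == "continuous" & stats::runif(n_de) < spec$p_median,
                    "median", "mean")
  if (any(kinds == "continuous" & central == "mean"))
    format_draws$mean <- sample_one(spec$mean_format_dist)
  if (any(kinds == "continuous" & central == "median"))
    format_draws$median <- sample_one(spec$median_format_dist)
  if (any(kinds == "dichotomous"))
    format_draws$dichotomous <- sample_one(spec$dichotomous_format_dist)
  if (any(kinds == "categorical"))
    format_draws$categorical <- sample_one(spec$categorical_format_dist)

  # a multi-array draw makes the whole table single-kind (an all-means or
  # all-counts table), so its statistic sub-arrays are structurally uniform
  catalog <- format_catalog()
  multi_kind <- NULL
  if (!is.null(format_draws$mean) && catalog[[format_draws$mean]]$multi_array)
    multi_kind <- "continuous_mean"
  else if (!is.null(format_draws$dichotomous) &&
           catalog[[format_draws$dichotomous]]$multi_array)
    multi_kind <- "dichotomous"
  if (!is.null(multi_kind)) {
    if (multi_kind == "continuous_mean") {
      kinds[] <- "continuous"; central[] <- "mean"
    } else kinds[] <- "dichotomous"
  }

  # realize data elements
  des <- vector("list", n_de)
  cont_rows <- sample(seq_len(nrow(pools$continuous)))
  dich_names <- sample(pools$dichotomous)
  cat_pool <- sample(pools$categorical)
  icl_pool <- sample(pools$in_cell)
  ci_cont <- 0L; ci_dich <- 0L; ci_cat <- 0L; ci_icl <- 0L
  for (i in seq_len(n_de)) {
    if (kinds[i] == "continuous") {
      ci_cont <- ci_cont %% nrow(pools$continuous) + 1L
      p <- pools$continuous[cont_rows[ci_cont], ]
      fmt_id <- if (central[i] == "mean") format_draws$mean
                else format_draws$median
      des[[i]] <- list(name = p$name, kind = "continuous",
                       central = central[i], unit = p$unit, fmt = fmt_id,
                       categories = character())
    } else if (kinds[i] == "dichotomous") {
      ci_dich <- ci_dich %% length(pools$dichotomous) + 1L
      des[[i]] <- list(name = dich_names[ci_dich], kind = "dichotomous",
                       unit = NULL, fmt = format_draws$dichotomous,
                       categories = character())
    } else {
      placement_cat <- sample_one(spec$cat_placement_dist)
      if (placement_cat == "in_cell") {
        ci_icl <- ci_icl %% length(pools$in_cell) + 1L
        p <- icl_pool[[ci_icl]]
        # in-cell reporting prints bare counts joined by "/"
        des[[i]] <- list(name = p$name, kind = "categorical",
                         unit = NULL, fmt = "cat_n",
                         categories = p$categories, cat_placement = "in_cell")
      } else {
        ci_cat <- ci_cat %% length(pools$categorical) + 1L
        p <- cat_pool[[ci_cat]]
        des[[i]] <- list(name = p$name, kind = "categorical",
                         unit = NULL, fmt = format_draws$categorical,
                         categories = p$categories,
                         cat_placement = placement_cat)
      }
    }
  }
  # distinct names only
  nm <- vapply(des, `[[`, "", "name")
  des <- des[!duplicated(nm)]
  n_de <- length(des)

  units_shown <- props$units_relevant &&
    props$units_location == "in_header"
  decl_header <- props$format_declared &&
    props$format_location == "in_header"
  de_label <- function(d) {
    lab <- d$name
    if (d$kind == "continuous" && units_shown) lab <- paste0(lab, ", ", d$unit)
    fmt <- catalog[[d$fmt]]
    if (decl_header && !fmt$multi_array &&
        !identical(d$cat_placement %||% "", "in_cell"))
      lab <- paste0(lab, ", ", fmt$name)
    if (identical(d$cat_placement %||% "", "in_cell"))
      lab <- paste0(lab, " ", paste(d$categories, collapse = "/"))
    lab
  }

  strata <- if (stratified) c("Male", "Female") else NULL
  multi_stat_rows <- !is.null(multi_kind) && identical(rk, "DATA_ELEMENT") &&
    !emb
  multi_stat_cols <- !is.null(multi_kind) && !multi_stat_rows
  multi_fmt <- if (!is.null(multi_kind)) {
    id <- if (multi_kind == "continuous_mean") format_draws$mean
          else format_draws$dichotomous
    catalog[[id]]
  }
  stat_names <- if (!is.null(multi_fmt))
    switch(multi_fmt$id, mean_sd_separate = c("Mean", "SD"),
           n_pct_separate = c("n", "%"))
  stat_comps <- if (!is.null(multi_fmt))
    switch(multi_fmt$id, mean_sd_separate = c("MEAN", "SD"),
           n_pct_separate = c("N", "PCT"))

  ent <- function(kind) {
    switch(kind,
      ARM = lapply(seq_len(nrow(arms)), function(j)
        list(label = arm_display[j], arm = arms$label[j])),
      TIME_POINT = lapply(tps, function(tp) list(label = tp, tp = tp)),
      DATA_ELEMENT = lapply(seq_along(des), function(j)
        list(label = de_label(des[[j]]), de = j)))
  }

  # ---- column axis ----
  col_leafs <- list()
  col_header <- list()  # list of char vectors (one per header row)
  if (emb && identical(ck, c("ARM", "TIME_POINT"))) {
    labs <- character()
    for (ae in ent("ARM")) for (te in ent("TIME_POINT")) {
      col_leafs[[length(col_leafs) + 1L]] <- list(arm = ae$arm, tp = te$tp)
      labs <- c(labs, paste0(ae$label, ", ", te$label))
    }
    col_header <- list(labs)
  } else if (length(ck) == 1L) {
    for (e in ent(ck)) col_leafs[[length(col_leafs) + 1L]] <- e
    col_header <- list(vapply(ent(ck), `[[`, "", "label"))
  } else {
    outer <- ent(ck[1]); inner <- ent(ck[2])
    l1 <- character(); l2 <- character()
    for (oe in outer) for (ie in inner) {
      leaf <- c(oe[setdiff(names(oe), "label")],
                ie[setdiff(names(ie), "label")])
      col_leafs[[length(col_leafs) + 1L]] <- leaf
      l1 <- c(l1, oe$label); l2 <- c(l2, ie$label)
    }
    col_header <- list(l1, l2)
  }
  if (!is.null(strata)) {
    base_leafs <- col_leafs; base_header <- col_header
    col_leafs <- list(); l0 <- character()
    rest <- lapply(base_header, function(x) character())
    for (s in strata) for (j in seq_along(base_leafs)) {
      col_leafs[[length(col_leafs) + 1L]] <- c(base_leafs[[j]],
                                               list(stratum = s))
      l0 <- c(l0, s)
      for (k in seq_along(base_header))
        rest[[k]] <- c(rest[[k]], base_header[[k]][j])
    }
    col_header <- c(list(l0), rest)
  }
  if (multi_stat_cols) {
    base_leafs <- col_leafs; base_header <- col_header
    col_leafs <- list()
    rest <- lapply(base_header, function(x) character())
    lstat <- character()
    for (j in seq_along(base_leafs)) for (k in seq_along(stat_names)) {
      col_leafs[[length(col_leafs) + 1L]] <- c(base_leafs[[j]],
                                               list(comp = stat_comps[k]))
      for (h in seq_along(base_header))
        rest[[h]] <- c(rest[[h]], base_header[[h]][j])
      lstat <- c(lstat, stat_names[k])
    }
    col_header <- c(rest, list(lstat))
  }

  # ---- row axis ----
  rows <- list()
  add_row <- function(label, type, de = NULL, arm = NULL, tp = NULL,
                      comp = NULL, category = NULL, cat_index = NULL)
    rows[[length(rows) + 1L]] <<- list(label = label, type = type, de = de,
                                       arm = arm, tp = tp, comp = comp,
                                       category = category,
                                       cat_index = cat_index)
  if (identical(placement, "separate_array"))
    add_row("No. of participants", "size")
  if (emb && identical(rk, c("DATA_ELEMENT", "TIME_POINT"))) {
    for (j in seq_along(des)) for (tp in tps)
      add_row(paste(tp, de_label(des[[j]])), "metric", de = j, tp = tp)
  } else if (length(rk) == 1L) {
    for (e in ent(rk)) {
      if (rk == "DATA_ELEMENT") {
        d <- des[[e$de]]
        if (d$kind == "categorical" &&
            d$cat_placement %in% c("same_array_indented", "same_array")) {
          add_row(de_label(d), "group", de = e$de)
          ind <- if (d$cat_placement == "same_array_indented") "  " else ""
          for (k in seq_along(d$categories))
            add_row(paste0(ind, d$categories[k]), "cat", de = e$de,
                    category = d$categories[k], cat_index = k)
        } else if (multi_stat_rows) {
          add_row(de_label(d), "group", de = e$de)
          for (k in seq_along(stat_names))
            add_row(paste0("  ", stat_names[k]), "stat", de = e$de,
                    comp = stat_comps[k])
        } else {
          add_row(de_label(d), "metric", de = e$de)
        }
      } else {
        add_row(e$label, "metric", arm = e$arm, tp = e$tp)
      }
    }
  } else {
    outer <- ent(rk[1]); inner <- ent(rk[2])
    for (oe in outer) {
      add_row(oe$label, "group", de = oe$de, arm = oe$arm, tp = oe$tp)
      for (ie in inner)
        add_row(paste0("  ", ie$label), "metric",
                de = oe$de %||% ie$de, arm = oe$arm %||% ie$arm,
                tp = oe$tp %||% ie$tp)
    }
  }

  # ---- assemble grid and ground truth ----
  nhr <- length(col_header)
  n_rows <- nhr + length(rows)
  n_cols <- 1L + length(col_leafs)
  m <- matrix("", n_rows, n_cols)
  for (h in seq_len(nhr)) m[h, -1L] <- col_header[[h]]
  corner <- if (!de_explicit) de_label(des[[1]])
            else if (identical(rk, "DATA_ELEMENT")) "Characteristic" else ""
  m[nhr, 1L] <- corner
  for (i in seq_along(rows)) m[nhr + i, 1L] <- rows[[i]]$label

  sizes <- stats::setNames(arms$size, arms$label)
  cache <- new.env(parent = emptyenv())
  value_set <- function(de_j, arm, tp, stratum) {
    key <- paste(de_j, arm %||% "", tp %||% "", stratum %||% "", sep = "\r")
    if (!is.null(cache[[key]])) return(cache[[key]])
    d <- des[[de_j]]
    size <- if (!is.null(arm)) {
      s <- sizes[[arm]]
      if (!is.null(stratum)) max(1L, s %/% 2L) else s
    } else 40L
    v <- switch(d$kind,
                continuous = draw_cont_values(),
                dichotomous = draw_dich_values(size, dec),
                categorical = draw_cat_values(size, length(d$categories), dec))
    cache[[key]] <- v
    v
  }

  metrics <- list()
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (r$type == "group") next
    for (j in seq_along(col_leafs)) {
      leaf <- col_leafs[[j]]
      gr <- nhr + i - 1L   # 0-based grid row
      gc <- j              # 0-based grid col (header col is 0)
      if (r$type == "size") {
        if (is.null(leaf$comp) && !is.null(leaf$arm) &&
            (is.null(leaf$tp) || leaf$tp == tps[1]))
          m[gr + 1L, gc + 1L] <- as.character(sizes[[leaf$arm]])
        next
      }
      de_j <- r$de %||% leaf$de %||% 1L
      arm <- r$arm %||% leaf$arm
      tp <- r$tp %||% leaf$tp
      comp <- r$comp %||% leaf$comp
      stratum <- leaf$stratum
      d <- des[[de_j]]
      v <- value_set(de_j, arm, tp, stratum)
      fmt <- catalog[[d$fmt]]
      rec <- list(row = gr, col = gc, de = d$name, arm = arm, tp = tp,
                  stratum = stratum, format_id = d$fmt)
      if (r$type == "cat") {
        ph_pct <- "PCT" %in% fmt$pattern
        vals <- c(N = v$ns[r$cat_index],
                  if (ph_pct) c(PCT = v$pcts[r$cat_index]))
        txt <- render_metric(vals, fmt, dec)
        rec <- c(rec, list(kind = "scalar", values = vals,
                           category = r$category, text = txt))
      } else if (!is.null(comp)) {
        val <- unname(v[[comp]])
        printed <- if (comp %in% INT_PLACEHOLDERS) sprintf("%d", val)
                   else formatC(round_half_up(val, dec), format = "f",
                                digits = dec)
        vals <- stats::setNames(round_half_up(val, dec), comp)
        if (comp %in% INT_PLACEHOLDERS) vals <- stats::setNames(val, comp)
        txt <- printed
        rec <- c(rec, list(kind = "component", values = vals, text = txt))
      } else if (identical(d$cat_placement %||% "", "in_cell")) {
        txt <- paste(sprintf("%d", v$ns), collapse = "/")
        rec <- c(rec, list(kind = "in_cell", ns = v$ns,
                           categories = d$categories, text = txt))
      } else {
        vals <- printed_values(v, fmt, dec)
        txt <- render_metric(vals, fmt, dec)
        rec <- c(rec, list(kind = "scalar", values = vals, text = txt))
      }
      m[gr + 1L, gc + 1L] <- rec$text
      metrics[[length(metrics) + 1L]] <- rec
    }
  }

  footnotes <- character()
  if (props$format_declared &&
      props$format_location == "in_description_or_footnotes") {
    for (k in names(format_draws))
      footnotes <- c(footnotes,
                     sprintf("%s data are %s.",
                             switch(k, mean = "Continuous",
                                    median = "Continuous",
                                    dichotomous = "Dichotomous",
                                    categorical = "Categorical"),
                             catalog[[format_draws[[k]]]]$name))
  }
  has_cont <- any(vapply(des, `[[`, "", "kind") == "continuous")
  if (has_cont && props$units_relevant &&
      props$units_location == "in_description_or_footnotes") {
    cont <- Filter(function(d) d$kind == "continuous", des)
    footnotes <- c(footnotes,
                   paste0("Units: ",
                          paste(vapply(cont, function(d)
                            paste0(d$name, ", ", d$unit), ""),
                            collapse = "; "), "."))
  }
  if (identical(placement, "in_description"))
    caption <- paste0(caption, " Arm sizes: ",
                      paste(sprintf("%s, n=%d", arms$label, arms$size),
                            collapse = "; "), ".")

  grid <- grid_from_matrix(m, n_header_rows = nhr, n_header_cols = 1L,
                           caption = caption, footnotes = footnotes,
                           rotated = rotated, multipage = multipage)
  grid <- apply_noise(grid, spec)

  structure_truth <- if (stratified)
    context_structure(rk, ck, embedded = FALSE, cls = "OTHER",
                      other_reason = "stratified", sublayout = "stratified")
  else context_structure(rk, ck, embedded = emb, sublayout = layout_id)

  unit_location <- if (!has_cont) NULL
    else if (!props$units_relevant) "not_relevant"
    else if (props$units_location == "missing") NULL
    else props$units_location
  ann <- annotated_table(
    grid = grid, structure = structure_truth, table_type = table_type,
    arm_breakout = "arm_level", secondary_only = secondary_only,
    arm_sizes = sizes, arm_size_placement = placement,
    intervention_kinds = props$intervention_kind,
    timepoint_kinds = if (needs_tp) props$timepoint_kind else character(),
    format_location = if (props$format_declared) props$format_location,
    unit_location = unit_location,
    format_ids = unique(vapply(des, `[[`, "", "fmt")),
    category_placements = unique(unlist(lapply(des, function(d)
      d$cat_placement %||% NULL))),
    has_descriptives = TRUE)

  list(grid = grid,
       truth = list(layout_id = layout_id, structure = structure_truth,
                    arms = arms, arm_size_placement = placement,
                    data_elements = des, timepoints = tps,
                    format_draws = format_draws, metrics = metrics,
                    table_type = table_type, secondary_only = secondary_only,
                    annotated = ann))
}

generate_comparative_table <- function(spec, props, table_type, caption,
                                       rotated, multipage, dec) {
  n_de <- sample(spec$n_data_elements_range, 1L)
  pools <- de_pools()
  names_ <- sample(pools$continuous$name, min(n_de, nrow(pools$continuous)))
  m <- matrix("", length(names_) + 1L, 3L)
  m[1, ] <- c("Outcome", "Mean difference (95% CI)", "P value")
  for (i in seq_along(names_)) {
    d <- stats::runif(1, -5, 5)
    w <- stats::runif(1, 0.5, 3)
    m[i + 1L, ] <- c(names_[i],
                     sprintf("%.1f (%.1f to %.1f)", d, d - w, d + w),
                     sprintf("%.2f", stats::runif(1, 0.001, 0.9)))
  }
  grid <- grid_from_matrix(m, 1L, 1L, caption = caption,
                           rotated = rotated, multipage = multipage)
  grid <- apply_noise(grid, spec)
  structure_truth <- context_structure("DATA_ELEMENT", character(),
                                       cls = "OTHER",
                                       other_reason = "comparative_only",
                                       sublayout = "comparative_only")
  ann <- annotated_table(grid = grid, structure = structure_truth,
                         table_type = table_type, arm_breakout = "none",
                         intervention_kinds = character(),
                         has_descriptives = TRUE)
  list(grid = grid,
       truth = list(layout_id = "comparative_only",
                    structure = structure_truth,
                    arms = props$arms[0, ], arm_size_placement = NULL,
                    data_elements = list(), timepoints = NULL,
                    format_draws = list(), metrics = list(),
                    table_type = table_type, secondary_only = FALSE,
                    annotated = ann))
}

apply_noise <- function(grid, spec) {
  p_miss <- spec$noise$missing_cell_prob
  p_uni <- spec$noise$unicode_variant_prob
  if (p_miss <= 0 && p_uni <= 0) return(grid)
  m <- grid_matrix(grid)
  body <- m[(grid$n_header_rows + 1L):nrow(m),
            (grid$n_header_cols + 1L):ncol(m), drop = FALSE]
  drop <- matrix(stats::runif(length(body)) < p_miss, nrow(body))
  body[drop] <- ""
  swap <- matrix(stats::runif(length(body)) < p_uni, nrow(body))
  body[swap] <- gsub("±", "+/-", body[swap], fixed = TRUE)
  m[(grid$n_header_rows + 1L):nrow(m),
    (grid$n_header_cols + 1L):ncol(m)] <- body
  grid_from_matrix(m, grid$n_header_rows, grid$n_header_cols, grid$caption,
                   grid$footnotes, grid$flags$rotated, grid$flags$multipage)
}

#' Generate a synthetic tagged corpus
#'
#' Per-article table composition follows the spec's article composition
#' probabilities (a baseline table with probability `p_baseline`; one or
#' more outcome tables with probability `p_outcomes`); article-level
#' reporting properties are sampled independently at the configured rates
#' and applied consistently across the article's tables. Deterministic
#' given `seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param n_articles number of articles.
#' @param seed integer seed; defaults to `spec$seed`.
#' @param lexicons detector lexicons.
#' @return list of [article_record()] objects; each table entry carries its
#'   ground truth in `$truth`.
#' @export
generate_corpus <- function(spec, n_articles, seed = spec$seed,
                            lexicons = default_lexicons()) {
  stopifnot(n_articles >= 1)
  if (!is.null(seed)) set.seed(seed)
  comp <- spec$article_composition
  out <- vector("list", n_articles)
  for (i in seq_len(n_articles)) {
    props <- sample_article_props(spec, lexicons)
    gens <- list()
    if (stats::runif(1) < comp$p_baseline)
      gens[[length(gens) + 1L]] <- generate_table(spec, props, "baseline",
                                                  lexicons = lexicons)
    if (stats::runif(1) < comp$p_outcomes) {
      n_out <- 1L + stats::rpois(1, comp$extra_outcome_table_rate)
      for (k in seq_len(n_out))
        gens[[length(gens) + 1L]] <- generate_table(
          spec, props, "outcome",
          secondary_only = stats::runif(1) < comp$p_secondary_only,
          lexicons = lexicons)
    }
    tables <- lapply(gens, function(g) {
      t <- g$truth$annotated
      t$truth <- g$truth
      t
    })
    out[[i]] <- article_record(sprintf("A%03d", i), tables)
  }
  out
}

# ---- ground-truth verification ----------------------------------------------

# placeholder-named values recoverable from a parsed-stats object
stats_values <- function(st, fmt) {
  if (inherits(st, "continuous_stats")) {
    v <- c(MEAN = st$mean %||% NA, SD = st$sd %||% NA,
           MEDIAN = st$median %||% NA, P25 = st$p25 %||% NA,
           P75 = st$p75 %||% NA, MIN = st$min %||% NA, MAX = st$max %||% NA,
           CI_LO = st$ci_lo %||% NA, CI_HI = st$ci_hi %||% NA)
  } else if (inherits(st, "dichotomous_stats")) {
    v <- c(N = st$n %||% NA, N_TOTAL = st$n_total %||% NA,
           N_REST = if (!is.null(st$n_total) && !is.na(st$n))
             st$n_total - st$n else NA,
           PCT = st$pct %||% NA)
  } else {
    v <- c(N = st$entries$n[1], PCT = st$entries$pct[1])
  }
  v[intersect(fmt$pattern, PLACEHOLDERS)]
}

#' Verify that the analysis pipeline recovers a generated table's truth
#'
#' Runs [assign_context_kinds()] and [classify_structure()] on the rendered
#' grid and compares against the ground-truth structure; recovers arm sizes
#' with [recover_arm_sizes()]; and re-parses every rendered metric cell with
#' [parse_metric()] under its recorded format, comparing all constituents at
#' printed precision.
#'
#' @param gen output of [generate_table()].
#' @param lexicons detector lexicons.
#' @return list with logical fields `layout_ok`, `context_ok`, `arms_ok`,
#'   `metrics_ok`, overall `ok`, and a character vector `failures`.
#' @export
verify_ground_truth <- function(gen, lexicons = default_lexicons()) {
  truth <- gen$truth
  fail <- character()
  a <- assign_context_kinds(gen$grid, lexicons)
  s <- classify_structure(a)
  ts <- truth$structure
  layout_ok <- identical(s$cls, ts$cls) &&
    identical(s$other_reason, ts$other_reason) &&
    identical(s$sublayout %||% NA_character_, ts$sublayout %||% NA_character_)
  if (!layout_ok)
    fail <- c(fail, sprintf("layout: expected %s/%s got %s/%s",
                            ts$cls, ts$sublayout %||% "?", s$cls,
                            s$sublayout %||% "?"))
  context_ok <- identical(s$row_kinds, ts$row_kinds) &&
    identical(s$col_kinds, ts$col_kinds) &&
    identical(s$embedded, ts$embedded)
  if (!context_ok) fail <- c(fail, "context kinds differ")

  arms_ok <- TRUE
  if (!is.null(truth$arm_size_placement)) {
    rec <- recover_arm_sizes(gen$grid, a)
    truth_sizes <- stats::setNames(truth$arms$size, truth$arms$label)
    arms_ok <- identical(rec$placement, truth$arm_size_placement) &&
      setequal(names(rec$sizes), names(truth_sizes)) &&
      all(rec$sizes[names(truth_sizes)] == truth_sizes)
    if (!arms_ok) fail <- c(fail, "arm sizes not recovered")
  }

  metrics_ok <- TRUE
  m <- grid_matrix(gen$grid)
  catalog <- format_catalog()
  for (rec in truth$metrics) {
    txt <- m[rec$row + 1L, rec$col + 1L]
    if (!identical(txt, rec$text)) {
      metrics_ok <- FALSE
      fail <- c(fail, sprintf("cell (%d,%d) text mismatch", rec$row, rec$col))
      next
    }
    ok <- tryCatch({
      if (rec$kind == "component") {
        abs(as.numeric(normalize_metric_text(txt)) - rec$values) < 1e-9
      } else if (rec$kind == "in_cell") {
        st <- parse_metric(txt, catalog[[rec$format_id]],
                           categories = rec$categories,
                           label_placement = "in_cell")
        all(st$entries$n == rec$ns)
      } else {
        st <- parse_metric(txt, catalog[[rec$format_id]],
                           categories = rec$category)
        got <- stats_values(st, catalog[[rec$format_id]])
        want <- rec$values[names(got)]
        all(abs(got - want) < 1e-9)
      }
    }, error = function(e) FALSE)
    if (!isTRUE(ok)) {
      metrics_ok <- FALSE
      fail <- c(fail, sprintf("metric at (%d,%d) \"%s\" not recovered",
                              rec$row, rec$col, txt))
    }
  }
  ok <- layout_ok && context_ok && arms_ok && metrics_ok
  list(ok = ok, layout_ok = layout_ok, context_ok = context_ok,
       arms_ok = arms_ok, metrics_ok = metrics_ok, failures = fail)
}

#' Analytic high-density match rate implied by a spec's property rates
#'
#' The product of the independent article-level property rates that the
#' density classifier conjoins: baseline-or-outcome table present, arm size
#' reported, full-name/abbreviation intervention labels (dropped when
#' `require_intervention_labels = FALSE`), units reported when relevant, and
#' statistic format declared.
#'
#' @param spec a [synthetic_spec()].
#' @param require_intervention_labels include the label clause.
#' @return expected match probability.
#' @export
expected_density_rate <- function(spec, require_intervention_labels = TRUE) {
  comp <- spec$article_composition
  p_t <- 1 - (1 - comp$p_baseline) * (1 - comp$p_outcomes)
  p_a <- spec$p_arm_size_reported
  p_l <- if (require_intervention_labels)
    sum(spec$intervention_label_dist[c("acronym_abbreviation", "full_name")])
  else 1
  p_u <- (1 - spec$p_units_relevant) +
    spec$p_units_relevant * (1 - spec$units_location_dist[["missing"]])
  p_f <- spec$p_format_declared
  unname(p_t * p_a * p_l * p_u * p_f)
}
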