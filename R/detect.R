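# ---- lexicons ---------------------------------------------------------------

#' Load a lexicon from a plain-text file (one term per line, case-insensitive)
#'
#' @param path file path.
#' @return lowercase character vector of terms.
#' @export
load_lexicon <- function(path) {
  x <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  tolower(x[nzchar(x) & !startsWith(x, "#")])
}

#' Default lexicons used by the context detectors
#'
#' Control/experimental terms, pre/post time terms, subgroup (stratification)
#' terms, comparative-statistic headers, known intervention full names (with
#' their derived initialisms as the default abbreviation lexicon), and common
#' measurement units. All are plain-text files under
#' `system.file("extdata/lexicons", package = "trialtables")` and can be
#' overridden per call.
#'
#' @param dir directory containing the lexicon files.
#' @return named list of lowercase character vectors: `control`, `prepost`,
#'   `subgroup`, `comparative`, `interventions`, `abbreviations`, `units`.
#' @export
default_lexicons <- function(dir = system.file("extdata", "lexicons",
                                               package = "trialtables")) {
  lx <- list(
    control = load_lexicon(file.path(dir, "control_terms.txt")),
    prepost = load_lexicon(file.path(dir, "prepost_terms.txt")),
    subgroup = load_lexicon(file.path(dir, "subgroup_terms.txt")),
    comparative = load_lexicon(file.path(dir, "comparative_terms.txt")),
    interventions = load_lexicon(file.path(dir, "interventions.txt")),
    units = load_lexicon(file.path(dir, "units.txt")),
    stat = load_lexicon(file.path(dir, "stat_terms.txt"))
  )
  # initialisms of one-word names are bare letters and far too promiscuous
  ab <- initialism(lx$interventions)
  lx$abbreviations <- ab[nchar(ab) >= 2]
  lx
}

#' Initialism of a multi-word name ("high flow nasal cannula" -> "HFNC")
#'
#' @param x character vector of names.
#' @return uppercase initialisms; single-word names yield their first letter.
#' @export
initialism <- function(x) {
  vapply(strsplit(x, "[ -]+"), function(w)
    paste(toupper(substr(w, 1, 1)), collapse = ""), "")
}

# ---- per-cell detectors -----------------------------------------------------

#' Detect an embedded arm size in a header label
#'
#' Recognizes `(n=K)`, `[n=K]`, `N = K`, and a trailing `, n=K`
#' (case-insensitive, flexible spacing) and returns the label with the size
#' expression removed. A label without a size expression is returned
#' unchanged with a `NULL` size, so composition with re-rendering is
#' idempotent.
#'
#' @param text header cell text.
#' @return list with `label` (trimmed residual text) and `size` (positive
#'   integer or `NULL`).
#' @export
#' @examples
#' detect_arm_size("Placebo [n=25]")  # label "Placebo", size 25
detect_arm_size <- function(text) {
  pats <- c("[\\(\\[]\\s*n\\s*=\\s*([0-9]+)\\s*[\\)\\]]",
            ",?\\s*\\bn\\s*=\\s*([0-9]+)\\s*$")
  for (p in pats) {
    m <- regexec(p, text, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] != -1L) {
      size <- as.integer(substr(text, m[2], m[2] + attr(m, "match.length")[2] - 1L))
      label <- paste0(substr(text, 1, m[1] - 1L),
                      substr(text, m[1] + attr(m, "match.length")[1], nchar(text)))
      label <- sub("[ ,;:]+$", "", strip_ws(label))
      return(list(label = label, size = size))
    }
  }
  list(label = strip_ws(text), size = NULL)
}

TIME_UNIT_RE <- paste0(
  "(\\d+(?:\\.\\d+)?)\\s*-?\\s*",
  "(hours?|hrs?|minutes?|mins?|days?|weeks?|wks?|months?|mos?|years?|yrs?)\\b")

canonical_time_unit <- function(u) {
  u <- tolower(u)
  if (grepl("^h", u)) "hour"
  else if (grepl("^min", u)) "minute"
  else if (grepl("^d", u)) "day"
  else if (grepl("^w", u)) "week"
  else if (grepl("^mo", u)) "month"
  else "year"
}

#' Classify a time-point header label
#'
#' Three labeling conventions are recognized, in order: an amount of time
#' with its unit (`"6-month follow-up"`), the pre/post vocabulary
#' (`"Baseline"`, `"Before"`, `"Follow-up"`), and incremental numbering
#' (`"t_2"`, `"Visit 3"`, `"Period II"`).
#'
#' @param text header cell text.
#' @param lexicons detector lexicons, see [default_lexicons()].
#' @return list with `label_kind` (`"unit_of_time"`, `"pre_post"`, or
#'   `"incremental"`), `amount`, and `unit`, or `NULL` when no rule fires.
#' @export
#' @examples
#' classify_timepoint_label("6-month follow-up")  # unit_of_time, 6, month
classify_timepoint_label <- function(text, lexicons = default_lexicons()) {
  tx <- normalize_metric_text(strip_ws(text))
  m <- regexec(TIME_UNIT_RE, tx, perl = TRUE, ignore.case = TRUE)[[1]]
  if (m[1] != -1L) {
    amt <- as.numeric(substr(tx, m[2], m[2] + attr(m, "match.length")[2] - 1L))
    unit <- substr(tx, m[3], m[3] + attr(m, "match.length")[3] - 1L)
    return(list(label_kind = "unit_of_time", amount = amt,
                unit = canonical_time_unit(unit)))
  }
  low <- tolower(tx)
  pp <- paste0("(^|[^a-z])(", paste(lexicons$prepost, collapse = "|"),
               ")($|[^a-z])")
  if (grepl(pp, low, perl = TRUE))
    return(list(label_kind = "pre_post", amount = NULL, unit = NULL))
  inc <- c("^t\\s*[_ ]?\\s*([0-9]+)$",
           "^(?:visit|period|time|phase|week)\\s+([0-9]+|[ivx]+)$")
  for (p in inc) {
    mm <- regexec(p, low, perl = TRUE)[[1]]
    if (mm[1] != -1L) {
      amt_txt <- substr(low, mm[2], mm[2] + attr(mm, "match.length")[2] - 1L)
      amt <- suppressWarnings(as.numeric(amt_txt))
      return(list(label_kind = "incremental",
                  amount = if (!is.na(amt)) amt, unit = NULL))
    }
  }
  NULL
}

#' Classify an intervention (arm) header label
#'
#' @param label arm header text (an embedded size expression is removed
#'   first).
#' @param lexicons detector lexicons; `lexicons$interventions` acts as the
#'   full-name lexicon and `lexicons$abbreviations` (plus an all-caps
#'   short-token heuristic) as the abbreviation lexicon.
#' @return one of `"control_experimental"`, `"abbreviation"`, `"full_name"`,
#'   `"alternate"`.
#' @export
#' @examples
#' classify_intervention_label("Control")  # control_experimental
#' classify_intervention_label("HFNC")     # abbreviation
#' classify_intervention_label("Group A")  # alternate
classify_intervention_label <- function(label, lexicons = default_lexicons()) {
  stopifnot(nzchar(strip_ws(label)))
  lab <- detect_arm_size(label)$label
  low <- tolower(lab)
  if (low %in% lexicons$control) return("control_experimental")
  if (grepl("^(group|arm)\\s+[a-z0-9]+$", low) || grepl("^[A-Z0-9]$", lab))
    return("alternate")
  if (low %in% tolower(lexicons$interventions)) return("full_name")
  if (toupper(lab) %in% lexicons$abbreviations) return("abbreviation")
  if (!grepl(" ", lab) && nchar(lab) <= 6 &&
      sum(strsplit(lab, "")[[1]] %in% LETTERS) >= 2)
    return("abbreviation")
  if (grepl("[a-z]", lab)) return("full_name")
  "alternate"
}

detect_unit <- function(label, lexicons = default_lexicons()) {
  # a comma segment or trailing parenthetical drawn from the unit lexicon
  m <- regexec("\\(([^()]+)\\)\\s*$", label, perl = TRUE)[[1]]
  if (m[1] != -1L) {
    cand <- tolower(strip_ws(substr(label, m[2],
                                    m[2] + attr(m, "match.length")[2] - 1L)))
    if (cand %in% lexicons$units) return(cand)
  }
  segs <- tolower(strip_ws(strsplit(label, ",")[[1]]))
  if (length(segs) > 1) {
    hit <- segs[-1][segs[-1] %in% lexicons$units]
    if (length(hit)) return(hit[1])
  }
  NULL
}

#' Detect categorical data elements in a header array
#'
#' Groups indented cells under the nearest preceding less-indented cell
#' (placement `same_array_indented`), recognizes slash-joined category labels
#' inside one cell such as `"Gender M/F"` (placement `in_cell`), and, when a
#' delimited secondary array is supplied, pairs its labels with the primary
#' array (placement `separate_array`). Ungrouped cells are flat data
#' elements.
#'
#' @param cells character vector (or list of [tt_cell()]) forming the
#'   data-element header array, leading whitespace intact.
#' @param secondary optional parallel array holding category labels.
#' @return list with one entry per data element: `name`, `categories`
#'   (character, possibly empty), `placement` (`NULL` for flat elements),
#'   and `rows` (0-based indices of the array cells involved).
#' @export
#' @examples
#' detect_category_structure(c("Smoking", "  Yes", "  No"))
#' detect_category_structure("Gender M/F")
detect_category_structure <- function(cells, secondary = NULL) {
  texts <- if (is.list(cells))
    vapply(cells, function(cl) cl$text, "") else as.character(cells)
  indents <- vapply(texts, indent_of, 0L)
  out <- list()
  i <- 1L
  n <- length(texts)
  while (i <= n) {
    name <- strip_ws(texts[i])
    base <- indents[i]
    if (!is.null(secondary) && i <= length(secondary) &&
        nzchar(strip_ws(secondary[i]))) {
      j <- i
      cats <- character()
      while (j <= n && (j == i || !nzchar(strip_ws(texts[j])) ||
                        identical(strip_ws(texts[j]), name))) {
        cats <- c(cats, strip_ws(secondary[j]))
        j <- j + 1L
      }
      out[[length(out) + 1L]] <- list(name = name, categories = cats,
                                      placement = "separate_array",
                                      rows = (i:(j - 1L)) - 1L)
      i <- j
      next
    }
    m <- regexec("^(.*\\S)\\s+((?:[A-Za-z]{1,3}/)+[A-Za-z]{1,3})$", name)[[1]]
    if (m[1] != -1L) {
      nm <- substr(name, m[2], m[2] + attr(m, "match.length")[2] - 1L)
      cats <- strsplit(substr(name, m[3],
                              m[3] + attr(m, "match.length")[3] - 1L), "/")[[1]]
      out[[length(out) + 1L]] <- list(name = nm, categories = cats,
                                      placement = "in_cell", rows = i - 1L)
      i <- i + 1L
      next
    }
    j <- i + 1L
    while (j <= n && indents[j] > base) j <- j + 1L
    if (j > i + 1L) {
      out[[length(out) + 1L]] <- list(
        name = name, categories = strip_ws(texts[(i + 1L):(j - 1L)]),
        placement = "same_array_indented", rows = (i:(j - 1L)) - 1L)
    } else {
      out[[length(out) + 1L]] <- list(name = name, categories = character(),
                                      placement = NULL, rows = i - 1L)
    }
    i <- j
  }
  out
}

# ---- header level extraction and scoring ------------------------------------

# runs of equal adjacent non-blank labels collapse to one entry (spans)
run_labels <- function(x) {
  x <- x[!vapply(x, is_blank, TRUE)]
  if (!length(x)) return(character())
  x[c(TRUE, x[-1] != x[-length(x)])]
}

# classify one header label into context-kind evidence
score_label <- function(text, lexicons) {
  lab <- strip_ws(text)
  if (!nzchar(lab)) return("BLANK")
  as_ <- detect_arm_size(lab)
  has_size <- !is.null(as_$size)
  core <- as_$label
  low <- tolower(core)
  arm <- has_size || low %in% lexicons$control ||
    low %in% tolower(lexicons$interventions) ||
    toupper(core) %in% lexicons$abbreviations ||
    grepl("^(group|arm)\\s+[a-z0-9]+$", low)
  tp <- classify_timepoint_label(core, lexicons)
  if (is.null(tp)) {
    # fused header cells join their parts with commas; the anchored
    # incremental patterns only fire on an isolated segment
    segs <- strip_ws(strsplit(core, ",")[[1]])
    if (length(segs) > 1) {
      for (sg in segs) {
        tp <- classify_timepoint_label(sg, lexicons)
        if (!is.null(tp)) break
      }
    }
    if (is.null(tp) && grepl(" ", core))
      tp <- classify_timepoint_label(strsplit(core, " +")[[1]][1], lexicons)
  }
  if (!is.null(tp)) {
    # strip every time expression; what remains decides embedding
    resid <- core
    resid <- gsub(TIME_UNIT_RE, " ", resid, perl = TRUE, ignore.case = TRUE)
    resid <- gsub(paste0("(?i)\\b(", paste(lexicons$prepost, collapse = "|"),
                         ")\\b"), " ", resid, perl = TRUE)
    resid <- gsub("\\bat\\b|\\bt\\s*[_ ]?[0-9]+\\b", " ", resid,
                  perl = TRUE, ignore.case = TRUE)
    resid <- gsub("(?i)\\b(visit|period|time|phase)\\s*[0-9ivx]+\\b", " ",
                  resid, perl = TRUE)
    resid <- strip_ws(gsub("[ ,;:-]+", " ", resid))
    if (nzchar(resid)) {
      resid_arm <- tolower(resid) %in% c(lexicons$control,
                                         tolower(lexicons$interventions)) ||
        toupper(resid) %in% lexicons$abbreviations ||
        grepl("^(group|arm)\\s+[a-z0-9]+", tolower(resid)) ||
        !is.null(detect_arm_size(resid)$size) || arm
      if (resid_arm) return("ARM+TIME_POINT")
      return("DATA_ELEMENT+TIME_POINT")
    }
    return("TIME_POINT")
  }
  if (arm) return("ARM")
  if (low %in% lexicons$subgroup) return("SUBGROUP")
  if (low %in% lexicons$comparative ||
      grepl("p\\s*value|95%\\s*ci|difference|ratio", low)) return("COMPARATIVE")
  if (low %in% lexicons$stat) return("STAT")
  "DATA_ELEMENT"
}

score_level <- function(labels, lexicons) {
  votes <- vapply(labels, score_label, "", lexicons = lexicons)
  votes <- votes[votes != "BLANK"]
  if (!length(votes)) return("BLANK")
  tab <- table(votes)
  prec <- c("ARM+TIME_POINT", "DATA_ELEMENT+TIME_POINT", "ARM", "TIME_POINT",
            "SUBGROUP", "COMPARATIVE", "STAT", "DATA_ELEMENT")
  winners <- names(tab)[tab == max(tab)]
  prec[prec %in% winners][1]
}

# detect an exact repeating label cycle: (g1, c1..cp, g2, c1..cp, ...)
detect_label_cycle <- function(labels) {
  n <- length(labels)
  for (p in 2:6) {
    if (n %% (p + 1L) != 0L || n < 2L * (p + 1L)) next
    blocks <- split(labels, rep(seq_len(n %/% (p + 1L)), each = p + 1L))
    cyc <- blocks[[1]][-1L]
    ok <- all(vapply(blocks, function(b) identical(b[-1L], cyc), TRUE))
    heads <- vapply(blocks, `[[`, "", 1L)
    if (ok && !anyDuplicated(heads) && !any(heads %in% cyc))
      return(list(outer = unname(heads), inner = cyc,
                  period = p, block = p + 1L))
  }
  NULL
}

#' Assign measurement-context kinds to a table's axes
#'
#' Each header array — and each nesting level within an array, identified
#' from spanning header cells, indentation, or an exact repeating label
#' cycle — is scored by the arm-size, time-point, and intervention detectors
#' (in that precedence); the majority kind labels the level and
#' `DATA_ELEMENT` is the fallback for an unscored level. A level whose cells
#' fire two kinds at once (e.g. `"Baseline BMI"`) contributes both kinds
#' with the `embedded` flag set. Subgroup-lexicon levels flag stratified
#' reporting; an axis of comparative-statistic headers flags
#' comparative-only reporting.
#'
#' @param grid a [table_grid()] with a header prefix.
#' @param lexicons detector lexicons.
#' @return a `context_assignment`: list with `row_kinds`, `col_kinds`
#'   (ordered outermost first), `embedded`, `stratified`,
#'   `only_comparative`, and `levels` (the label sets scored).
#' @export
assign_context_kinds <- function(grid, lexicons = default_lexicons()) {
  stopifnot(inherits(grid, "table_grid"))
  if (grid$n_header_rows == 0L && grid$n_header_cols == 0L)
    stop("headerless table: no header rows or columns to classify",
         call. = FALSE)
  m <- grid_matrix(grid)
  body_rows <- (grid$n_header_rows + 1L):grid$n_rows
  body_cols <- (grid$n_header_cols + 1L):grid$n_cols

  col_levels <- list()
  if (grid$n_header_rows > 0L) {
    for (r in seq_len(grid$n_header_rows)) {
      labs <- run_labels(m[r, body_cols])
      if (length(labs))
        col_levels[[length(col_levels) + 1L]] <-
          list(labels = labs, grid_row = r - 1L)
    }
  }

  row_levels <- list()
  if (grid$n_header_cols > 0L) {
    for (co in seq_len(grid$n_header_cols)) {
      raw <- m[body_rows, co]
      keep <- !vapply(raw, is_blank, TRUE)
      nonblank <- raw[keep]
      if (!length(nonblank)) next
      indents <- vapply(nonblank, indent_of, 0L)
      if (grid$n_header_cols == 1L && any(indents > 0L)) {
        # split indentation groups: a shared inner cycle means a nested
        # context level; otherwise the indented cells are category (or
        # statistic-name) labels nested in the same array
        starts <- which(indents == 0L)
        if (length(starts) >= 2L) {
          groups <- mapply(function(s, e) strip_ws(nonblank[s:e]),
                           starts, c(starts[-1L] - 1L, length(nonblank)),
                           SIMPLIFY = FALSE)
          inners <- lapply(groups, `[`, -1L)
          same_cycle <- length(inners[[1]]) >= 2L &&
            all(vapply(inners, identical, TRUE, inners[[1]]))
          if (same_cycle) {
            row_levels <- c(row_levels, list(
              list(labels = unname(vapply(groups, `[[`, "", 1L)),
                   grid_col = co - 1L, derived = "indent_outer"),
              list(labels = inners[[1]], grid_col = co - 1L,
                   derived = "indent_inner")))
            next
          }
        }
        row_levels[[length(row_levels) + 1L]] <-
          list(labels = strip_ws(nonblank[indents == 0L]), grid_col = co - 1L,
               derived = "indent_outer")
        next
      }
      labs <- run_labels(strip_ws(nonblank))
      if (grid$n_header_cols == 1L && length(labs) >= 6L) {
        cyc <- detect_label_cycle(labs)
        if (!is.null(cyc)) {
          row_levels <- c(row_levels, list(
            list(labels = cyc$outer, grid_col = co - 1L,
                 derived = "cycle_outer"),
            list(labels = cyc$inner, grid_col = co - 1L,
                 derived = "cycle_inner")))
          next
        }
      }
      row_levels[[length(row_levels) + 1L]] <-
        list(labels = labs, grid_col = co - 1L, derived = "column")
    }
  }

  resolve <- function(levels) {
    kinds <- character()
    verdicts <- character(length(levels))
    embedded <- FALSE
    stratified <- FALSE
    comparative <- FALSE
    for (i in seq_along(levels)) {
      v <- score_level(levels[[i]]$labels, lexicons)
      verdicts[i] <- v
      if (v %in% c("BLANK", "STAT")) next
      if (v == "SUBGROUP") { stratified <- TRUE; next }
      if (v == "COMPARATIVE") { comparative <- TRUE; next }
      if (grepl("+", v, fixed = TRUE)) {
        kinds <- c(kinds, strsplit(v, "+", fixed = TRUE)[[1]])
        embedded <- TRUE
      } else kinds <- c(kinds, v)
    }
    list(kinds = kinds, verdicts = verdicts, embedded = embedded,
         stratified = stratified, comparative = comparative)
  }
  rr <- resolve(row_levels)
  cc <- resolve(col_levels)
  for (i in seq_along(row_levels)) row_levels[[i]]$verdict <- rr$verdicts[i]
  for (i in seq_along(col_levels)) col_levels[[i]]$verdict <- cc$verdicts[i]
  structure(
    list(row_kinds = rr$kinds, col_kinds = cc$kinds,
         embedded = rr$embedded || cc$embedded,
         stratified = rr$stratified || cc$stratified,
         only_comparative = (cc$comparative && !length(cc$kinds)) ||
                            (rr$comparative && !length(rr$kinds)),
         levels = list(row = row_levels, col = col_levels)),
    class = "context_assignment")
}

#' Recover reported arm sizes from a classified table
#'
#' Looks for arm sizes in the three reporting modes, in order: embedded in
#' the arm header labels (`"Placebo (n=25)"`), a separate size array (a body
#' row labeled like `"No. of participants"` under arm columns), and the
#' table description (caption segments of the form `"<label>, n=<K>"`).
#'
#' @param grid a [table_grid()].
#' @param assignment its [assign_context_kinds()] result.
#' @return list with `placement` (`"embedded_in_arm"`, `"separate_array"`,
#'   `"in_description"`, or `NULL`) and `sizes` (named integer vector keyed
#'   by the size-stripped arm label; `NULL` when none found).
#' @export
recover_arm_sizes <- function(grid, assignment) {
  arm_levels <- Filter(function(lv) grepl("ARM", lv$verdict),
                       c(assignment$levels$row, assignment$levels$col))
  for (lv in arm_levels) {
    det <- lapply(lv$labels, function(x) {
      # embedded arm+time cells carry the size on the arm part
      detect_arm_size(x)
    })
    sizes <- vapply(det, function(d) d$size %||% NA_integer_, 1L)
    if (all(!is.na(sizes))) {
      labels <- vapply(det, function(d)
        strip_ws(sub(",.*$", "", d$label)), "")
      out <- sizes[!duplicated(labels)]
      names(out) <- labels[!duplicated(labels)]
      return(list(placement = "embedded_in_arm", sizes = out))
    }
  }
  # separate size array: a body row whose label is a size term
  size_terms <- c("n", "no. of participants", "number of participants",
                  "no. randomized", "participants")
  m <- grid_matrix(grid)
  if (grid$n_header_cols >= 1L && grid$n_header_rows >= 1L) {
    arm_col_levels <- Filter(function(lv) grepl("ARM", lv$verdict),
                             assignment$levels$col)
    for (r in (grid$n_header_rows + 1L):grid$n_rows) {
      if (tolower(strip_ws(m[r, 1])) %in% size_terms &&
          length(arm_col_levels)) {
        hr <- arm_col_levels[[1]]$grid_row + 1L
        vals <- suppressWarnings(
          as.integer(m[r, (grid$n_header_cols + 1L):grid$n_cols]))
        labs <- vapply(m[hr, (grid$n_header_cols + 1L):grid$n_cols],
                       function(x) detect_arm_size(x)$label, "")
        ok <- !is.na(vals)
        if (any(ok)) {
          out <- vals[ok][!duplicated(labs[ok])]
          names(out) <- labs[ok][!duplicated(labs[ok])]
          return(list(placement = "separate_array", sizes = out))
        }
      }
    }
  }
  # description: "<label>, n=25; <label>, n=30"
  segs <- strsplit(grid$caption, ";|\\.")[[1]]
  hits <- lapply(segs, detect_arm_size)
  got <- Filter(function(h) !is.null(h$size), hits)
  if (length(got)) {
    out <- vapply(got, function(h) h$size, 1L)
    names(out) <- vapply(got, function(h)
      strip_ws(sub("^.*:", "", h$label)), "")
    return(list(placement = "in_description", sizes = out))
  }
  list(placement = NULL, sizes = NULL)
}

#' @export
print.context_assignment <- function(x, ...) {
  cat("<context_assignment>\n",
      " rows: ", paste(x$row_kinds, collapse = " > "), "\n",
      " cols: ", paste(x$col_kinds, collapse = " > "), "\n", sep = "")
  if (x$embedded) cat("  embedded context\n")
  if (x$stratified) cat("  stratified axis detected\n")
  if (x$only_comparative) cat("  comparative statistics only\n")
  invisible(x)
}
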