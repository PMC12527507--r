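#' Input-dataset schema
#'
#' The fixed column dictionary recognized in extraction datasets. Every column
#' describes one reported statistic for a single estimand (one row = one
#' effect size to compute). Unknown columns in input files are ignored with a
#' warning; recognized columns are validated against the type given here.
#'
#' @return A data.frame with columns `name`, `type` and `description`.
#' @export
es_schema <- function() {
  s <- function(name, type, description) {
    data.frame(name = name, type = type, description = description,
               stringsAsFactors = FALSE)
  }
  rbind(
    s("study_id",    "text",      "Study label; clustering key for aggregation and dataset comparison"),
    s("es_direction","direction", "positive / negative / unspecified: sign applied when a route carries no sign (p, F, eta-squared)"),
    s("n1",          "count",     "Sample size, group 1 (exposed/treated)"),
    s("n2",          "count",     "Sample size, group 2 (control)"),
    s("n_total",     "count",     "Total sample size when group sizes are not reported"),
    s("n_cases",     "count",     "Number of cases (binary outcome)"),
    s("n_controls",  "count",     "Number of controls (binary outcome)"),
    s("m1",          "real",      "Mean of group 1 (outcome units; post-test for change designs)"),
    s("m2",          "real",      "Mean of group 2"),
    s("sd1",         "pos",       "Standard deviation of group 1"),
    s("sd2",         "pos",       "Standard deviation of group 2"),
    s("se1",         "pos",       "Standard error of the mean, group 1"),
    s("se2",         "pos",       "Standard error of the mean, group 2"),
    s("m1_ci_lo",    "real",      "Lower 95% CI bound of the group-1 mean"),
    s("m1_ci_up",    "real",      "Upper 95% CI bound of the group-1 mean"),
    s("m2_ci_lo",    "real",      "Lower 95% CI bound of the group-2 mean"),
    s("m2_ci_up",    "real",      "Upper 95% CI bound of the group-2 mean"),
    s("med1",        "real",      "Median of group 1"),
    s("med2",        "real",      "Median of group 2"),
    s("q1_1",        "real",      "First quartile, group 1"),
    s("q3_1",        "real",      "Third quartile, group 1"),
    s("q1_2",        "real",      "First quartile, group 2"),
    s("q3_2",        "real",      "Third quartile, group 2"),
    s("min1",        "real",      "Minimum, group 1"),
    s("max1",        "real",      "Maximum, group 1"),
    s("min2",        "real",      "Minimum, group 2"),
    s("max2",        "real",      "Maximum, group 2"),
    s("t_value",     "real",      "Student t statistic (two independent groups)"),
    s("f_value",     "nonneg",    "One-way ANOVA F statistic, 2 groups (sign from es_direction)"),
    s("p_value",     "p_open",    "Two-tailed p-value of the group comparison (sign from es_direction)"),
    s("eta_sq",      "unit_co",   "Eta-squared, 2 groups (sign from es_direction)"),
    s("md_value",    "real",      "Reported mean difference (group 1 minus group 2)"),
    s("md_se",       "pos",       "Standard error of the reported mean difference"),
    s("md_ci_lo",    "real",      "Lower 95% CI bound of the reported mean difference"),
    s("md_ci_up",    "real",      "Upper 95% CI bound of the reported mean difference"),
    s("pre_m1",      "real",      "Pre-test mean, group 1 (change-score route)"),
    s("pre_m2",      "real",      "Pre-test mean, group 2"),
    s("pre_sd1",     "pos",       "Pre-test SD, group 1"),
    s("pre_sd2",     "pos",       "Pre-test SD, group 2"),
    s("r_prepost",   "corr",      "Pre/post correlation used to build change-score SDs (must be supplied)"),
    s("adj_m1",      "real",      "Covariate-adjusted mean, group 1 (ANCOVA route)"),
    s("adj_m2",      "real",      "Covariate-adjusted mean, group 2"),
    s("adj_sd_pooled","pos",      "Pooled SD on the unadjusted scale accompanying the adjusted means"),
    s("a",           "count",     "2x2 cell: group-1 events"),
    s("b",           "count",     "2x2 cell: group-1 non-events"),
    s("c",           "count",     "2x2 cell: group-2 events"),
    s("d_cell",      "count",     "2x2 cell: group-2 non-events"),
    s("p_event1",    "prob",      "Proportion of events in group 1"),
    s("p_event2",    "prob",      "Proportion of events in group 2"),
    s("or_value",    "pos",       "Reported odds ratio"),
    s("or_ci_lo",    "pos",       "Lower 95% CI bound of the odds ratio"),
    s("or_ci_up",    "pos",       "Upper 95% CI bound of the odds ratio"),
    s("logor_value", "real",      "Reported log odds ratio"),
    s("logor_se",    "pos",       "Standard error of the log odds ratio"),
    s("rr_value",    "pos",       "Reported risk ratio"),
    s("rr_ci_lo",    "pos",       "Lower 95% CI bound of the risk ratio"),
    s("rr_ci_up",    "pos",       "Upper 95% CI bound of the risk ratio"),
    s("e1",          "count",     "Event count, group 1 (incidence-rate route)"),
    s("time1",       "pos",       "Person-time at risk, group 1"),
    s("e2",          "count",     "Event count, group 2"),
    s("time2",       "pos",       "Person-time at risk, group 2"),
    s("r_value",     "corr",      "Correlation coefficient"),
    s("n_r",         "count",     "Sample size of the reported correlation"),
    s("baseline_risk","prob_open","Control-group event probability (OR-to-RR and NNT conversions)")
  )
}

#' Column aliases accepted at read time
#'
#' A small documented alias map applied when reading datasets: a column whose
#' name matches an alias is renamed to its canonical schema name, provided the
#' canonical column is not itself present.
#'
#' @return Named character vector: names are aliases, values canonical names.
#' @export
es_aliases <- function() {
  c(d = "d_cell", t = "t_value", f = "f_value", p = "p_value",
    r = "r_value", eta2 = "eta_sq", or = "or_value", rr = "rr_value",
    logor = "logor_value")
}

# ---- canonicalization -------------------------------------------------------

#' Coerce a data.frame to the recognized schema
#'
#' Renames aliased columns, drops unknown columns with a warning, parses
#' numeric fields (a malformed cell is an error naming its row and column),
#' normalizes `es_direction`, and fills absent schema columns with NA. Blank
#' cells and the NA token become missing values; 0 is a value, never missing.
#'
#' @param df A data.frame, e.g. as read from a CSV.
#' @return A data.frame of class `es_dataset` holding every schema column.
#' @export
as_es_dataset <- function(df) {
  stopifnot(is.data.frame(df))
  schema <- es_schema()
  nm <- names(df)
  if (anyDuplicated(nm)) {
    stop_es("duplicate column names in input: %s",
            paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  al <- es_aliases()
  for (i in seq_along(nm)) {
    if (nm[i] %in% names(al) && !(al[[nm[i]]] %in% nm)) nm[i] <- al[[nm[i]]]
  }
  names(df) <- nm
  unknown <- setdiff(nm, schema$name)
  if (length(unknown)) {
    warn_es("ignoring unknown column(s): %s", paste(unknown, collapse = ", "))
    df <- df[, nm %in% schema$name, drop = FALSE]
  }

  out <- data.frame(row.names = seq_len(nrow(df)))
  bad <- character(0)
  for (k in seq_len(nrow(schema))) {
    col <- schema$name[k]
    type <- schema$type[k]
    if (!col %in% names(df)) {
      out[[col]] <- if (type == "direction") "unspecified"
                    else if (type == "text") NA_character_ else NA_real_
      next
    }
    v <- df[[col]]
    if (type %in% c("text", "direction")) {
      v <- as.character(v)
      v[!is.na(v) & trimws(v) == ""] <- NA_character_
      if (type == "direction") {
        v <- tolower(trimws(v))
        v[is.na(v)] <- "unspecified"
        ok <- v %in% c("positive", "negative", "unspecified")
        if (!all(ok)) {
          stop_es("row %d, column 'es_direction': '%s' is not positive/negative/unspecified",
                  which(!ok)[1L], v[which(!ok)[1L]])
        }
      }
      out[[col]] <- v
    } else {
      ch <- trimws(as.character(v))
      ch[ch == "" | ch == "NA"] <- NA
      parsed <- suppressWarnings(as.numeric(ch))
      mal <- which(!is.na(ch) & is.na(parsed))
      if (length(mal)) {
        bad <- c(bad, sprintf("(row %d, \"%s\": '%s')", mal, col, ch[mal]))
      }
      out[[col]] <- parsed
    }
  }
  if (length(bad)) {
    stop_es("malformed numeric cell(s): %s", paste(bad, collapse = ", "))
  }
  class(out) <- c("es_dataset", "data.frame")
  out
}

# ---- reading / writing ------------------------------------------------------

infer_dialect <- function(path) {
  switch(tolower(tools::file_ext(path)),
         csv = "csv", tsv = "tsv", txt = "tsv", xlsx = "xlsx",
         stop_es("cannot infer file dialect from '%s'; pass dialect=", path))
}

#' Read an extraction dataset
#'
#' Reads a CSV, TSV or XLSX file (first sheet) and coerces it to the schema
#' via [as_es_dataset()]. Numeric parsing accepts decimal points, not commas.
#' Row-level schema violations (see [validate_row()]) are summarized in a
#' warning and re-surface as per-row notes downstream; they are not fatal.
#'
#' @param path File path.
#' @param dialect "auto" (from the extension), "csv", "tsv" or "xlsx".
#' @return An `es_dataset` data.frame.
#' @export
read_dataset <- function(path, dialect = c("auto", "csv", "tsv", "xlsx")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_es("file not found: %s", path)
  if (dialect == "auto") dialect <- infer_dialect(path)
  raw <- switch(dialect,
    csv = utils::read.csv(path, check.names = FALSE, colClasses = "character",
                          na.strings = character(0)),
    tsv = utils::read.delim(path, check.names = FALSE, colClasses = "character",
                            na.strings = character(0)),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop_es("reading xlsx requires the 'readxl' package")
      }
      x <- readxl::read_excel(path, sheet = 1, col_types = "text")
      as.data.frame(x, stringsAsFactors = FALSE)
    })
  out <- as_es_dataset(raw)
  viol <- validate_dataset(out)
  if (nrow(viol)) {
    warn_es("%d schema violation(s) in %d row(s); first: row %d, %s",
            nrow(viol), length(unique(viol$row)), viol$row[1L], viol$violation[1L])
    attr(out, "violations") <- viol
  }
  out
}

#' Write a dataset or template to disk
#'
#' @param x A data.frame (dataset or template).
#' @param path Output path; extension picks the dialect unless given.
#' @param dialect "auto", "csv" or "tsv". XLSX output is not supported; write
#'   CSV and convert externally if a spreadsheet is required.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(x, path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- infer_dialect(path)
    if (dialect == "xlsx") {
      stop_es("writing xlsx is not supported; use csv or tsv")
    }
  }
  df <- as.data.frame(x)
  if (dialect == "csv") {
    utils::write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  } else {
    utils::write.table(df, path, sep = "\t", row.names = FALSE, na = "",
                       quote = TRUE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

# ---- template generation ----------------------------------------------------

#' Generate an empty data-extraction template
#'
#' Builds an empty sheet whose header is the union of every column needed by
#' any input route able to produce one of the requested measures; the first
#' (and only) row carries the per-column description. Delete that row before
#' filling the sheet in.
#'
#' @param measures Character vector of measure codes (see [es_measures()]).
#' @param path Optional output path (csv/tsv); when NULL nothing is written.
#' @param dialect Passed to [write_dataset()].
#' @return Invisibly, a data.frame of class `es_template` (columns = template
#'   header, single description row) with attribute `measures`.
#' @export
#' @examples
#' tpl <- make_template("IRR")
#' names(tpl)   # study_id, es_direction, e1, time1, e2, time2
make_template <- function(measures, path = NULL, dialect = c("auto", "csv", "tsv")) {
  if (length(measures) == 0) {
    stop_es("no measures requested; valid codes: %s",
            paste(es_measures(), collapse = ", "))
  }
  bad <- setdiff(measures, es_measures())
  if (length(bad)) {
    stop_es("unknown measure code(s): %s; valid codes: %s",
            paste(bad, collapse = ", "), paste(es_measures(), collapse = ", "))
  }
  reg <- registry_entries()
  needed <- unique(unlist(lapply(reg, function(e) {
    if (e$measure %in% measures) e$needs else NULL
  })))
  needed <- setdiff(needed, "es_direction")
  schema <- es_schema()
  cols <- c("study_id", "es_direction",
            schema$name[schema$name %in% needed & !schema$name %in%
                          c("study_id", "es_direction")])
  desc <- schema$description[match(cols, schema$name)]
  tpl <- as.data.frame(setNames(as.list(desc), cols), check.names = FALSE,
                       stringsAsFactors = FALSE)
  class(tpl) <- c("es_template", "data.frame")
  attr(tpl, "measures") <- measures
  if (!is.null(path)) write_dataset(tpl, path, dialect)
  invisible(tpl)
}

# ---- validation -------------------------------------------------------------

range_check <- function(type, v) {
  switch(type,
    count    = if (v < 0 || v != floor(v)) "must be a non-negative integer",
    pos      = if (v <= 0) "must be strictly positive",
    nonneg   = if (v < 0) "must be non-negative",
    p_open   = if (v <= 0 || v > 1) "must lie in (0, 1]",
    unit_co  = if (v < 0 || v >= 1) "must lie in [0, 1)",
    corr     = if (v <= -1 || v >= 1) "must lie in (-1, 1)",
    prob     = if (v < 0 || v > 1) "must lie in [0, 1]",
    prob_open= if (v <= 0 || v >= 1) "must lie in (0, 1)",
    NULL)
}

CI_PAIRS <- list(c("m1_ci_lo", "m1_ci_up"), c("m2_ci_lo", "m2_ci_up"),
                 c("md_ci_lo", "md_ci_up"), c("or_ci_lo", "or_ci_up"),
                 c("rr_ci_lo", "rr_ci_up"))

#' Validate one dataset row against the schema invariants
#'
#' Checks field ranges (counts integral and non-negative, SDs/SEs positive,
#' probabilities and correlations in range), CI bound ordering, quantile
#' ordering (min <= q1 <= median <= q3 <= max per group), and the 2x2/group
#' size consistency a+b = n1, c+d_cell = n2 when both representations are
#' present. Violations are returned as data, never raised; an empty character
#' vector means the row is clean. A fully blank row has no violations.
#'
#' @param row A single-row `es_dataset` (or coercible list).
#' @return Character vector of violation messages, each naming the field.
#' @export
validate_row <- function(row) {
  if (is.data.frame(row)) {
    stopifnot(nrow(row) == 1L)
    row <- as.list(row)
  }
  schema <- es_schema()
  out <- character(0)
  for (k in seq_len(nrow(schema))) {
    col <- schema$name[k]; type <- schema$type[k]
    if (type %in% c("text", "direction")) next
    v <- row[[col]]
    if (is.null(v) || length(v) == 0L || is.na(v)) next
    msg <- range_check(type, v)
    if (!is.null(msg)) out <- c(out, sprintf("%s %s (got %s)", col, msg, format(v)))
  }
  for (pr in CI_PAIRS) {
    if (has_val(row, pr) && num1(row, pr[1]) >= num1(row, pr[2])) {
      out <- c(out, sprintf("%s must be < %s", pr[1], pr[2]))
    }
  }
  for (g in 1:2) {
    q <- c(paste0("min", g), paste0("q1_", g), paste0("med", g),
           paste0("q3_", g), paste0("max", g))
    vals <- vapply(q, function(cl) num1(row, cl), numeric(1))
    prov <- which(!is.na(vals))
    if (length(prov) >= 2 && any(diff(vals[prov]) < 0)) {
      out <- c(out, sprintf("group-%d quantiles out of order (min <= q1 <= med <= q3 <= max)", g))
    }
  }
  if (has_val(row, c("a", "b", "n1")) && num1(row, "a") + num1(row, "b") != num1(row, "n1")) {
    out <- c(out, "a + b must equal n1")
  }
  if (has_val(row, c("c", "d_cell", "n2")) &&
      num1(row, "c") + num1(row, "d_cell") != num1(row, "n2")) {
    out <- c(out, "c + d_cell must equal n2")
  }
  out
}

#' Validate every row of a dataset
#'
#' @param data An `es_dataset` (or coercible data.frame).
#' @return A data.frame with columns `row` and `violation` (0 rows if clean).
#' @export
validate_dataset <- function(data) {
  if (!inherits(data, "es_dataset")) data <- as_es_dataset(data)
  res <- lapply(seq_len(nrow(data)), function(i) {
    v <- validate_row(data[i, , drop = FALSE])
    if (length(v)) data.frame(row = i, violation = v, stringsAsFactors = FALSE)
    else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(row = integer(0), violation = character(0))
  out
}
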