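# Cell-level diff of two data-extraction datasets after key-based row
# alignment, for reconciling independent double extraction.

#' Compare two extraction datasets
#'
#' Aligns the rows of `a` and `b` on the key columns (so differing row order
#' or row count between extractors is handled), then compares every shared
#' column cell by cell. Numeric-looking cells are compared after parsing (so
#' "2.0" equals "2") with optional absolute tolerance; other cells are
#' compared as whitespace-trimmed text. Only differences are reported.
#'
#' @param a,b Two data.frames (or file paths accepted by [read_dataset()]
#'   when they follow the schema; arbitrary tables are fine too).
#' @param key_cols Columns identifying a row, e.g. `c("study_id",
#'   "outcome")`. Key values must be unique within each table.
#' @param tol Absolute tolerance for numeric cells; default 0 (extraction
#'   values should match exactly).
#' @return A list of class `es_diff`: `diffs` (one row per differing cell:
#'   key columns, `column`, `value_a`, `value_b`), `only_in_a` / `only_in_b`
#'   (key tuples present in one table only), `columns_compared`, `rows_a`,
#'   `rows_b` (the differing rows, for rendering), and `summary` counts.
#'   Identical datasets give an empty report.
#' @export
#' @examples
#' a <- data.frame(study_id = c("s1", "s2"), or_value = c(2.1, 1.4))
#' b <- data.frame(study_id = c("s2", "s1"), or_value = c(1.4, 3.1))
#' compare_datasets(a, b, key_cols = "study_id")$diffs
compare_datasets <- function(a, b, key_cols, tol = 0) {
  load_tab <- function(x) {
    if (is.character(x) && length(x) == 1L) x <- read_dataset(x)
    df <- as.data.frame(x, stringsAsFactors = FALSE)
    df[] <- lapply(df, as.character)
    df
  }
  A <- load_tab(a)
  B <- load_tab(b)
  for (k in key_cols) {
    if (!k %in% names(A) || !k %in% names(B)) {
      stop_es("key column '%s' must exist in both datasets", k)
    }
  }
  key_of <- function(df) do.call(paste, c(df[key_cols], sep = "\r"))
  ka <- key_of(A); kb <- key_of(B)
  for (side in list(list(k = ka, lab = "A"), list(k = kb, lab = "B"))) {
    dup <- unique(side$k[duplicated(side$k)])
    if (length(dup)) {
      stop_es("duplicate key(s) in dataset %s: %s", side$lab,
              paste(gsub("\r", " / ", dup), collapse = "; "))
    }
  }
  cols <- setdiff(intersect(names(A), names(B)), key_cols)
  dropped <- setdiff(union(names(A), names(B)), c(cols, key_cols))
  if (length(dropped)) {
    warn_es("column(s) absent from one dataset, compared on the intersection: %s",
            paste(dropped, collapse = ", "))
  }

  common <- intersect(ka, kb)
  only_a <- A[!(ka %in% kb), key_cols, drop = FALSE]
  only_b <- B[!(kb %in% ka), key_cols, drop = FALSE]

  cells_differ <- function(x, y) {
    x <- trimws(x); y <- trimws(y)
    xna <- is.na(x) | x == ""; yna <- is.na(y) | y == ""
    if (xna && yna) return(FALSE)
    if (xna != yna) return(TRUE)
    xn <- suppressWarnings(as.numeric(x))
    yn <- suppressWarnings(as.numeric(y))
    if (!is.na(xn) && !is.na(yn)) return(abs(xn - yn) > tol)
    !identical(x, y)
  }

  diffs <- list()
  diff_keys <- character(0)
  for (k in common) {
    ra <- A[match(k, ka), , drop = FALSE]
    rb <- B[match(k, kb), , drop = FALSE]
    for (cl in cols) {
      if (cells_differ(ra[[cl]], rb[[cl]])) {
        rec <- ra[, key_cols, drop = FALSE]
        rec$column <- cl
        rec$value_a <- ra[[cl]]
        rec$value_b <- rb[[cl]]
        diffs[[length(diffs) + 1L]] <- rec
        diff_keys <- union(diff_keys, k)
      }
    }
  }
  diffs <- if (length(diffs)) do.call(rbind, diffs)
           else {
             empty <- A[0, key_cols, drop = FALSE]
             empty$column <- character(0)
             empty$value_a <- character(0)
             empty$value_b <- character(0)
             empty
           }
  rownames(diffs) <- NULL
  structure(list(
    diffs = diffs,
    only_in_a = only_a,
    only_in_b = only_b,
    columns_compared = cols,
    key_cols = key_cols,
    rows_a = A[ka %in% diff_keys, c(key_cols, cols), drop = FALSE],
    rows_b = B[kb %in% diff_keys, c(key_cols, cols), drop = FALSE],
    summary = c(n_diff_cells = nrow(diffs),
                n_diff_rows = length(diff_keys),
                n_only_in_a = nrow(only_a),
                n_only_in_b = nrow(only_b))
  ), class = "es_diff")
}

#' @export
print.es_diff <- function(x, ...) {
  s <- x$summary
  if (sum(s) == 0) {
    cat("No differences: the two datasets agree on every compared cell.\n")
    return(invisible(x))
  }
  cat(sprintf("Dataset comparison: %d differing cell(s) in %d row(s); %d row(s) only in A, %d only in B\n",
              s[["n_diff_cells"]], s[["n_diff_rows"]],
              s[["n_only_in_a"]], s[["n_only_in_b"]]))
  if (nrow(x$diffs)) {
    cat("\nDiffering cells:\n")
    print.data.frame(x$diffs, row.names = FALSE)
  }
  if (nrow(x$only_in_a)) {
    cat("\nRows only in A:\n"); print.data.frame(x$only_in_a, row.names = FALSE)
  }
  if (nrow(x$only_in_b)) {
    cat("\nRows only in B:\n"); print.data.frame(x$only_in_b, row.names = FALSE)
  }
  invisible(x)
}

#' Write a dataset comparison report
#'
#' Renders an [compare_datasets()] result as csv (the differing-cell table),
#' txt (the printed report) or a small self-contained html page showing the
#' aligned differing rows with unchanged cells in grey and discrepant cells
#' highlighted.
#'
#' @param x An `es_diff` object.
#' @param path Output path; the extension picks the format unless given.
#' @param format "auto", "csv", "txt" or "html".
#' @return `path`, invisibly.
#' @export
write_diff <- function(x, path, format = c("auto", "csv", "txt", "html")) {
  stopifnot(inherits(x, "es_diff"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", txt = "txt", html = "html",
                     xlsx = stop_es("writing xlsx is not supported; use csv, txt or html"),
                     stop_es("cannot infer report format from '%s'", path))
  }
  if (format == "csv") {
    utils::write.csv(x$diffs, path, row.names = FALSE, na = "")
  } else if (format == "txt") {
    writeLines(utils::capture.output(print(x)), path)
  } else {
    writeLines(render_diff_html(x), path)
  }
  invisible(path)
}

esc_html <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

render_diff_html <- function(x) {
  cols <- c(x$key_cols, x$columns_compared)
  key_of <- function(df) do.call(paste, c(df[x$key_cols], sep = "\r"))
  ka <- key_of(x$rows_a); kb <- key_of(x$rows_b)
  diff_cols_for <- function(k) {
    dk <- key_of(x$diffs)
    x$diffs$column[dk == k]
  }
  body <- c()
  for (k in intersect(ka, kb)) {
    ra <- x$rows_a[match(k, ka), , drop = FALSE]
    rb <- x$rows_b[match(k, kb), , drop = FALSE]
    dc <- diff_cols_for(k)
    cell <- function(row, cl, side) {
      cls <- if (cl %in% dc) paste0("diff ", side) else "same"
      sprintf('<td class="%s">%s</td>', cls,
              esc_html(ifelse(is.na(row[[cl]]), "", row[[cl]])))
    }
    body <- c(body,
      paste0("<tr><td>A</td>",
             paste(vapply(cols, function(cl) cell(ra, cl, "a"), ""),
                   collapse = ""), "</tr>"),
      paste0("<tr><td>B</td>",
             paste(vapply(cols, function(cl) cell(rb, cl, "b"), ""),
                   collapse = ""), "</tr>"))
  }
  c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<style>",
    "table{border-collapse:collapse;font-family:sans-serif;font-size:13px}",
    "td,th{border:1px solid #ccc;padding:3px 7px}",
    "td.same{color:#999}",
    "td.diff.a{background:#fde2e2;color:#a00;font-weight:bold}",
    "td.diff.b{background:#e2ecfd;color:#04a;font-weight:bold}",
    "</style></head><body>",
    sprintf("<p>%d differing cell(s) in %d row pair(s); %d row(s) only in A, %d only in B.</p>",
            x$summary[["n_diff_cells"]], x$summary[["n_diff_rows"]],
            x$summary[["n_only_in_a"]], x$summary[["n_only_in_b"]]),
    "<table>",
    paste0("<tr><th>set</th>",
           paste(sprintf("<th>%s</th>", esc_html(cols)), collapse = ""),
           "</tr>"),
    body,
    "</table></body></html>")
}
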