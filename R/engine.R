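# Per-row orchestration: route detection, candidate computation, selection of
# the main estimate, and the dataset-level convert_df() driver.

#' Engine options
#'
#' Bundles the tunable choices of the conversion engine: which method to use
#' for multi-method conversions and how consistency flags are raised.
#'
#' @param d_to_or Method converting d to lnOR: "hh" (Hasselblad-Hedges,
#'   default) or "cox".
#' @param or_to_rr One of [es_or_to_rr_methods()]; default "zhang_yu".
#' @param or_to_r "via_d_hh" (default), "via_d_cox" or "tetrachoric_approx".
#' @param overlap_denominator "shorter" (default: the shorter interval's
#'   width, so containment reads 100%) or "union".
#' @param sign_flip_tol Relative tolerance for the equal-magnitude,
#'   opposite-sign flag; default 0.01.
#' @param overlap_flag_threshold CI-overlap percentage below which the
#'   large-divergence flag is raised; default 25.
#' @param diff_flag_threshold Absolute difference (comparison scale) above
#'   which the large-divergence flag is raised; default Inf (disabled).
#' @param median_baseline Dataset-level median baseline risk, filled in by
#'   [convert_df()]; used by the "zhang_yu_median" OR-to-RR method.
#' @return A list of class `es_options`.
#' @export
es_options <- function(d_to_or = c("hh", "cox"),
                       or_to_rr = es_or_to_rr_methods(),
                       or_to_r = c("via_d_hh", "via_d_cox", "tetrachoric_approx"),
                       overlap_denominator = c("shorter", "union"),
                       sign_flip_tol = 0.01,
                       overlap_flag_threshold = 25,
                       diff_flag_threshold = Inf,
                       median_baseline = NULL) {
  structure(list(
    d_to_or = match.arg(d_to_or),
    or_to_rr = match.arg(or_to_rr),
    or_to_r = match.arg(or_to_r),
    overlap_denominator = match.arg(overlap_denominator),
    sign_flip_tol = sign_flip_tol,
    overlap_flag_threshold = overlap_flag_threshold,
    diff_flag_threshold = diff_flag_threshold,
    median_baseline = median_baseline
  ), class = "es_options")
}

need_satisfied <- function(row, need) {
  if (need == "es_direction") {
    isTRUE(row$es_direction %in% c("positive", "negative"))
  } else {
    has_val(row, need)
  }
}

route_applicable <- function(row, needs) {
  all(vapply(needs, function(nd) need_satisfied(row, nd), logical(1)))
}

# pick one registry entry per route: the ctx-selected method for multi-method
# groups, else the single (or first) entry
pick_entry <- function(group, ctx) {
  if (length(group) == 1L) return(group[[1L]])
  methods <- vapply(group, function(e) e$method, character(1))
  want <- if (all(methods %in% es_or_to_rr_methods())) ctx$or_to_rr
          else if (all(methods %in% c("hh", "cox"))) ctx$d_to_or
          else if (all(methods %in% c("via_d_hh", "via_d_cox", "tetrachoric_approx"))) ctx$or_to_r
          else NA_character_
  hit <- which(methods == want)
  group[[if (length(hit)) hit[1L] else 1L]]
}

#' Enumerate every computable candidate effect size for one row
#'
#' Walks the registry for the requested measure and computes one candidate
#' per applicable route, in registry (priority) order. Route-level formula
#' failures never abort the row: they are captured as notes, and the route
#' still counts as available. Rows with no applicable route yield an empty
#' candidate set with an explanatory note.
#'
#' @param row A single-row `es_dataset` (or coercible list).
#' @param measure A measure code (see [es_measures()]).
#' @param ctx Engine options from [es_options()].
#' @return A list of class `es_candidates`: `measure`, `candidates` (list of
#'   [es_estimate()]), `routes_available`, `notes`, plus selection fields
#'   filled in by [select_main()] (`selected`, `route_used`, `strategy`).
#' @export
enumerate_candidates <- function(row, measure, ctx = es_options()) {
  measure <- match.arg(measure, es_measures())
  if (is.data.frame(row)) {
    stopifnot(nrow(row) == 1L)
    row <- as.list(row)
  }
  E <- registry_entries()
  E <- E[vapply(E, function(e) e$measure == measure, logical(1))]
  routes <- unique(vapply(E, function(e) e$route, character(1)))

  candidates <- list()
  available <- character(0)
  notes <- character(0)
  for (rt in routes) {
    group <- E[vapply(E, function(e) e$route == rt, logical(1))]
    entry <- pick_entry(group, ctx)
    if (!route_applicable(row, entry$needs)) {
      # a test-statistic route blocked only by a missing direction deserves a
      # pointer rather than silence
      rest <- setdiff(entry$needs, "es_direction")
      if ("es_direction" %in% entry$needs && route_applicable(row, rest)) {
        notes <- c(notes, sprintf(
          "route %s: direction required (es_direction is unspecified)", rt))
      }
      next
    }
    available <- c(available, rt)
    est <- tryCatch(entry$fn(row, ctx), error = function(e) {
      notes <<- c(notes, sprintf("route %s: %s", rt, conditionMessage(e)))
      NULL
    })
    if (!is.null(est)) candidates[[length(candidates) + 1L]] <- est
  }
  if (length(available) == 0L) {
    notes <- c(notes, "no applicable input data")
  }
  structure(list(measure = measure, candidates = candidates,
                 routes_available = available, notes = notes,
                 selected = NULL, route_used = NA_character_,
                 strategy = NA_character_),
            class = "es_candidates")
}

#' Parse a hierarchy specification
#'
#' Accepts either a character vector of route ids or a single
#' `"means_sd > t > p"` style string. Duplicates and unregistered route ids
#' are errors.
#'
#' @param x Hierarchy specification.
#' @return Character vector of route ids, highest priority first.
#' @export
parse_hierarchy <- function(x) {
  if (length(x) == 1L && grepl(">", x, fixed = TRUE)) {
    x <- trimws(strsplit(x, ">", fixed = TRUE)[[1L]])
  }
  x <- as.character(x)
  if (anyDuplicated(x)) {
    stop_es("duplicate routes in hierarchy: %s",
            paste(unique(x[duplicated(x)]), collapse = ", "))
  }
  unknown <- setdiff(x, es_routes())
  if (length(unknown)) {
    stop_es("unknown route(s) in hierarchy: %s", paste(unknown, collapse = ", "))
  }
  x
}

#' Select the main effect size from a candidate set
#'
#' Three approaches: a user hierarchy (`strategy = "hierarchy"`; the first
#' candidate whose route appears earliest in the hierarchy wins), the shipped
#' pre-defined hierarchy for the measure (`"auto"`), or the extreme candidate
#' (`"smallest"` / `"largest"`: minimum / maximum absolute deviation from the
#' null on the comparison scale - 0 for D/G/MD/Z and Fisher-z of R, log 1 for
#' ratio measures, risk difference 0 for NNT - which makes the sensitivity
#' analysis meaningful for negative effects). Ties break by registry order. A
#' hierarchy covering none of the available routes falls back to "auto" with
#' a warning.
#'
#' @param cs An `es_candidates` object from [enumerate_candidates()].
#' @param strategy "auto", "hierarchy", "smallest" or "largest".
#' @param hierarchy Required when `strategy = "hierarchy"`; see
#'   [parse_hierarchy()].
#' @return The candidate set with `selected`, `route_used` and `strategy`
#'   filled in.
#' @export
select_main <- function(cs, strategy = c("auto", "hierarchy", "smallest", "largest"),
                        hierarchy = NULL) {
  stopifnot(inherits(cs, "es_candidates"))
  strategy <- match.arg(strategy)
  cs$strategy <- strategy
  if (length(cs$candidates) == 0L) return(cs)
  routes <- vapply(cs$candidates, function(e) e$route, character(1))

  idx <- switch(strategy,
    hierarchy = {
      if (is.null(hierarchy)) stop_es("strategy 'hierarchy' requires a hierarchy")
      h <- parse_hierarchy(hierarchy)
      pos <- match(routes, h)
      if (all(is.na(pos))) {
        warn_es("hierarchy (%s) covers none of the available routes (%s); falling back to the pre-defined hierarchy",
                paste(h, collapse = " > "), paste(routes, collapse = ", "))
        pos <- match(routes, es_default_hierarchy(cs$measure))
      }
      which.min(pos)  # NA ranks last; ties by candidate (registry) order
    },
    auto = {
      pos <- match(routes, es_default_hierarchy(cs$measure))
      which.min(pos)
    },
    smallest = ,
    largest = {
      dev <- abs(vapply(cs$candidates, es_comp_value, numeric(1)))
      if (strategy == "smallest") which.min(dev) else which.max(dev)
    })
  cs$selected <- cs$candidates[[idx]]
  cs$route_used <- cs$selected$route
  cs
}

#' @export
print.es_candidates <- function(x, ...) {
  cat(sprintf("Candidate %s estimates (%d route(s) available)\n",
              x$measure, length(x$routes_available)))
  for (est in x$candidates) {
    sel <- if (!is.null(x$selected) && identical(est, x$selected)) " [selected]" else ""
    cat(sprintf("  %-14s %s = %8.4f  se = %.4f%s\n", est$route, est$measure,
                est$value, est$se, sel))
  }
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}

dataset_median_baseline <- function(data) {
  p0 <- c(data$baseline_risk,
          data$p_event2,
          data$c / (data$c + data$d_cell))
  p0 <- p0[is.finite(p0) & p0 > 0 & p0 < 1]
  if (length(p0)) stats::median(p0) else NULL
}

#' Convert a dataset into effect sizes
#'
#' The core driver: for every row of a schema-shaped dataset it enumerates
#' all candidate estimates of `measure` from every applicable input route,
#' selects a main estimate, and - when two or more candidates overlap -
#' appends the five consistency indicators and any discrepancy flags. Rows
#' are processed independently in input order; per-row problems become notes
#' in the output, never errors.
#'
#' @param data An `es_dataset`, a data.frame coercible to one, or a file path
#'   accepted by [read_dataset()].
#' @param measure The effect size measure to estimate (see [es_measures()]).
#' @param es_selected Selection strategy: "auto" (pre-defined hierarchy,
#'   default), "hierarchy" (supply `hierarchy`), "smallest" or "largest".
#' @param hierarchy Route priority for `es_selected = "hierarchy"`, e.g.
#'   `"means_sd > t > p"`.
#' @param options Engine options from [es_options()].
#' @return A data.frame of class `es_converted`, one row per input row, with
#'   columns `study_id`, `measure`, `value`, `se`, `ci_lo`, `ci_up`, `scale`,
#'   `route_used`, `method_used`, `n_candidates`, `routes_available`
#'   (semicolon-joined), the consistency columns `es_min`, `es_max`,
#'   `es_diff`, `es_sd`, `ci_overlap_pct` (comparison scale; NA unless >= 2
#'   candidates), `flags` and `note`. The per-row candidate sets are attached
#'   as attribute `"candidates"`.
#' @export
#' @examples
#' df <- data.frame(study_id = "s1", n1 = 50, n2 = 50,
#'                  m1 = 103, m2 = 100, sd1 = 10, sd2 = 10)
#' convert_df(df, "G")
convert_df <- function(data, measure,
                       es_selected = c("auto", "hierarchy", "smallest", "largest"),
                       hierarchy = NULL, options = es_options()) {
  es_selected <- match.arg(es_selected)
  if (is.character(data) && length(data) == 1L) data <- read_dataset(data)
  if (!inherits(data, "es_dataset")) data <- as_es_dataset(data)
  measure <- match.arg(measure, es_measures())
  options$median_baseline <- options$median_baseline %||%
    dataset_median_baseline(data)

  n <- nrow(data)
  all_cs <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    row <- as.list(data[i, , drop = FALSE])
    viol <- validate_row(row)
    cs <- enumerate_candidates(row, measure, options)
    cs <- select_main(cs, es_selected, hierarchy)
    rep_ <- consistency_indicators(cs, denominator = options$overlap_denominator)
    flags <- if (!is.null(rep_)) {
      flag_discrepancies(cs, rep_, tol = options$sign_flip_tol,
                         overlap_threshold = options$overlap_flag_threshold,
                         diff_threshold = options$diff_flag_threshold)
    } else character(0)
    sel <- cs$selected
    notes <- c(if (length(viol)) paste("validation:", viol), cs$notes)
    rows[[i]] <- data.frame(
      study_id = row$study_id %||% NA_character_,
      measure = measure,
      value = if (!is.null(sel)) sel$value else NA_real_,
      se = if (!is.null(sel)) sel$se else NA_real_,
      ci_lo = if (!is.null(sel)) sel$ci_lo else NA_real_,
      ci_up = if (!is.null(sel)) sel$ci_up else NA_real_,
      scale = if (!is.null(sel)) sel$scale else NA_character_,
      route_used = cs$route_used,
      method_used = if (!is.null(sel)) sel$method else NA_character_,
      n_candidates = length(cs$candidates),
      routes_available = paste(cs$routes_available, collapse = ";"),
      es_min = if (!is.null(rep_)) rep_$es_min else NA_real_,
      es_max = if (!is.null(rep_)) rep_$es_max else NA_real_,
      es_diff = if (!is.null(rep_)) rep_$es_diff else NA_real_,
      es_sd = if (!is.null(rep_)) rep_$es_sd else NA_real_,
      ci_overlap_pct = if (!is.null(rep_)) rep_$ci_overlap_pct else NA_real_,
      flags = paste(flags, collapse = ";"),
      note = paste(notes, collapse = "; "),
      stringsAsFactors = FALSE)
    all_cs[[i]] <- cs
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("es_converted", "data.frame")
  attr(out, "measure") <- measure
  attr(out, "es_selected") <- es_selected
  attr(out, "candidates") <- all_cs
  no_est <- which(is.na(out$value))
  if (length(no_est)) {
    message(sprintf("no %s estimate for %d row(s): %s", measure,
                    length(no_est), paste(no_est, collapse = ", ")))
  }
  out
}

#' @export
print.es_converted <- function(x, digits = 4, ...) {
  cat(sprintf("Effect size conversion: measure %s, %d row(s), selection '%s'\n\n",
              attr(x, "measure"), nrow(x), attr(x, "es_selected")))
  show <- intersect(c("study_id", "value", "se", "ci_lo", "ci_up", "route_used",
                      "n_candidates", "ci_overlap_pct", "flags"), names(x))
  df <- as.data.frame(x)[, show, drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print.data.frame(df, row.names = TRUE)
  invisible(x)
}

#' @export
summary.es_converted <- function(object, ...) {
  df <- as.data.frame(object)
  cat(sprintf("measure: %s; rows: %d; with estimate: %d\n",
              attr(object, "measure"), nrow(df), sum(!is.na(df$value))))
  cat("routes used:\n")
  print(table(df$route_used, useNA = "ifany"))
  multi <- df[df$n_candidates >= 2, , drop = FALSE]
  if (nrow(multi)) {
    cat(sprintf("rows with overlapping inputs: %d; median CI overlap %.1f%%\n",
                nrow(multi), stats::median(multi$ci_overlap_pct, na.rm = TRUE)))
    flagged <- multi[nzchar(multi$flags), , drop = FALSE]
    if (nrow(flagged)) {
      cat(sprintf("flagged rows: %s\n",
                  paste(rownames(flagged), collapse = ", ")))
    }
  }
  invisible(object)
}
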