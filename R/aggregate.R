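# Collapse dependent effect sizes within a cluster into one independent
# estimate: correlation-aware composites for same-participant dependence,
# inverse-variance pooling for independent subgroups.

# Borenstein-style composite of m correlated estimates sharing correlation r:
# mean of the y's; Var = (1/m^2) [sum V_i + r * sum_{i != j} sqrt(V_i V_j)]
composite_es <- function(y, v, r) {
  m <- length(y)
  sqv <- sqrt(v)
  cross <- sum(sqv)^2 - sum(v)
  list(value = mean(y), var = (sum(v) + r * cross) / m^2)
}

pool_fixed <- function(y, v) {
  w <- 1 / v
  list(value = sum(w * y) / sum(w), var = 1 / sum(w))
}

to_transform_scale <- function(value, measure) {
  if (measure %in% RATIO_MEASURES) log(value)
  else if (measure == "R") atanh(value)
  else value
}

#' Aggregate dependent effect size estimates from one cluster
#'
#' Three dependence modes. `"outcomes"` (several measures of the same outcome
#' on the same participants) and `"times"` (the same outcome at several time
#' points) share the correlated-composite formula - the mean of the
#' estimates, with variance `(1/m^2) [sum(V_i) + r sum_{i!=j} sqrt(V_i V_j)]`
#' where `r` is the within-study correlation the user must supply (no silent
#' default); they differ only in what `r` means. `"subgroups"` (independent
#' participant subsets) uses inverse-variance pooling: `sum(w y)/sum(w)`,
#' `Var = 1/sum(w)`, `w = 1/V`. Ratio measures are aggregated on the log
#' scale, correlations on Fisher's z; singleton clusters pass through
#' unchanged.
#'
#' @param estimates List of [es_estimate()] objects, all of the same measure.
#' @param dependence One of [es_dependence_modes()].
#' @param r_dep Within-study correlation in `[0, 1]`; required for
#'   "outcomes" and "times", ignored for "subgroups".
#' @return A single `es_estimate` with route "aggregate" and the mode as
#'   method.
#' @export
#' @examples
#' e1 <- es_estimate("D", 0.4, 0.2, "means_sd")
#' e2 <- es_estimate("D", 0.4, 0.2, "means_sd")
#' aggregate_cluster(list(e1, e2), "outcomes", r_dep = 0.5)  # Var = 0.03
aggregate_cluster <- function(estimates, dependence = es_dependence_modes(),
                              r_dep = NULL) {
  dependence <- match.arg(dependence)
  stopifnot(length(estimates) >= 1L,
            all(vapply(estimates, inherits, logical(1), "es_estimate")))
  measures <- unique(vapply(estimates, function(e) e$measure, character(1)))
  if (length(measures) != 1L) {
    stop_es("mixed measures in one cluster: %s", paste(measures, collapse = ", "))
  }
  measure <- measures
  if (measure == "NNT") {
    stop_es("NNT estimates cannot be aggregated directly; aggregate the underlying risk differences")
  }
  if (length(estimates) == 1L) return(estimates[[1L]])
  y <- vapply(estimates, function(e) to_transform_scale(e$value, measure),
              numeric(1))
  v <- vapply(estimates, function(e) e$se^2, numeric(1))
  res <- if (dependence %in% c("outcomes", "times")) {
    if (is.null(r_dep) || is.na(r_dep)) {
      stop_es("dependence '%s' requires r_dep, the within-study correlation between the dependent estimates",
              dependence)
    }
    if (r_dep < 0 || r_dep > 1) stop_es("r_dep must lie in [0, 1]")
    composite_es(y, v, r_dep)
  } else {
    pool_fixed(y, v)
  }
  es_estimate(measure, res$value, sqrt(res$var), route = "aggregate",
              method = dependence,
              note = sprintf("aggregated %d dependent estimates", length(y)))
}

#' Aggregate dependent effect sizes in a results table
#'
#' Collapses each cluster of rows (typically a [convert_df()] output sharing
#' a `study_id`) into a single independent estimate via
#' [aggregate_cluster()]. Output rows appear in first-appearance order of the
#' clusters; non-effect columns are retained when constant within their
#' cluster and blanked (with one warning) otherwise.
#'
#' @param data A data.frame carrying the effect size columns and the cluster
#'   key.
#' @param dependence One of [es_dependence_modes()].
#' @param r_dep Within-study correlation for "outcomes"/"times".
#' @param agg_fact Name of the cluster-key column; default "study_id".
#' @param value_col,se_col,measure_col Column names of the estimate, its SE
#'   (transform scale) and its measure code.
#' @return A data.frame of class `es_aggregated`: `agg_fact`, `measure`,
#'   `value`, `se`, `ci_lo`, `ci_up`, `n_aggregated`, `dependence`, then any
#'   retained columns.
#' @export
aggregate_df <- function(data, dependence = es_dependence_modes(), r_dep = NULL,
                         agg_fact = "study_id", value_col = "value",
                         se_col = "se", measure_col = "measure") {
  dependence <- match.arg(dependence)
  df <- as.data.frame(data)
  if (!agg_fact %in% names(df)) {
    stop_es("cluster key column '%s' not found", agg_fact)
  }
  for (cl in c(value_col, se_col)) {
    if (!cl %in% names(df)) stop_es("column '%s' not found", cl)
  }
  keep <- !is.na(df[[value_col]]) & !is.na(df[[se_col]])
  if (!all(keep)) {
    warn_es("dropping %d row(s) without an estimate before aggregation",
            sum(!keep))
    df <- df[keep, , drop = FALSE]
  }
  clusters <- unique(df[[agg_fact]])
  extra_cols <- setdiff(names(df), c(agg_fact, value_col, se_col, measure_col,
                                     "ci_lo", "ci_up", "scale", "route_used",
                                     "method_used", "n_candidates",
                                     "routes_available", "es_min", "es_max",
                                     "es_diff", "es_sd", "ci_overlap_pct",
                                     "flags", "note"))
  blanked <- character(0)
  rows <- lapply(clusters, function(cl) {
    sub <- df[df[[agg_fact]] == cl, , drop = FALSE]
    measure <- if (measure_col %in% names(sub)) unique(sub[[measure_col]])
               else "D"
    if (length(measure) != 1L) {
      stop_es("cluster '%s' mixes measures: %s", cl,
              paste(measure, collapse = ", "))
    }
    ests <- lapply(seq_len(nrow(sub)), function(i) {
      es_estimate(measure, to_transform_scale(sub[[value_col]][i], measure),
                  sub[[se_col]][i], route = "input")
    })
    agg <- aggregate_cluster(ests, dependence, r_dep)
    out <- data.frame(cluster = cl, measure = measure, value = agg$value,
                      se = agg$se, ci_lo = agg$ci_lo, ci_up = agg$ci_up,
                      n_aggregated = nrow(sub), dependence = dependence,
                      stringsAsFactors = FALSE)
    names(out)[1L] <- agg_fact
    for (cl2 in extra_cols) {
      vals <- unique(sub[[cl2]])
      if (length(vals) == 1L) out[[cl2]] <- vals
      else {
        out[[cl2]] <- NA
        blanked <<- union(blanked, cl2)
      }
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (length(blanked)) {
    warn_es("column(s) not constant within cluster, blanked: %s",
            paste(blanked, collapse = ", "))
  }
  class(out) <- c("es_aggregated", "data.frame")
  attr(out, "dependence") <- dependence
  attr(out, "r_dep") <- r_dep
  out
}

#' @export
print.es_aggregated <- function(x, digits = 4, ...) {
  cat(sprintf("Aggregated effect sizes: %d cluster(s), dependence '%s'\n\n",
              nrow(x), attr(x, "dependence")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
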