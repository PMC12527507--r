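# Agreement among candidate effect sizes computed from overlapping inputs:
# five numeric indicators plus discrepancy flags.

#' Consistency indicators for overlapping input data
#'
#' For a candidate set with at least two estimates, computes on the common
#' comparison scale (identity for D/G/MD/Z, log for ratio measures, Fisher's
#' z for R, risk difference for NNT): (i) the smallest effect size, (ii) the
#' largest, (iii) their difference, (iv) the sample SD (n-1 denominator) of
#' all candidate values, and (v) the percentage of overlap between the 95%
#' CIs of the smallest and largest candidates,
#' `100 * max(0, min(up1, up2) - max(lo1, lo2)) / denom` where `denom` is the
#' shorter interval's width (default; containment reads 100%) or the width of
#' the union span.
#'
#' @param cs An `es_candidates` object.
#' @param denominator "shorter" (default) or "union".
#' @return A list of class `es_consistency` with fields `es_min`, `es_max`,
#'   `es_diff`, `es_sd`, `ci_overlap_pct`, `scale`, `n`; NULL when fewer than
#'   two candidates exist (the report is contractually absent, not zeroed).
#' @export
consistency_indicators <- function(cs, denominator = c("shorter", "union")) {
  stopifnot(inherits(cs, "es_candidates"))
  denominator <- match.arg(denominator)
  if (length(cs$candidates) < 2L) return(NULL)
  vals <- vapply(cs$candidates, es_comp_value, numeric(1))
  i_min <- which.min(vals)
  i_max <- which.max(vals)
  ci1 <- es_comp_ci(cs$candidates[[i_min]])
  ci2 <- es_comp_ci(cs$candidates[[i_max]])
  overlap <- ci_overlap_pct(ci1, ci2, denominator)
  scale_lab <- if (cs$measure %in% RATIO_MEASURES) "log"
               else if (cs$measure %in% c("R", "Z")) "fisher_z"
               else if (cs$measure == "NNT") "risk_difference"
               else "identity"
  structure(list(
    es_min = vals[i_min],
    es_max = vals[i_max],
    es_diff = vals[i_max] - vals[i_min],
    es_sd = stats::sd(vals),
    ci_overlap_pct = overlap,
    scale = scale_lab,
    n = length(vals)
  ), class = "es_consistency")
}

# overlap of two intervals as a percentage of the chosen denominator,
# bounded [0, 100]; symmetric in its arguments
ci_overlap_pct <- function(ci1, ci2, denominator = "shorter") {
  if (anyNA(c(ci1, ci2))) return(NA_real_)
  inter <- max(0, min(ci1[2], ci2[2]) - max(ci1[1], ci2[1]))
  w1 <- ci1[2] - ci1[1]
  w2 <- ci2[2] - ci2[1]
  denom <- if (denominator == "shorter") min(w1, w2)
           else max(ci1[2], ci2[2]) - min(ci1[1], ci2[1])
  if (denom <= 0) {
    # degenerate (zero-width) intervals: full overlap iff they coincide
    return(if (isTRUE(all.equal(ci1, ci2))) 100 else 0)
  }
  100 * min(1, inter / denom)
}

#' Flag discrepancies among overlapping candidates
#'
#' Two flags: `sign_flip` when two candidates have opposite signs but (near-)
#' equal magnitude on the comparison scale - `|x + y| <= tol * (|x| + |y|)` -
#' the signature of a forgotten direction reversal during extraction; and
#' `large_divergence` when the CI overlap drops below `overlap_threshold`
#' percent or the min-max difference exceeds `diff_threshold` (the signature
#' of a typo in one input).
#'
#' @param cs An `es_candidates` object.
#' @param report The matching [consistency_indicators()] result.
#' @param tol Relative tolerance of the sign-flip test; default 0.01.
#' @param overlap_threshold Percent overlap below which divergence is
#'   flagged; default 25.
#' @param diff_threshold Absolute comparison-scale difference above which
#'   divergence is flagged; default Inf (disabled).
#' @return Character vector, a subset of `c("sign_flip", "large_divergence")`.
#' @export
flag_discrepancies <- function(cs, report, tol = 0.01, overlap_threshold = 25,
                               diff_threshold = Inf) {
  stopifnot(inherits(cs, "es_candidates"))
  if (is.null(report)) return(character(0))
  vals <- vapply(cs$candidates, es_comp_value, numeric(1))
  flags <- character(0)
  n <- length(vals)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      x <- vals[i]; y <- vals[j]
      if (x * y < 0 && abs(x + y) <= tol * (abs(x) + abs(y))) {
        flags <- c(flags, "sign_flip")
        break
      }
    }
    if ("sign_flip" %in% flags) break
  }
  if ((!is.na(report$ci_overlap_pct) &&
       report$ci_overlap_pct < overlap_threshold) ||
      report$es_diff > diff_threshold) {
    flags <- c(flags, "large_divergence")
  }
  flags
}

#' @export
print.es_consistency <- function(x, digits = 4, ...) {
  cat(sprintf("Consistency of %d candidate effect sizes (%s scale)\n", x$n, x$scale))
  cat(sprintf("  smallest %.*f, largest %.*f, difference %.*f, sd %.*f\n",
              digits, x$es_min, digits, x$es_max, digits, x$es_diff,
              digits, x$es_sd))
  cat(sprintf("  95%% CI overlap (smallest vs largest): %.1f%%\n",
              x$ci_overlap_pct))
  invisible(x)
}
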