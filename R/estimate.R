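#' Effect size measures supported by the package
#'
#' The eleven measure codes understood throughout the package: Cohen's d (D),
#' Hedges' g (G), mean difference (MD), odds ratio (OR), risk ratio (RR),
#' incidence rate ratio (IRR), correlation coefficient (R), Fisher's r-to-z
#' transformed correlation (Z), variability ratio (VR), coefficient of
#' variation ratio (CVR), and number needed to treat (NNT).
#'
#' @return Character vector of the eleven measure codes.
#' @export
es_measures <- function() {
  c("D", "G", "MD", "OR", "RR", "IRR", "R", "Z", "VR", "CVR", "NNT")
}

RATIO_MEASURES <- c("OR", "RR", "IRR", "VR", "CVR")

# scale on which value +/- 1.96*se is formed
es_scale_for <- function(measure) {
  if (measure %in% RATIO_MEASURES) "log"
  else if (measure %in% c("R", "Z")) "fisher_z"
  else "identity"
}

#' Construct an effect size estimate
#'
#' The common container for a single computed effect size. `tval` and `se` are
#' given on the transform scale of the measure (log for ratio measures,
#' Fisher's z for R, identity otherwise); the stored point value and 95% CI
#' are back-transformed to the natural scale of the measure.
#'
#' @param measure One of [es_measures()].
#' @param tval Point estimate on the transform scale (e.g. log OR for OR).
#' @param se Standard error on the transform scale; must be finite, > 0.
#' @param route Identifier of the input-data combination used.
#' @param method Calculation method, for routes that register several.
#' @param df_like Degrees of freedom (or an analogue) when meaningful; used by
#'   the small-sample correction converting d to g.
#' @param note Optional free-text annotation (e.g. "approximation").
#'
#' @return An object of class `es_estimate`: a list with elements `measure`,
#'   `value`, `se`, `ci_lo`, `ci_up`, `scale`, `route`, `method`, `df_like`,
#'   `note`.
#' @export
#' @examples
#' es_estimate("OR", log(2.25), 0.41665, route = "2x2")
es_estimate <- function(measure, tval, se, route, method = NA_character_,
                        df_like = NA_real_, note = NA_character_) {
  measure <- match.arg(measure, es_measures())
  if (!is.finite(tval)) stop_es("non-finite effect size for measure %s", measure)
  if (!is.finite(se) || se <= 0) {
    stop_es("standard error must be finite and positive (measure %s, got %s)",
            measure, format(se))
  }
  scale <- es_scale_for(measure)
  lo <- tval - Z95 * se
  up <- tval + Z95 * se
  back <- switch(scale,
    log = exp,
    fisher_z = if (measure == "R") tanh else identity,
    identity = identity
  )
  structure(list(
    measure = measure,
    value = back(tval),
    se = se,
    ci_lo = back(lo),
    ci_up = back(up),
    scale = scale,
    route = route,
    method = method,
    df_like = df_like,
    note = note
  ), class = "es_estimate")
}

# NNT does not fit the symmetric-transform template: its point value is the
# reciprocal of an absolute risk difference (ARD) and its CI is obtained by
# transforming the ARD interval. `se` is stored on the ARD scale.
new_nnt <- function(ard, se_ard, route, method = NA_character_,
                    df_like = NA_real_, note = NA_character_) {
  if (!is.finite(ard) || ard == 0) {
    stop_es("infinite NNT: the two risks are equal (risk difference 0)")
  }
  if (!is.finite(se_ard) || se_ard <= 0) {
    stop_es("standard error of the risk difference must be positive")
  }
  blo <- ard - Z95 * se_ard
  bup <- ard + Z95 * se_ard
  if (sign(blo) == sign(bup) && blo != 0) {
    ci <- sort(1 / c(blo, bup))
    ci_note <- note
  } else {
    # ARD interval spans 0: the NNT interval is disjoint (runs through
    # infinity) and is reported as missing
    ci <- c(NA_real_, NA_real_)
    ci_note <- paste(stats::na.omit(c(note, "NNT CI undefined: risk-difference CI spans 0")),
                     collapse = "; ")
    if (identical(ci_note, "")) ci_note <- NA_character_
  }
  structure(list(
    measure = "NNT",
    value = 1 / ard,
    se = se_ard,
    ci_lo = ci[1L],
    ci_up = ci[2L],
    scale = "identity",
    route = route,
    method = method,
    df_like = df_like,
    note = ci_note
  ), class = "es_estimate")
}

#' Effect size on its comparison scale
#'
#' Candidate effect sizes computed from different input routes are compared,
#' and consistency indicators formed, on a common additive scale: identity for
#' D/G/MD/Z, log for ratio measures, Fisher's z (atanh) for R, and the
#' absolute risk difference (1/NNT) for NNT.
#'
#' @param est An `es_estimate`.
#' @return Numeric scalar on the comparison scale.
#' @export
es_comp_value <- function(est) {
  stopifnot(inherits(est, "es_estimate"))
  if (est$measure %in% RATIO_MEASURES) log(est$value)
  else if (est$measure == "R") atanh(est$value)
  else if (est$measure == "NNT") 1 / est$value
  else est$value
}

#' @rdname es_comp_value
#' @return For `es_comp_ci`, a numeric length-2 vector (lower, upper) of the
#'   95% CI mapped onto the comparison scale.
#' @export
es_comp_ci <- function(est) {
  stopifnot(inherits(est, "es_estimate"))
  ci <- c(est$ci_lo, est$ci_up)
  if (est$measure %in% RATIO_MEASURES) log(ci)
  else if (est$measure == "R") atanh(ci)
  else if (est$measure == "NNT") {
    if (anyNA(ci)) c(NA_real_, NA_real_) else sort(1 / ci)
  } else ci
}

#' @export
print.es_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("%s = %s", x$measure, format(round(x$value, digits))))
  if (!is.na(x$ci_lo)) {
    cat(sprintf(", 95%% CI [%s, %s]",
                format(round(x$ci_lo, digits)), format(round(x$ci_up, digits))))
  }
  cat(sprintf(", se = %s (%s scale)", format(round(x$se, digits)), x$scale))
  cat(sprintf("\n  route: %s", x$route))
  if (!is.na(x$method)) cat(sprintf("  method: %s", x$method))
  if (!is.na(x$note)) cat(sprintf("\n  note: %s", x$note))
  cat("\n")
  invisible(x)
}
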