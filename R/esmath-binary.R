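# Odds ratios, risk ratios, incidence rate ratios and numbers needed to
# treat, from counts, proportions, reported ratios and cross-measure
# conversions.

# Gart continuity correction: 0.5 added to all four cells iff any cell is 0
correct_2x2 <- function(a, b, c, d_cell) {
  cells <- c(a = a, b = b, c = c, d_cell = d_cell)
  if (any(cells < 0)) stop_es("2x2 cells must be non-negative")
  if (a + b <= 0 || c + d_cell <= 0) stop_es("each 2x2 margin must be positive")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  list(a = cells[["a"]], b = cells[["b"]], c = cells[["c"]],
       d_cell = cells[["d_cell"]], corrected = corrected)
}

#' Log odds ratio from a 2x2 table
#'
#' Cells follow the convention rows = groups (1 = exposed/treated), columns =
#' event/non-event: `a` group-1 events, `b` group-1 non-events, `c` group-2
#' events, `d_cell` group-2 non-events. `lnOR = ln(ad/(bc))` with
#' `SE = sqrt(1/a + 1/b + 1/c + 1/d)`; 0.5 is added to all four cells iff any
#' cell is zero.
#'
#' @param a,b,c,d_cell Cell counts.
#' @return An [es_estimate()] of measure OR (value on the OR scale, se on the
#'   log scale), route "2x2".
#' @export
#' @examples
#' logor_from_2x2(20, 80, 10, 90)   # OR = 2.25, se(lnOR) = 0.4167
logor_from_2x2 <- function(a, b, c, d_cell) {
  cc <- correct_2x2(a, b, c, d_cell)
  if (with(cc, a == 0 || b == 0 || c == 0 || d_cell == 0)) {
    stop_es("undefined effect: empty row or column in the 2x2 table")
  }
  lnor <- log(cc$a * cc$d_cell / (cc$b * cc$c))
  se <- sqrt(1 / cc$a + 1 / cc$b + 1 / cc$c + 1 / cc$d_cell)
  es_estimate("OR", lnor, se, route = "2x2",
              df_like = a + b + c + d_cell - 2,
              note = if (cc$corrected) "0.5 continuity correction applied" else NA_character_)
}

#' Log risk ratio from a 2x2 table
#'
#' `lnRR = ln((a/n1)/(c/n2))` with
#' `SE = sqrt(1/a - 1/n1 + 1/c - 1/n2)`, n1 = a+b, n2 = c+d. Zero cells
#' receive the same correction as [logor_from_2x2()].
#'
#' @inheritParams logor_from_2x2
#' @return An [es_estimate()] of measure RR, route "2x2".
#' @export
logrr_from_2x2 <- function(a, b, c, d_cell) {
  cc <- correct_2x2(a, b, c, d_cell)
  n1 <- cc$a + cc$b
  n2 <- cc$c + cc$d_cell
  if (cc$a == 0 || cc$c == 0) stop_es("undefined effect: no events in a group")
  lnrr <- log((cc$a / n1) / (cc$c / n2))
  se <- sqrt(1 / cc$a - 1 / n1 + 1 / cc$c - 1 / n2)
  es_estimate("RR", lnrr, se, route = "2x2",
              df_like = a + b + c + d_cell - 2,
              note = if (cc$corrected) "0.5 continuity correction applied" else NA_character_)
}

#' Log incidence rate ratio from event counts and person-time
#'
#' `lnIRR = ln((e1/time1)/(e2/time2))` with `SE = sqrt(1/e1 + 1/e2)`. If one
#' event count is zero (the other >= 1) it is replaced by 0.5; both zero is
#' undefined. Person-time units must match between groups (the package
#' cannot validate this).
#'
#' @param e1,e2 Event counts.
#' @param time1,time2 Person-time at risk, > 0.
#' @return An [es_estimate()] of measure IRR, route "rates".
#' @export
#' @examples
#' logirr_from_rates(30, 100, 20, 100)  # IRR = 1.5, se = 0.2887
logirr_from_rates <- function(e1, time1, e2, time2) {
  if (time1 <= 0 || time2 <= 0) stop_es("person-time must be strictly positive")
  if (e1 < 0 || e2 < 0) stop_es("event counts must be non-negative")
  if (e1 == 0 && e2 == 0) stop_es("undefined effect: no events in either group")
  corrected <- e1 == 0 || e2 == 0
  if (e1 == 0) e1 <- 0.5
  if (e2 == 0) e2 <- 0.5
  lnirr <- log((e1 / time1) / (e2 / time2))
  se <- sqrt(1 / e1 + 1 / e2)
  es_estimate("IRR", lnirr, se, route = "rates",
              note = if (corrected) "0.5 continuity correction applied" else NA_character_)
}

#' Ratio measure from a reported estimate with precision
#'
#' Rebuilds the log-scale SE of a reported OR, RR or IRR from its 95% CI as
#' `(ln upper - ln lower) / (2 * 1.96)`, or accepts a reported log value with
#' its SE directly.
#'
#' @param value Reported ratio (> 0), with `ci_lo`/`ci_up` its CI bounds. The
#'   CI must contain the point estimate.
#' @param log_value,log_se Alternatively the reported log ratio and its SE
#'   (route "logor_se"; only ORs are reported this way in the schema).
#' @param which "OR", "RR" or "IRR".
#' @return An [es_estimate()] with route "or_ci", "rr_ci", "irr_ci" or
#'   "logor_se".
#' @export
#' @examples
#' ratio_from_reported(2.25, 0.9937, 5.0945, which = "OR")
ratio_from_reported <- function(value = NULL, ci_lo = NULL, ci_up = NULL,
                                log_value = NULL, log_se = NULL,
                                which = c("OR", "RR", "IRR")) {
  which <- match.arg(which)
  if (!is.null(log_value)) {
    if (is.null(log_se) || log_se <= 0) stop_es("log_se must be positive")
    return(es_estimate(which, log_value, log_se, route = "logor_se"))
  }
  if (is.null(value) || is.null(ci_lo) || is.null(ci_up)) {
    stop_es("supply value with CI bounds, or log_value with log_se")
  }
  if (value <= 0 || ci_lo <= 0 || ci_up <= 0) stop_es("ratio and CI bounds must be > 0")
  if (ci_lo >= ci_up) stop_es("CI lower bound must be below the upper bound")
  if (value < ci_lo || value > ci_up) {
    stop_es("the 95%% CI (%s, %s) does not contain the point estimate %s",
            format(ci_lo), format(ci_up), format(value))
  }
  se <- (log(ci_up) - log(ci_lo)) / (2 * Z95)
  route <- c(OR = "or_ci", RR = "rr_ci", IRR = "irr_ci")[[which]]
  es_estimate(which, log(value), se, route = route)
}

# ---- d <-> lnOR -------------------------------------------------------------

HH_FACTOR <- pi / sqrt(3)

#' Convert Cohen's d to a log odds ratio (and back)
#'
#' Two registered conversions: the logistic-distribution identity of
#' Hasselblad and Hedges, `lnOR = d * pi / sqrt(3)` with
#' `Var(lnOR) = Var(d) * pi^2 / 3` (method "hh", default), and Cox's
#' `lnOR = 1.65 d` ("cox"). Both are exact algebraic inverses of each other's
#' reverse direction.
#'
#' @param est An [es_estimate()] of measure D (`logor_from_d`) or OR
#'   (`d_from_logor`).
#' @param method "hh" or "cox".
#' @param n1,n2 Optional group sizes, used by `d_from_logor` to attach
#'   `df_like` so the result can feed Hedges' correction.
#' @return An `es_estimate` of measure OR (resp. D); the input route is
#'   preserved and the method recorded.
#' @export
logor_from_d <- function(est, method = c("hh", "cox")) {
  stopifnot(inherits(est, "es_estimate"))
  if (est$measure != "D") stop_es("logor_from_d expects a D estimate")
  method <- match.arg(method)
  f <- if (method == "hh") HH_FACTOR else 1.65
  es_estimate("OR", est$value * f, est$se * f, route = est$route,
              method = method, df_like = est$df_like, note = est$note)
}

#' @rdname logor_from_d
#' @export
d_from_logor <- function(est, method = c("hh", "cox"), n1 = NULL, n2 = NULL) {
  stopifnot(inherits(est, "es_estimate"))
  if (est$measure != "OR") stop_es("d_from_logor expects an OR estimate")
  method <- match.arg(method)
  f <- if (method == "hh") HH_FACTOR else 1.65
  df <- if (!is.null(n1) && !is.null(n2) && !anyNA(c(n1, n2))) n1 + n2 - 2
        else est$df_like
  es_estimate("D", log(est$value) / f, est$se / f, route = est$route,
              method = method, df_like = df %||% NA_real_, note = est$note)
}

# ---- OR -> RR ---------------------------------------------------------------

OR_TO_RR_METHODS <- c("zhang_yu", "rare_disease", "zhang_yu_median",
                      "two_by_two", "via_smd", "sqrt_or")

#' Registered OR-to-RR conversion methods
#'
#' @return Character vector of the six method names accepted by
#'   [rr_from_or()].
#' @export
es_or_to_rr_methods <- function() OR_TO_RR_METHODS

#' Convert an odds ratio to a risk ratio
#'
#' Six registered approaches:
#' \describe{
#'   \item{zhang_yu}{`RR = OR / (1 - p0 + p0 * OR)` with the supplied
#'     control-group risk `p0` (default).}
#'   \item{rare_disease}{`RR = OR` (identity; adequate only for rare events).}
#'   \item{zhang_yu_median}{Zhang-Yu with the median baseline risk observed
#'     across the dataset (supplied by the conversion engine).}
#'   \item{two_by_two}{Reconstructs the 2x2 table from OR, the group sizes and
#'     the baseline risk, then computes RR from the reconstructed risks.}
#'   \item{via_smd}{Maps lnOR to d (Hasselblad-Hedges), shifts the normal
#'     quantile of the baseline risk by d, and forms the ratio of the implied
#'     risks.}
#'   \item{sqrt_or}{`RR = sqrt(OR)` (a crude halving of the log effect).}
#' }
#' SEs are propagated by the delta method on the chosen transform of lnOR.
#'
#' @param or_est An [es_estimate()] of measure OR.
#' @param baseline_risk Control-group event probability in (0, 1); required by
#'   zhang_yu, two_by_two and via_smd.
#' @param method One of [es_or_to_rr_methods()].
#' @param n1,n2 Group sizes (two_by_two only).
#' @param median_baseline Dataset-level median baseline risk
#'   (zhang_yu_median only).
#' @return An `es_estimate` of measure RR; the route is preserved and the
#'   method recorded.
#' @export
#' @examples
#' or_est <- ratio_from_reported(2.25, 0.9937, 5.0945, which = "OR")
#' rr_from_or(or_est, baseline_risk = 0.1)   # RR = 2.0
rr_from_or <- function(or_est, baseline_risk = NULL,
                       method = OR_TO_RR_METHODS, n1 = NULL, n2 = NULL,
                       median_baseline = NULL) {
  stopifnot(inherits(or_est, "es_estimate"))
  if (or_est$measure != "OR") stop_es("rr_from_or expects an OR estimate")
  method <- match.arg(method)
  lnor <- log(or_est$value)

  p0 <- switch(method,
    zhang_yu = , two_by_two = , via_smd = {
      if (is.null(baseline_risk) || is.na(baseline_risk)) {
        stop_es("method '%s' requires baseline_risk", method)
      }
      if (baseline_risk <= 0 || baseline_risk >= 1) {
        stop_es("baseline_risk must lie in (0, 1)")
      }
      baseline_risk
    },
    zhang_yu_median = {
      if (is.null(median_baseline) || is.na(median_baseline)) {
        stop_es("method 'zhang_yu_median' requires a dataset-level median baseline risk")
      }
      median_baseline
    },
    NULL)

  lnrr_of_lnor <- switch(method,
    rare_disease = function(x) x,
    sqrt_or = function(x) x / 2,
    zhang_yu = , zhang_yu_median = function(x) x - log(1 - p0 + p0 * exp(x)),
    two_by_two = function(x) {
      # odds of group 1 implied by OR and the baseline odds; RR of the
      # implied risks (group sizes cancel and are only checked for presence)
      odds1 <- exp(x) * p0 / (1 - p0)
      log((odds1 / (1 + odds1)) / p0)
    },
    via_smd = function(x) {
      d <- x / HH_FACTOR
      log(stats::pnorm(stats::qnorm(p0) + d) / p0)
    })
  if (method == "two_by_two" && (is.null(n1) || is.null(n2) ||
                                 anyNA(c(n1, n2)))) {
    stop_es("method 'two_by_two' requires both group sizes")
  }
  lnrr <- lnrr_of_lnor(lnor)
  se <- abs(num_deriv(lnrr_of_lnor, lnor)) * or_est$se
  if (se <= 0 || !is.finite(se)) {
    stop_es("degenerate OR-to-RR conversion: propagated SE is not positive")
  }
  es_estimate("RR", lnrr, se, route = or_est$route, method = method,
              df_like = or_est$df_like)
}

#' Convert a risk ratio to an odds ratio given the baseline risk
#'
#' Inverts the Zhang-Yu relation: `OR = RR (1 - p0) / (1 - RR * p0)`,
#' requiring `RR * p0 < 1` (i.e. the implied group-1 risk below 1).
#'
#' @param rr_est An [es_estimate()] of measure RR.
#' @param baseline_risk Control-group risk in (0, 1).
#' @return An `es_estimate` of measure OR.
#' @export
or_from_rr <- function(rr_est, baseline_risk) {
  stopifnot(inherits(rr_est, "es_estimate"))
  if (rr_est$measure != "RR") stop_es("or_from_rr expects an RR estimate")
  if (baseline_risk <= 0 || baseline_risk >= 1) stop_es("baseline_risk must lie in (0, 1)")
  p0 <- baseline_risk
  if (rr_est$value * p0 >= 1) {
    stop_es("RR * baseline_risk >= 1: implied group-1 risk is not below 1")
  }
  f <- function(x) x + log(1 - p0) - log(1 - exp(x) * p0)
  lnrr <- log(rr_est$value)
  es_estimate("OR", f(lnrr), abs(num_deriv(f, lnrr)) * rr_est$se,
              route = rr_est$route, method = "inverse_zhang_yu",
              df_like = rr_est$df_like)
}

# ---- NNT --------------------------------------------------------------------

#' Number needed to treat from two event risks
#'
#' `NNT = 1 / (p1 - p2)`; positive values mean benefit of group 1 under the
#' package's sign convention. The CI is obtained by transforming the bounds of
#' the risk-difference CI; when that interval spans 0 the NNT interval is
#' disjoint and reported as missing. The value is left unrounded (round up for
#' clinical use); `se` is on the risk-difference scale.
#'
#' @param p1,p2 Event risks in the two groups.
#' @param n1,n2 Group sizes, used for the risk-difference SE.
#' @return An [es_estimate()] of measure NNT.
#' @export
#' @examples
#' nnt_from_risks(0.2, 0.1, 100, 100)  # NNT = 10
nnt_from_risks <- function(p1, p2, n1, n2, route = "2x2") {
  if (any(c(p1, p2) < 0 | c(p1, p2) > 1)) stop_es("risks must lie in [0, 1]")
  if (p1 == p2) stop_es("infinite NNT: the two risks are equal (risk difference 0)")
  ard <- p1 - p2
  se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  if (se == 0) {
    stop_es("degenerate risks (0 or 1 in both groups): risk-difference SE is 0")
  }
  new_nnt(ard, se, route = route, method = "risk_difference")
}

#' Number needed to treat from a standardized mean difference
#'
#' Furukawa's conversion: `NNT = 1 / (Phi(d + Phi^{-1}(CER)) - CER)` where CER
#' is the control-group event rate; the SE of the implied risk difference
#' follows from the delta method on d.
#'
#' @param d_est An [es_estimate()] of measure D.
#' @param cer Control event rate in (0, 1).
#' @return An [es_estimate()] of measure NNT.
#' @export
#' @examples
#' nnt_from_d(d_from_means(103, 100, 10, 10, 50, 50), cer = 0.2)  # ~10.63
nnt_from_d <- function(d_est, cer) {
  stopifnot(inherits(d_est, "es_estimate"))
  if (d_est$measure != "D") stop_es("nnt_from_d expects a D estimate")
  if (cer <= 0 || cer >= 1) stop_es("cer must lie in (0, 1)")
  z0 <- stats::qnorm(cer)
  ard <- stats::pnorm(d_est$value + z0) - cer
  if (ard == 0) stop_es("infinite NNT: d = 0 implies equal risks")
  se <- stats::dnorm(d_est$value + z0) * d_est$se
  new_nnt(ard, se, route = d_est$route, method = "d_with_cer")
}

#' Number needed to treat from an odds ratio and baseline risk
#'
#' Converts the OR to an RR via Zhang-Yu, forms the implied risk difference
#' `p0 (RR - 1)` and inverts it; SE by the delta method on lnOR.
#'
#' @param or_est An [es_estimate()] of measure OR.
#' @param baseline_risk Control-group risk in (0, 1).
#' @return An [es_estimate()] of measure NNT.
#' @export
nnt_from_or <- function(or_est, baseline_risk) {
  stopifnot(inherits(or_est, "es_estimate"))
  if (or_est$measure != "OR") stop_es("nnt_from_or expects an OR estimate")
  if (baseline_risk <= 0 || baseline_risk >= 1) stop_es("baseline_risk must lie in (0, 1)")
  p0 <- baseline_risk
  ard_of_lnor <- function(x) p0 * (exp(x) / (1 - p0 + p0 * exp(x)) - 1)
  lnor <- log(or_est$value)
  ard <- ard_of_lnor(lnor)
  if (ard == 0) stop_es("infinite NNT: OR = 1 implies equal risks")
  se <- abs(num_deriv(ard_of_lnor, lnor)) * or_est$se
  new_nnt(ard, se, route = or_est$route, method = "or_with_cer")
}
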