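# Standardized mean differences (Cohen's d, Hedges' g) and mean differences,
# from raw moments, precision statistics, test statistics, quantile summaries,
# change scores and ANCOVA results.

d_var <- function(d, n1, n2) (n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2))

#' Cohen's d from group means and standard deviations
#'
#' Standardizes the mean difference by the pooled SD
#' \eqn{S_p = \sqrt{((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)}} and attaches
#' the large-sample variance
#' \eqn{(n_1+n_2)/(n_1 n_2) + d^2/(2(n_1+n_2))}.
#'
#' @param m1,m2 Group means (group 1 minus group 2 defines the sign).
#' @param sd1,sd2 Group standard deviations, > 0.
#' @param n1,n2 Group sizes, >= 2.
#' @param route Route label recorded on the estimate (callers reconstructing
#'   moments from SEs, CIs or quantiles pass their own).
#' @return An [es_estimate()] of measure D with `df_like = n1 + n2 - 2`.
#' @export
#' @examples
#' d_from_means(103, 100, 10, 10, 50, 50)  # d = 0.30, se = 0.2011
d_from_means <- function(m1, m2, sd1, sd2, n1, n2, route = "means_sd") {
  if (n1 < 2 || n2 < 2) stop_es("group sizes must be >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop_es("standard deviations must be > 0")
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (sp == 0) stop_es("undefined effect: pooled SD is 0")
  d <- (m1 - m2) / sp
  es_estimate("D", d, sqrt(d_var(d, n1, n2)), route = route,
              df_like = n1 + n2 - 2)
}

#' Reconstruct a mean's SD from its standard error or confidence interval
#'
#' `sd = se * sqrt(n)`; from a 95% CI, `se = (upper - lower) / (2 * 1.96)`.
#'
#' @param mean Group mean (returned unchanged).
#' @param se Standard error of the mean, if reported.
#' @param ci_lo,ci_up 95% CI bounds of the mean, if reported instead.
#' @param n Group size, >= 2.
#' @return List with elements `mean`, `sd`, `se`.
#' @export
moments_from_precision <- function(mean, se = NULL, ci_lo = NULL, ci_up = NULL, n) {
  if (n < 2) stop_es("n must be >= 2")
  if (is.null(se)) {
    if (is.null(ci_lo) || is.null(ci_up)) {
      stop_es("supply either se or both CI bounds")
    }
    width <- ci_up - ci_lo
    if (width <= 0) stop_es("CI width must be positive (got %s)", format(width))
    se <- width / (2 * Z95)
  }
  if (se <= 0) stop_es("standard error must be positive")
  list(mean = mean, sd = se * sqrt(n), se = se)
}

#' Cohen's d from a test statistic
#'
#' Converts a two-group test statistic to d: \eqn{d = t\sqrt{1/n_1 + 1/n_2}};
#' for F (one-way, 2 groups) \eqn{t = \sqrt{F}}; for a two-tailed p-value
#' \eqn{t = t^{-1}(1 - p/2,\, n_1+n_2-2)}; for eta-squared
#' \eqn{d = 2\sqrt{\eta^2/(1-\eta^2)}}. F, p and eta-squared carry no sign, so
#' `es_direction` must be "positive" or "negative" for them; one-tailed
#' p-values must be doubled by the user before input.
#'
#' @param stat One of "t", "f", "p", "eta2".
#' @param value The statistic's value.
#' @param n1,n2 Group sizes.
#' @param es_direction "positive", "negative" or "unspecified".
#' @return An [es_estimate()] of measure D; the route records the statistic.
#' @export
#' @examples
#' d_from_test_stat("t", 2, 50, 50)                      # d = 0.4
#' d_from_test_stat("p", 0.05, 50, 50, "positive")        # d = 0.3969
d_from_test_stat <- function(stat = c("t", "f", "p", "eta2"), value, n1, n2,
                             es_direction = "unspecified") {
  stat <- match.arg(stat)
  if (n1 < 2 || n2 < 2) stop_es("group sizes must be >= 2")
  sgn <- 1
  if (stat != "t") {
    if (!es_direction %in% c("positive", "negative")) {
      stop_es("direction required: %s carries no sign; set es_direction to positive or negative",
              stat)
    }
    sgn <- if (es_direction == "positive") 1 else -1
  }
  d <- switch(stat,
    t = value * sqrt(1 / n1 + 1 / n2),
    f = {
      if (value < 0) stop_es("F must be >= 0")
      sgn * sqrt(value) * sqrt(1 / n1 + 1 / n2)
    },
    p = {
      if (value <= 0 || value > 1) stop_es("p-value must lie in (0, 1]")
      sgn * stats::qt(1 - value / 2, df = n1 + n2 - 2) * sqrt(1 / n1 + 1 / n2)
    },
    eta2 = {
      if (value < 0 || value >= 1) stop_es("eta-squared must lie in [0, 1)")
      sgn * 2 * sqrt(value / (1 - value))
    })
  route <- c(t = "t", f = "f", p = "p", eta2 = "eta")[[stat]]
  es_estimate("D", d, sqrt(d_var(d, n1, n2)), route = route,
              df_like = n1 + n2 - 2)
}

#' Estimate mean and SD from median, quartiles and/or range
#'
#' Scenario estimators for samples summarized by order statistics: the mean
#' uses the optimal weighted estimators of Luo et al. (2018), the SD the
#' normal-quantile formulas of Wan et al. (2014). These assume approximate
#' normality; downstream routes tag results "median_*" so users can see an
#' approximation was involved.
#'
#' @param med Median.
#' @param q1,q3 First/third quartiles (iqr scenarios).
#' @param min,max Sample range (range scenarios).
#' @param n Sample size, >= 5.
#' @param scenario "range_only", "iqr_only" or "both"; inferred from the
#'   supplied fields when NULL.
#' @return List with elements `mean`, `sd`, `scenario`.
#' @export
#' @examples
#' moments_from_quantiles(med = 10, q1 = 8, q3 = 12, n = 25)  # sd ~ 3.144
moments_from_quantiles <- function(med, q1 = NULL, q3 = NULL, min = NULL,
                                   max = NULL, n, scenario = NULL) {
  if (n < 5) stop_es("quantile-based estimation requires n >= 5")
  have_iqr <- !is.null(q1) && !is.null(q3)
  have_rng <- !is.null(min) && !is.null(max)
  if (is.null(scenario)) {
    scenario <- if (have_iqr && have_rng) "both"
                else if (have_iqr) "iqr_only"
                else if (have_rng) "range_only"
                else stop_es("supply quartiles and/or range")
  }
  scenario <- match.arg(scenario, c("range_only", "iqr_only", "both"))
  ord <- c(min, q1, med, q3, max)
  if (any(diff(ord) < 0)) {
    stop_es("ordering violation: need min <= q1 <= median <= q3 <= max")
  }
  xi_rng <- 2 * stats::qnorm((n - 0.375) / (n + 0.25))
  xi_iqr <- 2 * stats::qnorm((0.75 * n - 0.125) / (n + 0.25))
  if (scenario == "range_only") {
    if (!have_rng) stop_es("range_only scenario needs min and max")
    w <- 4 / (4 + n^0.75)
    mean <- w * (min + max) / 2 + (1 - w) * med
    sd <- (max - min) / xi_rng
  } else if (scenario == "iqr_only") {
    if (!have_iqr) stop_es("iqr_only scenario needs q1 and q3")
    w <- 0.7 + 0.39 / n
    mean <- w * (q1 + q3) / 2 + (1 - w) * med
    sd <- (q3 - q1) / xi_iqr
  } else {
    if (!(have_iqr && have_rng)) stop_es("'both' scenario needs quartiles and range")
    w1 <- 2.2 / (2.2 + n^0.75)
    w2 <- 0.7 - 0.72 / n^0.55
    mean <- w1 * (min + max) / 2 + w2 * (q1 + q3) / 2 + (1 - w1 - w2) * med
    sd <- (max - min) / (2 * xi_rng) + (q3 - q1) / (2 * xi_iqr)
  }
  list(mean = mean, sd = sd, scenario = scenario)
}

change_sd <- function(sd_pre, sd_post, r) {
  sqrt(sd_pre^2 + sd_post^2 - 2 * r * sd_pre * sd_post)
}

#' Cohen's d from pre/post change scores
#'
#' Builds per-group change-score SDs
#' \eqn{\sqrt{s_{pre}^2 + s_{post}^2 - 2 r s_{pre} s_{post}}} from the
#' user-supplied pre/post correlation (no silent default), then standardizes
#' the difference in mean changes by the pooled change SD.
#'
#' @param m1,m2 Post-test means.
#' @param pre_m1,pre_m2 Pre-test means.
#' @param sd1,sd2 Post-test SDs; `pre_sd1`, `pre_sd2` pre-test SDs.
#' @param r_prepost Pre/post correlation in (-1, 1); must be supplied.
#' @param n1,n2 Group sizes.
#' @return An [es_estimate()] of measure D, route "change_scores".
#' @export
d_from_change <- function(m1, m2, pre_m1, pre_m2, sd1, sd2, pre_sd1, pre_sd2,
                          r_prepost = NULL, n1, n2) {
  if (is.null(r_prepost) || is.na(r_prepost)) {
    stop_es("r_prepost is required for the change-score route: supply the pre/post correlation (no default is assumed)")
  }
  sdc1 <- change_sd(pre_sd1, sd1, r_prepost)
  sdc2 <- change_sd(pre_sd2, sd2, r_prepost)
  if (sdc1 <= 1e-12 || sdc2 <= 1e-12) {
    stop_es("undefined effect: change-score SD is 0 (pre/post correlation too close to 1)")
  }
  d_from_means(m1 - pre_m1, m2 - pre_m2, sdc1, sdc2, n1, n2,
               route = "change_scores")
}

#' Cohen's d from covariate-adjusted (ANCOVA) means
#'
#' `d = (adj_m1 - adj_m2) / adj_sd_pooled` with the usual d variance. The
#' supplied SD must be on the unadjusted outcome scale (not the model's
#' residual SD); reconstructing it from the error SD and R-squared is left to
#' the user to avoid silent assumptions.
#'
#' @param adj_m1,adj_m2 Adjusted means.
#' @param adj_sd_pooled Pooled unadjusted-scale SD, > 0.
#' @param n1,n2 Group sizes.
#' @return An [es_estimate()] of measure D, route "ancova_means".
#' @export
d_from_ancova <- function(adj_m1, adj_m2, adj_sd_pooled, n1, n2) {
  if (adj_sd_pooled <= 0) stop_es("adj_sd_pooled must be > 0")
  d_from_means(adj_m1, adj_m2, adj_sd_pooled, adj_sd_pooled, n1, n2,
               route = "ancova_means")
}

#' Small-sample correction factor J
#'
#' Rational approximation `J = 1 - 3/(4 df - 1)`; accurate to 4 decimals for
#' df >= 10 and monotonically increasing towards 1.
#'
#' @param df Degrees of freedom, >= 2.
#' @return Numeric J in (0, 1).
#' @export
hedges_j <- function(df) {
  if (any(df < 2)) stop_es("J requires df >= 2")
  1 - 3 / (4 * df - 1)
}

#' Convert Cohen's d to Hedges' g
#'
#' `g = J d` with `Var(g) = J^2 Var(d)`, J from [hedges_j()] evaluated at the
#' estimate's `df_like`. The input route is preserved.
#'
#' @param est An [es_estimate()] of measure D carrying `df_like`.
#' @return An `es_estimate` of measure G.
#' @export
hedges_correction <- function(est) {
  stopifnot(inherits(est, "es_estimate"))
  if (est$measure != "D") stop_es("hedges_correction expects a D estimate")
  if (is.na(est$df_like)) {
    stop_es("group sizes required: Hedges' correction needs degrees of freedom")
  }
  j <- hedges_j(est$df_like)
  es_estimate("G", j * est$value, j * est$se, route = est$route,
              method = est$method, df_like = est$df_like, note = est$note)
}

#' Mean difference from group summary statistics
#'
#' `MD = m1 - m2` with `Var = sd1^2/n1 + sd2^2/n2`.
#'
#' @inheritParams d_from_means
#' @return An [es_estimate()] of measure MD.
#' @export
md_from_means <- function(m1, m2, sd1, sd2, n1, n2, route = "means_sd") {
  if (n1 < 2 || n2 < 2) stop_es("group sizes must be >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop_es("standard deviations must be > 0")
  se <- sqrt(sd1^2 / n1 + sd2^2 / n2)
  es_estimate("MD", m1 - m2, se, route = route, df_like = n1 + n2 - 2)
}

#' Mean difference from a reported estimate with precision
#'
#' Pass-through of a reported MD with its SE, or with SE reconstructed from a
#' 95% CI as `(upper - lower) / (2 * 1.96)`.
#'
#' @param md_value Reported mean difference.
#' @param md_se Its standard error (route "md_se").
#' @param ci_lo,ci_up Alternatively its 95% CI bounds (route "md_ci").
#' @param df Optional degrees of freedom to carry along.
#' @return An [es_estimate()] of measure MD.
#' @export
md_from_reported <- function(md_value, md_se = NULL, ci_lo = NULL,
                             ci_up = NULL, df = NA_real_) {
  if (!is.null(md_se)) {
    if (md_se <= 0) stop_es("md_se must be positive")
    return(es_estimate("MD", md_value, md_se, route = "md_se", df_like = df))
  }
  if (is.null(ci_lo) || is.null(ci_up)) {
    stop_es("supply md_se or both CI bounds")
  }
  width <- ci_up - ci_lo
  if (width <= 0) stop_es("CI width must be positive")
  es_estimate("MD", md_value, width / (2 * Z95), route = "md_ci", df_like = df)
}
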