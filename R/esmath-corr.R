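# Correlation coefficients, Fisher's z, and conversions into r from d and OR.

#' Correlation and Fisher's z from a reported r and its sample size
#'
#' `z = atanh(r)` with `Var(z) = 1/(n - 3)`. For measure R the point value
#' stays on the r scale while the interval is formed on the z scale and
#' back-transformed by `tanh`; the stored `se` is the z-scale SE (the package
#' uses one scale convention per measure).
#'
#' @param r_value Correlation in (-1, 1).
#' @param n_r Sample size, >= 4.
#' @param measure "Z" (default) or "R" - both derive from the same input.
#' @return An [es_estimate()] of the requested measure, route "r_n".
#' @export
#' @examples
#' z_from_r(0.5, 103)            # z = 0.5493, se = 0.1
#' z_from_r(0.5, 103, "R")       # r = 0.5, CI [0.339, 0.632]
z_from_r <- function(r_value, n_r, measure = c("Z", "R")) {
  measure <- match.arg(measure)
  if (abs(r_value) >= 1) stop_es("r must lie strictly in (-1, 1)")
  if (n_r <= 3) stop_es("Fisher's z needs n >= 4 (variance is 1/(n-3))")
  es_estimate(measure, atanh(r_value), 1 / sqrt(n_r - 3), route = "r_n")
}

#' Correlation from a standardized mean difference
#'
#' `r = d / sqrt(d^2 + a)` with `a = (n1 + n2)^2 / (n1 n2)` (a = 4 when group
#' sizes are unknown). The CI is built on the Fisher-z scale with
#' `n = n1 + n2`; when group sizes are missing the z-scale SE is propagated
#' from `Var(d)` by the delta method instead.
#'
#' @param est An [es_estimate()] of measure D.
#' @param n1,n2 Group sizes behind the d (optional).
#' @param measure "R" (default) or "Z" for the Fisher-transformed value.
#' @return An `es_estimate`; the input route is preserved.
#' @export
#' @examples
#' r_from_d(d_from_means(5, 3, 2, 4, 10, 10), 10, 10)  # r = 0.3015
r_from_d <- function(est, n1 = NULL, n2 = NULL, measure = c("R", "Z")) {
  stopifnot(inherits(est, "es_estimate"))
  if (est$measure != "D") stop_es("r_from_d expects a D estimate")
  measure <- match.arg(measure)
  have_n <- !is.null(n1) && !is.null(n2) && !anyNA(c(n1, n2))
  a <- if (have_n) (n1 + n2)^2 / (n1 * n2) else 4
  z_of_d <- function(d) atanh(d / sqrt(d^2 + a))
  z <- z_of_d(est$value)
  se <- if (have_n && n1 + n2 > 3) 1 / sqrt(n1 + n2 - 3)
        else abs(num_deriv(z_of_d, est$value)) * est$se
  es_estimate(measure, z, se, route = est$route, method = est$method,
              df_like = est$df_like)
}

#' Cohen's d from a correlation coefficient
#'
#' The algebraic inverse of the equal-groups d-to-r conversion:
#' `d = 2 r / sqrt(1 - r^2)` with
#' `Var(d) = 4 Var(r) / (1 - r^2)^3`, `Var(r) = (1 - r^2)^2 / (n - 1)`.
#'
#' @param r_value Correlation in (-1, 1).
#' @param n_r Sample size behind it, >= 4.
#' @return An [es_estimate()] of measure D, route "r_n",
#'   `df_like = n_r - 2`.
#' @export
d_from_r <- function(r_value, n_r) {
  if (abs(r_value) >= 1) stop_es("r must lie strictly in (-1, 1)")
  if (n_r < 4) stop_es("n_r must be >= 4")
  d <- 2 * r_value / sqrt(1 - r_value^2)
  var_r <- (1 - r_value^2)^2 / (n_r - 1)
  var_d <- 4 * var_r / (1 - r_value^2)^3
  es_estimate("D", d, sqrt(var_d), route = "r_n", df_like = n_r - 2)
}

OR_TO_R_METHODS <- c("via_d_hh", "via_d_cox", "tetrachoric_approx")

#' Correlation from an odds ratio
#'
#' Three registered methods: conversion through d with the
#' Hasselblad-Hedges factor (`via_d_hh`, default) or Cox's factor
#' (`via_d_cox`), both followed by `r = d / sqrt(d^2 + 4)`, and the classical
#' cosine approximation to the tetrachoric correlation
#' `r = cos(pi / (1 + sqrt(OR)))`. All agree in sign and vanish at OR = 1.
#' The z-scale SE comes from `1/(n-3)` when group sizes are known, else from
#' the delta method on lnOR.
#'
#' @param or_est An [es_estimate()] of measure OR.
#' @param method One of `via_d_hh`, `via_d_cox`, `tetrachoric_approx`.
#' @param n1,n2 Optional group sizes.
#' @param measure "R" (default) or "Z".
#' @return An `es_estimate`; the input route is preserved, method recorded.
#' @export
r_from_or <- function(or_est, method = OR_TO_R_METHODS, n1 = NULL, n2 = NULL,
                      measure = c("R", "Z")) {
  stopifnot(inherits(or_est, "es_estimate"))
  if (or_est$measure != "OR") stop_es("r_from_or expects an OR estimate")
  method <- match.arg(method)
  measure <- match.arg(measure)
  z_of_lnor <- switch(method,
    via_d_hh = function(x) { d <- x / HH_FACTOR; atanh(d / sqrt(d^2 + 4)) },
    via_d_cox = function(x) { d <- x / 1.65; atanh(d / sqrt(d^2 + 4)) },
    tetrachoric_approx = function(x) atanh(cos(pi / (1 + exp(x / 2)))))
  lnor <- log(or_est$value)
  z <- z_of_lnor(lnor)
  have_n <- !is.null(n1) && !is.null(n2) && !anyNA(c(n1, n2))
  se <- if (have_n && n1 + n2 > 3) 1 / sqrt(n1 + n2 - 3)
        else abs(num_deriv(z_of_lnor, lnor)) * or_est$se
  es_estimate(measure, z, se, route = or_est$route, method = method,
              df_like = or_est$df_like)
}
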