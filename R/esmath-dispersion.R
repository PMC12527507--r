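# Variability ratio and coefficient-of-variation ratio, on the log scale.

#' Log variability ratio from group SDs
#'
#' `lnVR = ln(sd1/sd2) + 1/(2(n1-1)) - 1/(2(n2-1))` (the bias-correction
#' terms cancel for equal group sizes) with
#' `Var = 1/(2(n1-1)) + 1/(2(n2-1))`.
#'
#' @param sd1,sd2 Group SDs, > 0.
#' @param n1,n2 Group sizes, >= 2.
#' @param route Route label recorded on the estimate.
#' @return An [es_estimate()] of measure VR.
#' @export
#' @examples
#' lnvr_from_moments(15, 10, 25, 25)  # lnVR = 0.4055, se = 0.2041
lnvr_from_moments <- function(sd1, sd2, n1, n2, route = "means_sd") {
  if (sd1 <= 0 || sd2 <= 0) stop_es("standard deviations must be > 0")
  if (n1 < 2 || n2 < 2) stop_es("group sizes must be >= 2")
  lnvr <- log(sd1 / sd2) + 1 / (2 * (n1 - 1)) - 1 / (2 * (n2 - 1))
  v <- 1 / (2 * (n1 - 1)) + 1 / (2 * (n2 - 1))
  es_estimate("VR", lnvr, sqrt(v), route = route)
}

#' Log coefficient-of-variation ratio from group moments
#'
#' `lnCVR = ln((sd1/m1)/(sd2/m2)) + 1/(2(n1-1)) - 1/(2(n2-1))` with
#' `Var = sd1^2/(n1 m1^2) + 1/(2(n1-1)) + sd2^2/(n2 m2^2) + 1/(2(n2-1))`.
#' The mean-SD correlation term of the full variance is set to 0 since the
#' schema carries no within-study raw data (documented limitation). Both
#' means must be strictly positive: CVs are only meaningful for ratio-scale
#' outcomes.
#'
#' @param m1,m2 Group means, > 0.
#' @param sd1,sd2 Group SDs, > 0.
#' @param n1,n2 Group sizes, >= 2.
#' @param route Route label recorded on the estimate.
#' @return An [es_estimate()] of measure CVR.
#' @export
#' @examples
#' lncvr_from_moments(100, 15, 100, 10, 25, 25)  # lnCVR = 0.4055
lncvr_from_moments <- function(m1, sd1, m2, sd2, n1, n2, route = "means_sd") {
  if (m1 <= 0 || m2 <= 0) {
    stop_es("CVR requires ratio-scale data: both group means must be strictly positive")
  }
  if (sd1 <= 0 || sd2 <= 0) stop_es("standard deviations must be > 0")
  if (n1 < 2 || n2 < 2) stop_es("group sizes must be >= 2")
  lncvr <- log((sd1 / m1) / (sd2 / m2)) + 1 / (2 * (n1 - 1)) - 1 / (2 * (n2 - 1))
  v <- sd1^2 / (n1 * m1^2) + 1 / (2 * (n1 - 1)) +
       sd2^2 / (n2 * m2^2) + 1 / (2 * (n2 - 1))
  es_estimate("CVR", lncvr, sqrt(v), route = route)
}
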