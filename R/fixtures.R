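# Synthetic schema-valid datasets with controlled overlapping inputs, for
# tests and demos. Each row's overlapping statistics are derived from the
# same simulated summary data, so candidate estimates agree exactly (up to
# estimator approximation error for the order-statistic family).

FIXTURE_FAMILIES <- c("smd", "smd2", "change", "median", "binary", "rates", "corr")

# families whose overlapping routes are algebraically exact transforms of
# one another (candidate estimates coincide to rounding)
EXACT_FAMILIES <- c("smd", "smd2", "binary")

#' Generate a synthetic extraction dataset
#'
#' Simulates per-study summary statistics under a two-group normal outcome
#' model (standardized mean difference family), a two-group binomial model
#' (2x2 family), a Poisson person-time model (rates) and a bivariate-normal
#' correlation model, then writes every input-data representation of each
#' simulated study into one schema row. Within the "smd", "smd2" and
#' "binary" families the overlapping inputs are exact transforms of the same
#' summary data (t derived from the simulated means/SDs, the OR CI from the
#' simulated 2x2, ...), so candidate effect sizes agree and CI overlap is
#' complete; the "median" family reports order statistics of an actual
#' simulated sample alongside its moments, exercising the approximation
#' routes.
#'
#' A `corruption` fraction > 0 injects a classic extraction error into that
#' share of the corruptible (exact-family) rows: a sign flip of the t
#' statistic (smd) or an inverted reported OR (binary), which
#' [flag_discrepancies()] is designed to catch. Corrupted row indices are
#' recorded in attribute `"corrupted"`; rows that remain exactly
#' self-consistent are listed in attribute `"exact"`.
#'
#' @param n_studies Number of rows.
#' @param families Which row families to cycle through; subset of
#'   `c("smd", "smd2", "change", "median", "binary", "rates", "corr")`.
#' @param true_smd True standardized mean difference of the SMD families.
#' @param true_logor True log odds ratio of the binary family.
#' @param true_logirr True log incidence rate ratio of the rates family.
#' @param true_r True correlation of the correlation family.
#' @param corruption Fraction of corruptible rows to corrupt; default 0.
#' @param seed RNG seed; the caller's RNG state is restored afterwards.
#' @return An `es_dataset` with attributes `family`, `exact`, `corrupted`.
#' @export
#' @examples
#' fx <- generate_fixture(n_studies = 7, seed = 7)
#' table(attr(fx, "family"))
generate_fixture <- function(n_studies = 20, families = FIXTURE_FAMILIES,
                             true_smd = 0.3, true_logor = log(2),
                             true_logirr = log(1.5), true_r = 0.3,
                             corruption = 0, seed = 42) {
  families <- match.arg(families, FIXTURE_FAMILIES, several.ok = TRUE)
  stopifnot(n_studies >= 1, corruption >= 0, corruption <= 1)
  with_seed(seed, {
    fam <- rep(families, length.out = n_studies)
    rows <- lapply(seq_len(n_studies), function(i) {
      r <- switch(fam[i],
        smd = fixture_smd(true_smd, variant = 1L),
        smd2 = fixture_smd(true_smd, variant = 2L),
        change = fixture_change(true_smd),
        median = fixture_median(true_smd),
        binary = fixture_binary(true_logor),
        rates = fixture_rates(true_logirr),
        corr = fixture_corr(true_r))
      r$study_id <- sprintf("study_%02d", i)
      r
    })

    corrupted <- integer(0)
    if (corruption > 0) {
      corruptible <- which(fam %in% c("smd", "binary"))
      k <- min(length(corruptible), round(corruption * n_studies))
      if (k > 0) {
        corrupted <- sort(sample(corruptible, k))
        for (i in corrupted) {
          if (fam[i] == "smd") {
            # forgotten direction reversal in the test-statistic extraction
            rows[[i]]$t_value <- -rows[[i]]$t_value
          } else {
            # reversed reported OR (its CI follows suit to stay well-formed)
            rows[[i]]$or_value <- 1 / rows[[i]]$or_value
            ci <- sort(1 / c(rows[[i]]$or_ci_lo, rows[[i]]$or_ci_up))
            rows[[i]]$or_ci_lo <- ci[1L]
            rows[[i]]$or_ci_up <- ci[2L]
          }
        }
      }
    }

    schema <- es_schema()
    df <- as.data.frame(
      lapply(stats::setNames(schema$name, schema$name), function(cl) {
        vapply(rows, function(r) {
          v <- r[[cl]]
          if (is.null(v)) NA_character_ else as.character(v)
        }, character(1))
      }), check.names = FALSE, stringsAsFactors = FALSE)
    out <- as_es_dataset(df)
    attr(out, "family") <- fam
    attr(out, "exact") <- setdiff(which(fam %in% EXACT_FAMILIES), corrupted)
    attr(out, "corrupted") <- corrupted
    out
  })
}

# two-group normal summaries; variant 1 reports means+SD/SE and t/p/eta,
# variant 2 reports mean CIs, F, and the MD with SE and CI
fixture_smd <- function(true_smd, variant = 1L) {
  n1 <- sample(40:120, 1); n2 <- sample(40:120, 1)
  sd1 <- stats::runif(1, 8, 12); sd2 <- stats::runif(1, 8, 12)
  m2 <- stats::rnorm(1, 50, 5)
  d_i <- true_smd + stats::rnorm(1, 0, 0.1)
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  m1 <- m2 + d_i * sp
  d <- (m1 - m2) / sp
  t <- d / sqrt(1 / n1 + 1 / n2)
  out <- list(n1 = n1, n2 = n2, m1 = m1, m2 = m2,
              es_direction = if (d >= 0) "positive" else "negative")
  if (variant == 1L) {
    out$sd1 <- sd1; out$sd2 <- sd2
    out$se1 <- sd1 / sqrt(n1); out$se2 <- sd2 / sqrt(n2)
    out$t_value <- t
    out$p_value <- 2 * stats::pt(-abs(t), df = n1 + n2 - 2)
    out$eta_sq <- d^2 / (d^2 + 4)
  } else {
    out$m1_ci_lo <- m1 - 1.96 * sd1 / sqrt(n1)
    out$m1_ci_up <- m1 + 1.96 * sd1 / sqrt(n1)
    out$m2_ci_lo <- m2 - 1.96 * sd2 / sqrt(n2)
    out$m2_ci_up <- m2 + 1.96 * sd2 / sqrt(n2)
    out$f_value <- t^2
    out$md_value <- m1 - m2
    md_se <- sqrt(sd1^2 / n1 + sd2^2 / n2)
    out$md_se <- md_se
    out$md_ci_lo <- (m1 - m2) - 1.96 * md_se
    out$md_ci_up <- (m1 - m2) + 1.96 * md_se
  }
  out
}

# pre/post design: the change-score and ANCOVA representations describe the
# same simulated change, post-test moments are also reported
fixture_change <- function(true_smd) {
  n1 <- sample(40:120, 1); n2 <- sample(40:120, 1)
  sdp <- stats::runif(1, 8, 12)
  r <- 0.6
  pre_m <- stats::rnorm(1, 50, 5)
  sdc <- sqrt(2 * (1 - r)) * sdp   # change SD for equal pre/post SDs
  delta1 <- (true_smd + stats::rnorm(1, 0, 0.1)) * sdc
  out <- list(n1 = n1, n2 = n2,
              pre_m1 = pre_m, pre_m2 = pre_m,
              pre_sd1 = sdp, pre_sd2 = sdp,
              m1 = pre_m + delta1, m2 = pre_m,
              sd1 = sdp, sd2 = sdp,
              r_prepost = r,
              adj_m1 = pre_m + delta1, adj_m2 = pre_m,
              adj_sd_pooled = sdc,
              es_direction = if (delta1 >= 0) "positive" else "negative")
  out
}

# an actual normal sample is drawn so that the reported order statistics and
# the reported moments describe the same data (approximately consistent)
fixture_median <- function(true_smd) {
  n1 <- sample(100:300, 1); n2 <- sample(100:300, 1)
  sd0 <- 10
  x2 <- stats::rnorm(n2, 50, sd0)
  x1 <- stats::rnorm(n1, 50 + true_smd * sd0, sd0)
  q1 <- stats::quantile(x1, c(0.25, 0.5, 0.75), names = FALSE)
  q2 <- stats::quantile(x2, c(0.25, 0.5, 0.75), names = FALSE)
  list(n1 = n1, n2 = n2,
       m1 = mean(x1), m2 = mean(x2), sd1 = stats::sd(x1), sd2 = stats::sd(x2),
       med1 = q1[2], q1_1 = q1[1], q3_1 = q1[3], min1 = min(x1), max1 = max(x1),
       med2 = q2[2], q1_2 = q2[1], q3_2 = q2[3], min2 = min(x2), max2 = max(x2),
       es_direction = "positive")
}

# one simulated 2x2 table, reported as cells, proportions, OR with CI,
# lnOR with SE, and RR with CI
fixture_binary <- function(true_logor) {
  n1 <- sample(150:400, 1); n2 <- sample(150:400, 1)
  p2 <- stats::runif(1, 0.1, 0.3)
  lnor_i <- true_logor + stats::rnorm(1, 0, 0.1)
  odds1 <- exp(lnor_i) * p2 / (1 - p2)
  p1 <- odds1 / (1 + odds1)
  a <- max(1L, min(n1 - 1L, round(p1 * n1)))
  c_ <- max(1L, min(n2 - 1L, round(p2 * n2)))
  b <- n1 - a; d_ <- n2 - c_
  lnor <- log(a * d_ / (b * c_))
  se_or <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d_)
  rr <- (a / n1) / (c_ / n2)
  se_rr <- sqrt(1 / a - 1 / n1 + 1 / c_ - 1 / n2)
  list(n1 = n1, n2 = n2, a = a, b = b, c = c_, d_cell = d_,
       p_event1 = a / n1, p_event2 = c_ / n2,
       or_value = exp(lnor),
       or_ci_lo = exp(lnor - 1.96 * se_or), or_ci_up = exp(lnor + 1.96 * se_or),
       logor_value = lnor, logor_se = se_or,
       rr_value = rr,
       rr_ci_lo = exp(log(rr) - 1.96 * se_rr),
       rr_ci_up = exp(log(rr) + 1.96 * se_rr),
       baseline_risk = c_ / n2,
       es_direction = "positive")
}

fixture_rates <- function(true_logirr) {
  time1 <- stats::runif(1, 80, 200); time2 <- stats::runif(1, 80, 200)
  rate2 <- stats::runif(1, 0.08, 0.25)
  e2 <- max(1L, stats::rpois(1, rate2 * time2))
  e1 <- max(1L, stats::rpois(1, rate2 * exp(true_logirr) * time1))
  list(e1 = e1, time1 = time1, e2 = e2, time2 = time2,
       es_direction = "positive")
}

fixture_corr <- function(true_r) {
  n_r <- sample(60:300, 1)
  r <- tanh(atanh(true_r) + stats::rnorm(1, 0, 1 / sqrt(n_r - 3)))
  list(r_value = r, n_r = n_r, es_direction = if (r >= 0) "positive" else "negative")
}
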