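mk_d <- function(y, v) es_estimate("D", y, sqrt(v), "means_sd")

test_that("the correlated composite matches hand arithmetic", {
  agg <- aggregate_cluster(list(mk_d(0.4, 0.04), mk_d(0.4, 0.04)),
                           "outcomes", r_dep = 0.5)
  expect_equal(agg$value, 0.4, tolerance = 1e-12)
  expect_equal(agg$se^2, 0.03, tolerance = 1e-12)  # (0.08 + 2*0.5*0.04)/4
  # r = 1: perfectly correlated duplicates add no information
  agg1 <- aggregate_cluster(list(mk_d(0.4, 0.04), mk_d(0.4, 0.04)),
                            "times", r_dep = 1)
  expect_equal(agg1$se^2, 0.04, tolerance = 1e-12)
  # r = 0, m equal-V estimates: V/m
  ests <- replicate(4, mk_d(0.4, 0.04), simplify = FALSE)
  agg0 <- aggregate_cluster(ests, "outcomes", r_dep = 0)
  expect_equal(agg0$se^2, 0.01, tolerance = 1e-12)
})

test_that("composite variance is bounded between V/m and V for equal-V inputs", {
  ests <- replicate(3, mk_d(0.2, 0.09), simplify = FALSE)
  vs <- sapply(c(0, 0.25, 0.5, 0.75, 1), function(r) {
    aggregate_cluster(ests, "outcomes", r_dep = r)$se^2
  })
  expect_equal(vs[1], 0.09 / 3, tolerance = 1e-12)
  expect_equal(vs[5], 0.09, tolerance = 1e-12)
  expect_true(all(diff(vs) > 0))
})

test_that("subgroups mode equals brute-force inverse-variance pooling", {
  agg <- aggregate_cluster(list(mk_d(0.2, 0.04), mk_d(0.6, 0.04)), "subgroups")
  expect_equal(agg$value, 0.4, tolerance = 1e-12)
  expect_equal(agg$se^2, 0.02, tolerance = 1e-12)
  set.seed(31)
  y <- rnorm(5, 0.3, 0.2)
  v <- runif(5, 0.01, 0.2)
  agg2 <- aggregate_cluster(mapply(mk_d, y, v, SIMPLIFY = FALSE), "subgroups")
  w <- 1 / v
  expect_equal(agg2$value, sum(w * y) / sum(w), tolerance = 1e-12)
  expect_equal(agg2$se^2, 1 / sum(w), tolerance = 1e-12)
})

test_that("guard rails: correlation required, mixed measures refused, singletons pass", {
  ests <- list(mk_d(0.2, 0.04), mk_d(0.6, 0.04))
  expect_error(aggregate_cluster(ests, "outcomes"), "r_dep")
  expect_error(aggregate_cluster(ests, "outcomes", r_dep = 1.5), "\\[0, 1\\]")
  mixed <- list(mk_d(0.2, 0.04), es_estimate("OR", 0.3, 0.2, "2x2"))
  expect_error(aggregate_cluster(mixed, "subgroups"), "mixed measures")
  single <- aggregate_cluster(list(mk_d(0.2, 0.04)), "outcomes", r_dep = 0.5)
  expect_equal(single$value, 0.2)
  expect_identical(single$route, "means_sd")
})

test_that("ratio measures aggregate on the log scale", {
  o1 <- es_estimate("OR", log(2), 0.2, "2x2")
  o2 <- es_estimate("OR", log(4), 0.2, "or_ci")
  agg <- aggregate_cluster(list(o1, o2), "outcomes", r_dep = 0)
  expect_equal(log(agg$value), (log(2) + log(4)) / 2, tolerance = 1e-12)
  expect_equal(agg$value, sqrt(8), tolerance = 1e-12)
})

test_that("aggregate_df collapses clusters in first-appearance order", {
  df <- data.frame(
    study_id = c("B", "B", "A", "A", "A"),
    measure = "D",
    value = c(0.2, 0.4, 0.1, 0.3, 0.5),
    se = sqrt(0.04),
    year = c(2001, 2001, 1999, 1999, 1999))
  agg <- aggregate_df(df, "outcomes", r_dep = 0.5)
  expect_equal(nrow(agg), 2)
  expect_identical(agg$study_id, c("B", "A"))
  expect_equal(agg$n_aggregated, c(2L, 3L))
  expect_equal(agg$value, c(0.3, 0.3), tolerance = 1e-12)
  expect_equal(agg$year, c(2001, 1999))   # constant within cluster: retained

  # all-singleton input passes values through
  singles <- df[c(1, 3), ]
  agg2 <- aggregate_df(singles, "outcomes", r_dep = 0.5)
  expect_equal(agg2$value, singles$value)

  # non-constant extra column is blanked with a warning
  df$year[2] <- 2002
  expect_warning(agg3 <- aggregate_df(df, "outcomes", r_dep = 0.5), "year")
  expect_true(is.na(agg3$year[1]))
  expect_error(aggregate_df(df, "outcomes", r_dep = 0.5, agg_fact = "cohort"),
               "cohort")
})

test_that("aggregation commutes with linear rescaling (D vs MD, constant SD)", {
  sd0 <- 10   # MD = sd0 * d when every study shares one SD
  d_vals <- c(0.2, 0.5, 0.35)
  d_se <- c(0.1, 0.12, 0.11)
  d_agg <- aggregate_cluster(
    mapply(function(y, s) es_estimate("D", y, s, "means_sd"), d_vals, d_se,
           SIMPLIFY = FALSE), "outcomes", r_dep = 0.6)
  md_agg <- aggregate_cluster(
    mapply(function(y, s) es_estimate("MD", y * sd0, s * sd0, "means_sd"),
           d_vals, d_se, SIMPLIFY = FALSE), "outcomes", r_dep = 0.6)
  expect_equal(md_agg$value, sd0 * d_agg$value, tolerance = 1e-12)
  expect_equal(md_agg$se, sd0 * d_agg$se, tolerance = 1e-12)
})
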