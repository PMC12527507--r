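test_that("the five indicators match two-candidate arithmetic", {
  a <- es_estimate("D", 0.3, 0.1, "means_sd")
  b <- es_estimate("D", 0.5, 0.1, "t")
  rep_ <- consistency_indicators(cand_set(a, b))
  expect_equal(rep_$es_min, 0.3)
  expect_equal(rep_$es_max, 0.5)
  expect_equal(rep_$es_diff, 0.2, tolerance = 1e-12)
  expect_equal(rep_$es_sd, 0.1414213562, tolerance = 1e-9)  # diff / sqrt(2)
  expect_identical(sort(names(rep_)[1:5]),
                   sort(es_consistency_indicator_names()))
})

test_that("identical candidates give zero spread and full overlap", {
  a <- es_estimate("D", 0.3, 0.1, "means_sd")
  b <- es_estimate("D", 0.3, 0.1, "t")
  rep_ <- consistency_indicators(cand_set(a, b))
  expect_equal(rep_$es_diff, 0)
  expect_equal(rep_$es_sd, 0)
  expect_equal(rep_$ci_overlap_pct, 100)
  expect_length(flag_discrepancies(cand_set(a, b), rep_), 0)
})

test_that("CI overlap follows the interval-arithmetic definition", {
  # intervals (0,1) and (0.5,1.5): intersection 0.5, shorter width 1 -> 50
  mk <- function(lo, up) es_estimate("MD", (lo + up) / 2, (up - lo) / (2 * 1.96),
                                     "means_sd")
  rep_ <- consistency_indicators(cand_set(mk(0, 1), mk(0.5, 1.5)))
  expect_equal(rep_$ci_overlap_pct, 50, tolerance = 1e-9)
  # disjoint intervals -> 0
  expect_equal(consistency_indicators(cand_set(mk(0, 1), mk(2, 3)))$ci_overlap_pct, 0)
  # containment of the shorter interval -> 100 under the default denominator
  rep2 <- consistency_indicators(cand_set(mk(0, 4), mk(1, 2)))
  expect_equal(rep2$ci_overlap_pct, 100)
  # union denominator: intersection 1 / union 4 -> 25
  rep3 <- consistency_indicators(cand_set(mk(0, 4), mk(1, 2)),
                                 denominator = "union")
  expect_equal(rep3$ci_overlap_pct, 25, tolerance = 1e-9)
})

test_that("overlap is symmetric, order-invariant, and 100 iff intersection equals the shorter width", {
  set.seed(23)
  for (i in 1:30) {
    lo1 <- rnorm(1); w1 <- runif(1, 0.1, 2)
    lo2 <- rnorm(1); w2 <- runif(1, 0.1, 2)
    mk <- function(lo, w) es_estimate("D", lo + w / 2, w / (2 * 1.96), "t")
    r12 <- consistency_indicators(cand_set(mk(lo1, w1), mk(lo2, w2)))
    r21 <- consistency_indicators(cand_set(mk(lo2, w2), mk(lo1, w1)))
    expect_equal(r12$ci_overlap_pct, r21$ci_overlap_pct, tolerance = 1e-9)
    inter <- max(0, min(lo1 + w1, lo2 + w2) - max(lo1, lo2))
    expect_equal(r12$ci_overlap_pct == 100, abs(inter - min(w1, w2)) < 1e-12)
  }
})

test_that("ratio-measure indicators are computed on the log scale", {
  a <- es_estimate("OR", log(2), 0.2, "2x2")
  b <- es_estimate("OR", log(3), 0.2, "or_ci")
  rep_ <- consistency_indicators(cand_set(a, b))
  expect_equal(rep_$es_min, log(2), tolerance = 1e-12)
  expect_equal(rep_$es_max, log(3), tolerance = 1e-12)
  expect_identical(rep_$scale, "log")
})

test_that("fewer than two candidates yields no report at all", {
  a <- es_estimate("D", 0.3, 0.1, "means_sd")
  expect_null(consistency_indicators(cand_set(a)))
})

test_that("equal-magnitude opposite-sign candidates raise the sign_flip flag", {
  a <- es_estimate("D", 0.42, 0.15, "means_sd")
  b <- es_estimate("D", -0.42, 0.15, "t")
  cs <- cand_set(a, b)
  rep_ <- consistency_indicators(cs)
  expect_true("sign_flip" %in% flag_discrepancies(cs, rep_))
  # near-equal magnitudes within the 1% tolerance still flag
  b2 <- es_estimate("D", -0.4205, 0.15, "t")
  cs2 <- cand_set(a, b2)
  expect_true("sign_flip" %in%
                flag_discrepancies(cs2, consistency_indicators(cs2)))
  # clearly different magnitudes do not
  b3 <- es_estimate("D", -0.2, 0.15, "t")
  cs3 <- cand_set(a, b3)
  expect_false("sign_flip" %in%
                 flag_discrepancies(cs3, consistency_indicators(cs3)))
})

test_that("an extraction typo (OR 3.1 for 2.1) triggers large_divergence", {
  # both reported with tight CIs so the intervals barely overlap
  good <- ratio_from_reported(2.1, 1.9, 2.32, which = "OR")
  typo <- ratio_from_reported(3.1, 2.8, 3.43, which = "OR")
  cs <- cand_set(good, typo)
  rep_ <- consistency_indicators(cs)
  expect_lt(rep_$ci_overlap_pct, 25)
  expect_true("large_divergence" %in% flag_discrepancies(cs, rep_))
  # the configurable difference threshold also raises it
  a <- es_estimate("D", 0.1, 0.5, "means_sd")
  b <- es_estimate("D", 0.6, 0.5, "t")
  cs2 <- cand_set(a, b)
  rep2 <- consistency_indicators(cs2)
  expect_false("large_divergence" %in% flag_discrepancies(cs2, rep2))
  expect_true("large_divergence" %in%
                flag_discrepancies(cs2, rep2, diff_threshold = 0.4))
})

test_that("indicators are invariant to candidate ordering", {
  a <- es_estimate("D", 0.1, 0.1, "means_sd")
  b <- es_estimate("D", 0.5, 0.2, "t")
  c_ <- es_estimate("D", 0.3, 0.15, "p")
  r1 <- consistency_indicators(cand_set(a, b, c_))
  r2 <- consistency_indicators(cand_set(c_, a, b))
  for (f in es_consistency_indicator_names()) {
    expect_equal(r1[[f]], r2[[f]], tolerance = 1e-12)
  }
})
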