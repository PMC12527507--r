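# Frozen expected values come from direct arithmetic on the stated formulas.

test_that("2x2 tables give the classic lnOR and its Woolf SE", {
  e <- logor_from_2x2(20, 80, 10, 90)
  expect_equal(e$value, 2.25, tolerance = 1e-12)
  expect_equal(log(e$value), 0.8109302162, tolerance = 1e-9)
  expect_equal(e$se, 0.4166666667, tolerance = 1e-9)
  expect_identical(e$scale, "log")
  expect_equal(e$ci_lo, exp(log(2.25) - 1.96 * e$se), tolerance = 1e-12)

  # a*d = b*c -> OR 1
  expect_equal(logor_from_2x2(20, 40, 10, 20)$value, 1, tolerance = 1e-12)

  # 0.5 added to all four cells iff any is zero
  z <- logor_from_2x2(0, 10, 5, 5)
  expect_equal(z$value, (0.5 * 5.5) / (10.5 * 5.5), tolerance = 1e-12)
  expect_match(z$note, "continuity")
  nz <- logor_from_2x2(1, 9, 5, 5)
  expect_equal(nz$value, (1 * 5) / (9 * 5), tolerance = 1e-12)  # uncorrected

  expect_error(logor_from_2x2(0, 0, 5, 5), "margin")
})

test_that("2x2 risk ratios and the proportions route coincide", {
  e <- logrr_from_2x2(20, 80, 10, 90)
  expect_equal(e$value, 2, tolerance = 1e-12)
  expect_equal(e$se, 0.3605551275, tolerance = 1e-9)
  expect_equal(logrr_from_2x2(10, 90, 10, 90)$value, 1, tolerance = 1e-12)

  # p1 = 0.2, p2 = 0.1 with n = 100/100 reconstructs the same table
  row <- as_es_dataset(data.frame(study_id = "s", p_event1 = 0.2,
                                  p_event2 = 0.1, n1 = 100, n2 = 100))
  cs <- enumerate_candidates(row[1, ], "RR")
  prop <- cs$candidates[[which(cs$routes_available == "props")]]
  expect_equal(prop$value, e$value, tolerance = 1e-12)
  expect_equal(prop$se, e$se, tolerance = 1e-12)
})

test_that("incidence rates give lnIRR with 1/e1 + 1/e2 variance", {
  e <- logirr_from_rates(30, 100, 20, 100)
  expect_equal(e$value, 1.5, tolerance = 1e-12)
  expect_equal(e$se, 0.2886751346, tolerance = 1e-9)
  expect_equal(logirr_from_rates(10, 50, 20, 100)$value, 1, tolerance = 1e-12)
  z <- logirr_from_rates(0, 100, 20, 100)
  expect_equal(z$value, 0.025, tolerance = 1e-12)
  expect_error(logirr_from_rates(0, 100, 0, 100), "undefined")
  expect_error(logirr_from_rates(10, 0, 5, 100), "person-time")
})

test_that("reported ratios rebuild the log-scale SE from the CI", {
  ci <- exp(log(2.25) + c(-1, 1) * 1.96 * 0.4166667)
  e <- ratio_from_reported(2.25, ci[1], ci[2], which = "OR")
  expect_equal(e$se, 0.4166667, tolerance = 1e-9)
  expect_identical(e$route, "or_ci")
  e1 <- ratio_from_reported(1, 0.5, 2, which = "OR")
  expect_equal(e1$se, 0.3536465207, tolerance = 1e-9)
  expect_error(ratio_from_reported(2.25, 2.5, 5, which = "OR"), "contain")
  expect_identical(ratio_from_reported(1.5, 1.1, 2.1, which = "IRR")$route, "irr_ci")
  expect_identical(ratio_from_reported(log_value = 0.8, log_se = 0.4)$route,
                   "logor_se")
})

test_that("d <-> lnOR conversions are exact inverses", {
  d <- d_from_means(103, 100, 10, 10, 50, 50)
  or <- logor_from_d(d)
  expect_equal(log(or$value), 0.5441398093, tolerance = 1e-9)
  expect_equal(logor_from_d(d, "cox")$value, exp(1.65 * 0.3), tolerance = 1e-12)
  expect_equal(logor_from_d(d_from_means(7, 7, 1, 1, 10, 10))$value, 1)
  for (m in c("hh", "cox")) {
    back <- d_from_logor(logor_from_d(d, m), m)
    expect_lt(abs(back$value - d$value), 1e-12)
    expect_lt(abs(back$se - d$se), 1e-12)
  }
})

test_that("all six OR-to-RR methods exist and behave at their anchors", {
  expect_length(es_or_to_rr_methods(), 6)
  or <- logor_from_2x2(20, 80, 10, 90)   # OR 2.25
  zy <- rr_from_or(or, baseline_risk = 0.1, method = "zhang_yu")
  expect_equal(zy$value, 2, tolerance = 1e-9)
  expect_equal(rr_from_or(or, method = "rare_disease")$value, 2.25,
               tolerance = 1e-12)
  expect_equal(rr_from_or(or, method = "sqrt_or")$value, sqrt(2.25),
               tolerance = 1e-12)
  # every method maps OR = 1 to RR = 1
  one <- ratio_from_reported(1, 0.5, 2, which = "OR")
  for (m in es_or_to_rr_methods()) {
    rr <- rr_from_or(one, baseline_risk = 0.3, method = m, n1 = 100, n2 = 100,
                     median_baseline = 0.2)
    expect_equal(rr$value, 1, tolerance = 1e-9)
  }
  expect_error(rr_from_or(or, method = "zhang_yu"), "baseline_risk")
  expect_error(rr_from_or(or, method = "zhang_yu_median"), "median")
  # the 2x2-reconstruction method agrees with Zhang-Yu (both are exact
  # odds-to-risk maps)
  tb <- rr_from_or(or, baseline_risk = 0.1, method = "two_by_two",
                   n1 = 100, n2 = 100)
  expect_equal(tb$value, zy$value, tolerance = 1e-9)
})

test_that("RR to OR inverts the Zhang-Yu relation", {
  or <- logor_from_2x2(20, 80, 10, 90)
  rr <- rr_from_or(or, baseline_risk = 0.1, method = "zhang_yu")
  back <- or_from_rr(rr, baseline_risk = 0.1)
  expect_equal(back$value, or$value, tolerance = 1e-9)
  big <- ratio_from_reported(6, 4, 9, which = "RR")
  expect_error(or_from_rr(big, 0.2), ">= 1")
})

test_that("NNT routes agree with risk-difference arithmetic", {
  e <- nnt_from_risks(0.2, 0.1, 100, 100)
  expect_equal(e$value, 10, tolerance = 1e-12)
  expect_identical(e$scale, "identity")
  d <- d_from_means(103, 100, 10, 10, 50, 50)
  f <- nnt_from_d(d, cer = 0.2)
  expect_equal(f$value, 10.63380333, tolerance = 1e-7)
  expect_error(nnt_from_risks(0.2, 0.2, 100, 100), "infinite NNT")
  o <- nnt_from_or(logor_from_2x2(20, 80, 10, 90), baseline_risk = 0.1)
  # Zhang-Yu RR = 2 at p0 = 0.1 -> implied risks 0.2 vs 0.1 -> NNT 10
  expect_equal(o$value, 10, tolerance = 1e-9)
  # non-significant risk difference: CI reported missing, value still present
  ns <- nnt_from_risks(0.22, 0.2, 50, 50)
  expect_true(is.na(ns$ci_lo))
  expect_match(ns$note, "spans 0")
})

test_that("group swap inverts OR, RR and IRR exactly", {
  or1 <- logor_from_2x2(20, 80, 10, 90)
  or2 <- logor_from_2x2(10, 90, 20, 80)
  expect_equal(log(or1$value), -log(or2$value), tolerance = 1e-12)
  rr1 <- logrr_from_2x2(20, 80, 10, 90)
  rr2 <- logrr_from_2x2(10, 90, 20, 80)
  expect_equal(log(rr1$value), -log(rr2$value), tolerance = 1e-12)
  ir1 <- logirr_from_rates(30, 100, 20, 150)
  ir2 <- logirr_from_rates(20, 150, 30, 100)
  expect_equal(log(ir1$value), -log(ir2$value), tolerance = 1e-12)
})

test_that("OR lies farther from 1 than RR, and lnOR increases in a", {
  set.seed(11)
  for (i in 1:25) {
    a <- sample(1:50, 1); b <- sample(1:50, 1)
    c_ <- sample(1:50, 1); d_ <- sample(1:50, 1)
    or <- log(logor_from_2x2(a, b, c_, d_)$value)
    rr <- log(logrr_from_2x2(a, b, c_, d_)$value)
    expect_true(abs(or) >= abs(rr) - 1e-12)
    expect_true(or == 0 || sign(or) == sign(rr) || rr == 0)
  }
  lnors <- sapply(5:30, function(a) log(logor_from_2x2(a, 100 - a, 10, 90)$value))
  expect_true(all(diff(lnors) > 0))
})

test_that("OR from a 2x2 agrees with an independent implementation", {
  skip_if_not_installed("metafor")
  es <- metafor::escalc(measure = "OR", ai = 20, bi = 80, ci = 10, di = 90)
  e <- logor_from_2x2(20, 80, 10, 90)
  expect_equal(log(e$value), as.numeric(es$yi), tolerance = 1e-10)
  expect_equal(e$se^2, as.numeric(es$vi), tolerance = 1e-10)
})
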