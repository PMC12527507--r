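# Expected values below were frozen from direct evaluation of the stated
# formulas with base R distribution functions, independently of the package.

test_that("d from means matches hand-evaluated pooled-SD formula", {
  e <- d_from_means(103, 100, 10, 10, 50, 50)
  expect_equal(e$value, 0.3, tolerance = 1e-10)
  expect_equal(e$se, 0.2011218536, tolerance = 1e-8)
  expect_equal(e$df_like, 98)
  expect_equal(e$ci_lo, 0.3 - 1.96 * e$se)

  e2 <- d_from_means(5, 3, 2, 4, 10, 10)
  expect_equal(e2$value, 0.632455532, tolerance = 1e-8)
  expect_equal(e2$se^2, 0.21, tolerance = 1e-10)

  expect_equal(d_from_means(7, 7, 1, 1, 10, 10)$value, 0)
  expect_error(d_from_means(1, 2, 1, 1, 1, 5), ">= 2")
  expect_error(d_from_means(1, 2, 0, 1, 10, 10), "> 0")
})

test_that("moments are reconstructed from SE and CI precision", {
  expect_equal(moments_from_precision(10, se = 2, n = 25)$sd, 10)
  mp <- moments_from_precision(10, ci_lo = 6.08, ci_up = 13.92, n = 25)
  expect_equal(mp$se, 2, tolerance = 1e-12)
  expect_equal(mp$sd, 10, tolerance = 1e-12)
  expect_error(moments_from_precision(10, ci_lo = 5, ci_up = 5, n = 25), "width")
})

test_that("test statistics convert to d, with direction enforced", {
  expect_equal(d_from_test_stat("t", 2, 50, 50)$value, 0.4, tolerance = 1e-12)
  expect_equal(d_from_test_stat("f", 4, 50, 50, "positive")$value, 0.4,
               tolerance = 1e-12)
  expect_equal(d_from_test_stat("f", 4, 50, 50, "negative")$value, -0.4,
               tolerance = 1e-12)
  expect_equal(d_from_test_stat("p", 0.05, 50, 50, "positive")$value,
               0.3968934909, tolerance = 1e-8)
  # eta-squared route is the algebraic inverse of eta = d^2/(d^2+4)
  expect_equal(d_from_test_stat("eta2", 0.09 / 4.09, 50, 50, "positive")$value,
               0.3, tolerance = 1e-10)
  expect_error(d_from_test_stat("f", 4, 50, 50), "direction required")
  expect_error(d_from_test_stat("p", 0.05, 50, 50, "unspecified"),
               "direction required")
  # variance matches the means-route variance formula
  expect_equal(d_from_test_stat("t", 2, 50, 50)$se,
               sqrt(100 / 2500 + 0.16 / 200), tolerance = 1e-12)
})

test_that("quantile summaries give Luo means and Wan SDs", {
  mq <- moments_from_quantiles(med = 10, q1 = 8, q3 = 12, n = 25)
  expect_equal(mq$mean, 10, tolerance = 1e-12)   # symmetric quartiles
  expect_equal(mq$sd, 3.144472437, tolerance = 1e-8)
  expect_identical(mq$scenario, "iqr_only")

  # asymmetric case: the weighted mean leans toward the quartile midpoint
  mq2 <- moments_from_quantiles(med = 10, q1 = 9, q3 = 14, n = 25)
  w <- 0.7 + 0.39 / 25
  expect_equal(mq2$mean, w * 11.5 + (1 - w) * 10, tolerance = 1e-12)

  rng <- moments_from_quantiles(med = 10, min = 2, max = 18, n = 25)
  expect_equal(rng$sd, 16 / (2 * qnorm((25 - 0.375) / 25.25)), tolerance = 1e-12)

  both <- moments_from_quantiles(med = 10, q1 = 8, q3 = 12, min = 2, max = 18,
                                 n = 25)
  expect_equal(both$sd, (rng$sd + mq$sd) / 2, tolerance = 1e-12)

  expect_error(moments_from_quantiles(med = 10, q1 = 12, q3 = 8, n = 25),
               "ordering")
  expect_error(moments_from_quantiles(med = 10, q1 = 8, q3 = 12, n = 4), "n >= 5")
  # q1 = q3 collapses the SD and errors downstream
  degenerate <- moments_from_quantiles(med = 10, q1 = 10, q3 = 10, n = 25)
  expect_equal(degenerate$sd, 0)
  expect_error(d_from_means(10, 9, degenerate$sd, 1, 25, 25), "> 0")
})

test_that("change-score d reduces to the means formula on change scores", {
  # sd_pre = sd_post = 10, r = 0.5 -> change SD 10 per group
  e <- d_from_change(m1 = 13, m2 = 10, pre_m1 = 10, pre_m2 = 10,
                     sd1 = 10, sd2 = 10, pre_sd1 = 10, pre_sd2 = 10,
                     r_prepost = 0.5, n1 = 50, n2 = 50)
  expect_equal(e$value, 0.3, tolerance = 1e-12)
  expect_identical(e$route, "change_scores")
  # r = 0: Pythagorean change SD
  e0 <- d_from_change(10 + sqrt(200), 10, 10, 10, 10, 10, 10, 10, 0, 50, 50)
  expect_equal(e0$value, 1, tolerance = 1e-12)
  expect_error(d_from_change(13, 10, 10, 10, 10, 10, 10, 10, NULL, 50, 50),
               "r_prepost")
  expect_error(d_from_change(13, 10, 10, 10, 10, 10, 10, 10, 1, 50, 50),
               "correlation too close to 1")
})

test_that("ANCOVA-adjusted means standardize against the supplied pooled SD", {
  e <- d_from_ancova(10.3, 10.0, 1.0, 50, 50)
  expect_equal(e$value, 0.3, tolerance = 1e-12)
  expect_identical(e$route, "ancova_means")
  expect_equal(d_from_ancova(5, 5, 2, 20, 20)$value, 0)
  expect_error(d_from_ancova(10.3, 10, 0, 50, 50), "> 0")
})

test_that("Hedges' correction applies J = 1 - 3/(4 df - 1)", {
  d <- d_from_means(103, 100, 10, 10, 50, 50)
  g <- hedges_correction(d)
  expect_equal(hedges_j(98), 0.9923273657, tolerance = 1e-9)
  expect_equal(g$value, 0.2976982097, tolerance = 1e-8)
  expect_identical(g$measure, "G")
  expect_identical(g$route, d$route)
  expect_equal(g$se, hedges_j(98) * d$se, tolerance = 1e-12)

  # J in (0,1), increasing in df, g -> d in the large-df limit
  dfs <- c(2, 5, 10, 50, 100, 1000, 1e4)
  js <- hedges_j(dfs)
  expect_true(all(js > 0 & js < 1))
  expect_true(all(diff(js) > 0))
  expect_lt(abs(hedges_j(1e4) - 1), 1e-3)

  d$df_like <- NA_real_
  expect_error(hedges_correction(d), "degrees of freedom")
})

test_that("mean differences carry the exact SE from moments or precision", {
  e <- md_from_means(103, 100, 10, 10, 50, 50)
  expect_equal(e$value, 3)
  expect_equal(e$se, 2, tolerance = 1e-12)
  r <- md_from_reported(3, ci_lo = -0.92, ci_up = 6.92)
  expect_equal(r$se, 2, tolerance = 1e-12)
  expect_identical(r$route, "md_ci")
  expect_identical(md_from_reported(3, md_se = 1.5)$route, "md_se")
  expect_equal(md_from_means(7, 7, 2, 2, 30, 30)$value, 0)
})

test_that("swapping groups exactly negates d, g and MD", {
  cases <- list(c(103, 100, 10, 12, 50, 40), c(5, 3, 2, 4, 10, 10),
                c(-1, 4, 3, 3, 25, 35))
  for (cs in cases) {
    a <- d_from_means(cs[1], cs[2], cs[3], cs[4], cs[5], cs[6])
    b <- d_from_means(cs[2], cs[1], cs[4], cs[3], cs[6], cs[5])
    expect_equal(a$value, -b$value, tolerance = 1e-12)
    expect_equal(hedges_correction(a)$value, -hedges_correction(b)$value,
                 tolerance = 1e-12)
    ma <- md_from_means(cs[1], cs[2], cs[3], cs[4], cs[5], cs[6])
    mb <- md_from_means(cs[2], cs[1], cs[4], cs[3], cs[6], cs[5])
    expect_equal(ma$value, -mb$value, tolerance = 1e-12)
  }
})

test_that("d and g agree with an independent meta-analysis implementation", {
  skip_if_not_installed("metafor")
  es <- metafor::escalc(measure = "SMD", m1i = 103, m2i = 100, sd1i = 10,
                        sd2i = 10, n1i = 50, n2i = 50)
  g <- hedges_correction(d_from_means(103, 100, 10, 10, 50, 50))
  # escalc uses the exact gamma-ratio J; the rational approximation agrees
  # to ~1e-5 at df = 98
  expect_equal(g$value, as.numeric(es$yi), tolerance = 1e-4)
  # variance conventions differ slightly (J^2-scaled d variance here vs the
  # d^2 term evaluated at g there): agreement to ~2%
  expect_equal(g$se^2, as.numeric(es$vi), tolerance = 0.02)
})
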