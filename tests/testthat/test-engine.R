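test_that("candidates are enumerated once per applicable route, in registry order", {
  d <- 0.3
  t <- d / sqrt(1 / 50 + 1 / 50)
  row <- as_es_dataset(data.frame(
    study_id = "s", n1 = 50, n2 = 50, m1 = 103, m2 = 100, sd1 = 10, sd2 = 10,
    t_value = t, p_value = 2 * pt(-abs(t), 98), es_direction = "positive"))
  cs <- enumerate_candidates(row[1, ], "G")
  expect_identical(cs$routes_available, c("means_sd", "t", "p"))
  expect_length(cs$candidates, 3)
  vals <- sapply(cs$candidates, function(e) e$value)
  # t was constructed from the same data: exact agreement; p inverts through
  # the t quantile, agreeing to numerical precision
  expect_lt(abs(vals[1] - vals[2]), 1e-12)
  expect_lt(abs(vals[1] - vals[3]), 1e-8)
})

test_that("an empty row yields no candidates plus an explanatory note", {
  row <- as_es_dataset(data.frame(study_id = "s1"))
  cs <- enumerate_candidates(row[1, ], "D")
  expect_length(cs$candidates, 0)
  expect_identical(cs$routes_available, character(0))
  expect_match(paste(cs$notes, collapse = ";"), "no applicable input data")
})

test_that("route failures become notes, never errors, and the route stays listed", {
  # direction unspecified blocks signless routes with a pointer
  row <- as_es_dataset(data.frame(study_id = "s", f_value = 4, n1 = 50, n2 = 50))
  cs <- enumerate_candidates(row[1, ], "D")
  expect_length(cs$candidates, 0)
  expect_match(paste(cs$notes, collapse = ";"), "direction required")
  # a computable route that errors (q1 = q3) is available but estimate-less
  row2 <- as_es_dataset(data.frame(study_id = "s", med1 = 10, q1_1 = 10,
                                   q3_1 = 10, med2 = 9, q1_2 = 8, q3_2 = 10,
                                   n1 = 25, n2 = 25))
  cs2 <- enumerate_candidates(row2[1, ], "D")
  expect_identical(cs2$routes_available, "med_iqr")
  expect_length(cs2$candidates, 0)
  expect_match(paste(cs2$notes, collapse = ";"), "med_iqr")
})

test_that("selection honors hierarchy, predefined order, and extremes", {
  row <- as_es_dataset(data.frame(
    study_id = "s", n1 = 50, n2 = 50, t_value = 1.5, m1 = 103, m2 = 100,
    sd1 = 10, sd2 = 10))
  cs <- enumerate_candidates(row[1, ], "G")
  sel <- select_main(cs, "hierarchy", hierarchy = "means_sd > t > p")
  expect_identical(sel$route_used, "means_sd")
  sel2 <- select_main(cs, "hierarchy", hierarchy = "t > means_sd")
  expect_identical(sel2$route_used, "t")
  expect_identical(select_main(cs, "auto")$route_used, "means_sd")

  # smallest/largest compare absolute deviation from the null
  a <- es_estimate("D", 0.3, 0.1, "means_sd")
  b <- es_estimate("D", -0.4, 0.1, "t")
  cs2 <- cand_set(a, b)
  expect_equal(select_main(cs2, "smallest")$selected$value, 0.3)
  expect_equal(select_main(cs2, "largest")$selected$value, -0.4)

  # single candidate wins under every strategy
  cs3 <- cand_set(a)
  for (st in c("auto", "smallest", "largest")) {
    expect_equal(select_main(cs3, st)$selected$value, 0.3)
  }

  # hierarchy covering no available route falls back to auto with a warning
  expect_warning(f <- select_main(cs, "hierarchy", hierarchy = "rates"),
                 "falling back")
  expect_identical(f$route_used, "means_sd")
  expect_error(select_main(cs, "hierarchy"), "requires a hierarchy")
  expect_error(parse_hierarchy("means_sd > means_sd"), "duplicate")
  expect_error(parse_hierarchy("not_a_route"), "unknown route")
})

test_that("selection on ratio measures uses the log scale", {
  near <- es_estimate("OR", log(1.2), 0.2, "2x2")
  far <- es_estimate("OR", log(0.5), 0.2, "or_ci")   # |ln 0.5| > |ln 1.2|
  cs <- cand_set(near, far)
  expect_equal(select_main(cs, "smallest")$selected$value, 1.2)
  expect_equal(select_main(cs, "largest")$selected$value, 0.5)
})

test_that("convert_df returns one structured row per input row", {
  d <- 0.3
  t2 <- d / sqrt(1 / 50 + 1 / 50)
  df <- data.frame(
    study_id = c("s1", "s2", "s3"),
    n1 = c(50, 50, NA), n2 = c(50, 50, NA),
    m1 = c(103, 103, NA), m2 = c(100, 100, NA),
    sd1 = c(10, 10, NA), sd2 = c(10, 10, NA),
    t_value = c(NA, t2, NA),
    r_value = c(NA, NA, 0.5), n_r = c(NA, NA, 103))
  res <- suppressMessages(convert_df(df, "D"))
  expect_s3_class(res, "es_converted")
  expect_equal(nrow(res), 3)
  expect_identical(res$route_used, c("means_sd", "means_sd", "r_n"))
  expect_equal(res$n_candidates, c(1L, 2L, 1L))
  # consistency columns only where >= 2 candidates
  expect_true(is.na(res$ci_overlap_pct[1]))
  expect_false(is.na(res$ci_overlap_pct[2]))
  expect_equal(res$ci_overlap_pct[2], 100)
  expect_equal(res$es_diff[2], 0, tolerance = 1e-12)

  # determinism: the same call is bit-identical
  res2 <- suppressMessages(convert_df(df, "D"))
  expect_identical(as.data.frame(res), as.data.frame(res2))
})

test_that("self-consistent 2x2 and OR+CI inputs agree within tolerance", {
  e <- logor_from_2x2(20, 80, 10, 90)
  df <- data.frame(study_id = "s1", a = 20, b = 80, c = 10, d_cell = 90,
                   or_value = e$value, or_ci_lo = e$ci_lo, or_ci_up = e$ci_up)
  res <- convert_df(df, "OR")
  expect_equal(res$n_candidates, 2L)
  expect_lt(res$es_diff, 1e-6)
  expect_equal(res$ci_overlap_pct, 100, tolerance = 1e-6)
  expect_identical(res$flags, "")
})

test_that("row validation problems surface as notes and bad routes fail softly", {
  df <- data.frame(study_id = c("s1", "s2"),
                   m1 = c(103, 103), m2 = c(100, 100),
                   sd1 = c(-2, 10), sd2 = c(10, 10),
                   n1 = c(50, 50), n2 = c(50, 50))
  res <- suppressMessages(convert_df(df, "D"))
  expect_true(is.na(res$value[1]))
  expect_match(res$note[1], "sd1")
  expect_equal(res$value[2], 0.3, tolerance = 1e-12)
})

test_that("the multi-method defaults are switchable through options", {
  df <- data.frame(study_id = "s1", a = 20, b = 80, c = 10, d_cell = 90)
  hh <- convert_df(df, "D")
  cox <- convert_df(df, "D", options = es_options(d_to_or = "cox"))
  expect_identical(hh$method_used, "hh")
  expect_identical(cox$method_used, "cox")
  expect_equal(hh$value * pi / sqrt(3), cox$value * 1.65, tolerance = 1e-9)
})
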