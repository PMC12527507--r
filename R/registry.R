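# The formula registry: every (measure, route, method) triple the engine can
# compute, with its required columns, its priority class and its compute
# function. The registry is data - counts, route lists and the shipped
# hierarchies all derive from it.

.es_env <- new.env(parent = emptyenv())

# priority classes, highest first: direct raw statistics, reported estimates
# with precision, test statistics, then approximations (order-statistic
# reconstructions and cross-measure conversions)
CLASS_RANK <- c(raw = 1L, reported = 2L, test_stat = 3L, approx = 4L)

moment_needs_full <- function(route) {
  switch(route,
    means_sd = c("m1", "m2", "sd1", "sd2", "n1", "n2"),
    means_se = c("m1", "m2", "se1", "se2", "n1", "n2"),
    means_ci = c("m1", "m1_ci_lo", "m1_ci_up", "m2", "m2_ci_lo", "m2_ci_up", "n1", "n2"),
    med_iqr = c("med1", "q1_1", "q3_1", "med2", "q1_2", "q3_2", "n1", "n2"),
    med_range = c("med1", "min1", "max1", "med2", "min2", "max2", "n1", "n2"),
    med_iqr_range = c("med1", "q1_1", "q3_1", "min1", "max1",
                      "med2", "q1_2", "q3_2", "min2", "max2", "n1", "n2"),
    stop_es("unknown moment route '%s'", route))
}

moment_needs_sd <- function(route) {
  switch(route,
    means_sd = c("sd1", "sd2", "n1", "n2"),
    means_se = c("se1", "se2", "n1", "n2"),
    means_ci = c("m1_ci_lo", "m1_ci_up", "m2_ci_lo", "m2_ci_up", "n1", "n2"),
    moment_needs_full(route))
}

# reconstruct (m, sd) per group from whichever summary the route uses
moments_from_row <- function(row, route) {
  n1 <- num1(row, "n1"); n2 <- num1(row, "n2")
  grab <- function(g) {
    switch(route,
      means_sd = list(mean = num1(row, paste0("m", g)),
                      sd = num1(row, paste0("sd", g))),
      means_se = {
        mp <- moments_from_precision(num1(row, paste0("m", g)),
                                     se = num1(row, paste0("se", g)),
                                     n = if (g == 1) n1 else n2)
        list(mean = mp$mean, sd = mp$sd)
      },
      means_ci = {
        mp <- moments_from_precision(num1(row, paste0("m", g)),
                                     ci_lo = num1(row, paste0("m", g, "_ci_lo")),
                                     ci_up = num1(row, paste0("m", g, "_ci_up")),
                                     n = if (g == 1) n1 else n2)
        list(mean = mp$mean, sd = mp$sd)
      },
      med_iqr = , med_range = , med_iqr_range = {
        scen <- c(med_iqr = "iqr_only", med_range = "range_only",
                  med_iqr_range = "both")[[route]]
        q <- function(stub) {
          v <- num1(row, stub)
          if (is.na(v)) NULL else v
        }
        mq <- moments_from_quantiles(
          med = num1(row, paste0("med", g)),
          q1 = if (scen != "range_only") q(paste0("q1_", g)) else NULL,
          q3 = if (scen != "range_only") q(paste0("q3_", g)) else NULL,
          min = if (scen != "iqr_only") q(paste0("min", g)) else NULL,
          max = if (scen != "iqr_only") q(paste0("max", g)) else NULL,
          n = if (g == 1) n1 else n2, scenario = scen)
        list(mean = mq$mean, sd = mq$sd)
      })
  }
  g1 <- grab(1); g2 <- grab(2)
  list(m1 = g1$mean, sd1 = g1$sd, m2 = g2$mean, sd2 = g2$sd, n1 = n1, n2 = n2)
}

sd_from_row <- function(row, route) {
  n1 <- num1(row, "n1"); n2 <- num1(row, "n2")
  if (route == "means_sd") {
    list(sd1 = num1(row, "sd1"), sd2 = num1(row, "sd2"), n1 = n1, n2 = n2)
  } else if (route == "means_se") {
    list(sd1 = num1(row, "se1") * sqrt(n1), sd2 = num1(row, "se2") * sqrt(n2),
         n1 = n1, n2 = n2)
  } else if (route == "means_ci") {
    w1 <- num1(row, "m1_ci_up") - num1(row, "m1_ci_lo")
    w2 <- num1(row, "m2_ci_up") - num1(row, "m2_ci_lo")
    if (w1 <= 0 || w2 <= 0) stop_es("CI width must be positive")
    list(sd1 = w1 / (2 * Z95) * sqrt(n1), sd2 = w2 / (2 * Z95) * sqrt(n2),
         n1 = n1, n2 = n2)
  } else {
    mo <- moments_from_row(row, route)
    list(sd1 = mo$sd1, sd2 = mo$sd2, n1 = n1, n2 = n2)
  }
}

MED_NOTE <- "moments estimated from order statistics (normality assumed)"

# ---- per-route base builders ------------------------------------------------

build_d <- function(row, ctx, route) {
  switch(route,
    means_sd = , means_se = , means_ci = , med_iqr = , med_range = ,
    med_iqr_range = {
      mo <- moments_from_row(row, route)
      est <- d_from_means(mo$m1, mo$m2, mo$sd1, mo$sd2, mo$n1, mo$n2,
                          route = route)
      if (startsWith(route, "med")) est$note <- MED_NOTE
      est
    },
    change_scores = d_from_change(
      num1(row, "m1"), num1(row, "m2"), num1(row, "pre_m1"), num1(row, "pre_m2"),
      num1(row, "sd1"), num1(row, "sd2"), num1(row, "pre_sd1"), num1(row, "pre_sd2"),
      num1(row, "r_prepost"), num1(row, "n1"), num1(row, "n2")),
    ancova_means = d_from_ancova(
      num1(row, "adj_m1"), num1(row, "adj_m2"), num1(row, "adj_sd_pooled"),
      num1(row, "n1"), num1(row, "n2")),
    t = d_from_test_stat("t", num1(row, "t_value"), num1(row, "n1"),
                         num1(row, "n2"), row$es_direction),
    f = d_from_test_stat("f", num1(row, "f_value"), num1(row, "n1"),
                         num1(row, "n2"), row$es_direction),
    p = d_from_test_stat("p", num1(row, "p_value"), num1(row, "n1"),
                         num1(row, "n2"), row$es_direction),
    eta = d_from_test_stat("eta2", num1(row, "eta_sq"), num1(row, "n1"),
                           num1(row, "n2"), row$es_direction),
    stop_es("no d builder for route '%s'", route))
}

build_or <- function(row, ctx, route) {
  switch(route,
    "2x2" = logor_from_2x2(num1(row, "a"), num1(row, "b"),
                           num1(row, "c"), num1(row, "d_cell")),
    props = {
      n1 <- num1(row, "n1"); n2 <- num1(row, "n2")
      p1 <- num1(row, "p_event1"); p2 <- num1(row, "p_event2")
      est <- logor_from_2x2(p1 * n1, (1 - p1) * n1, p2 * n2, (1 - p2) * n2)
      est$route <- "props"
      est
    },
    or_ci = ratio_from_reported(num1(row, "or_value"), num1(row, "or_ci_lo"),
                                num1(row, "or_ci_up"), which = "OR"),
    logor_se = ratio_from_reported(log_value = num1(row, "logor_value"),
                                   log_se = num1(row, "logor_se"), which = "OR"),
    stop_es("no OR builder for route '%s'", route))
}

binary_group_sizes <- function(row, route) {
  if (route == "2x2") {
    list(n1 = num1(row, "a") + num1(row, "b"),
         n2 = num1(row, "c") + num1(row, "d_cell"))
  } else {
    n1 <- num1(row, "n1"); n2 <- num1(row, "n2")
    list(n1 = if (is.na(n1)) NULL else n1, n2 = if (is.na(n2)) NULL else n2)
  }
}

# ---- registry construction --------------------------------------------------

D_RAW_ROUTES <- c("means_sd", "change_scores")
D_REPORTED_ROUTES <- c("means_se", "means_ci", "ancova_means")
D_TEST_ROUTES <- c("t", "f", "p", "eta")
D_MED_ROUTES <- c("med_iqr", "med_iqr_range", "med_range")
# every route producing a D from within the SMD family, hierarchy order
D_FAMILY_ROUTES <- c(D_RAW_ROUTES, D_REPORTED_ROUTES, D_TEST_ROUTES, D_MED_ROUTES)
OR_DIRECT_ROUTES <- c("2x2", "props", "or_ci", "logor_se")

d_route_class <- function(route) {
  if (route %in% D_RAW_ROUTES) "raw"
  else if (route %in% D_REPORTED_ROUTES) "reported"
  else if (route %in% D_TEST_ROUTES) "test_stat"
  else "approx"
}

d_route_needs <- function(route) {
  switch(route,
    means_sd = , means_se = , means_ci = , med_iqr = , med_range = ,
    med_iqr_range = moment_needs_full(route),
    change_scores = c("m1", "m2", "sd1", "sd2", "pre_m1", "pre_m2",
                      "pre_sd1", "pre_sd2", "r_prepost", "n1", "n2"),
    ancova_means = c("adj_m1", "adj_m2", "adj_sd_pooled", "n1", "n2"),
    t = c("t_value", "n1", "n2"),
    f = c("f_value", "n1", "n2", "es_direction"),
    p = c("p_value", "n1", "n2", "es_direction"),
    eta = c("eta_sq", "n1", "n2", "es_direction"),
    stop_es("no needs table for route '%s'", route))
}

or_route_needs <- function(route) {
  switch(route,
    "2x2" = c("a", "b", "c", "d_cell"),
    props = c("p_event1", "p_event2", "n1", "n2"),
    or_ci = c("or_value", "or_ci_lo", "or_ci_up"),
    logor_se = c("logor_value", "logor_se"),
    stop_es("no needs table for route '%s'", route))
}

build_registry <- function() {
  E <- list()
  add <- function(measure, route, class, needs, fn, method = NA_character_) {
    E[[length(E) + 1L]] <<- list(measure = measure, route = route,
                                 method = method, class = class,
                                 needs = unique(needs), fn = fn)
  }

  ## --- D and G: the SMD family, then cross-measure conversions -------------
  for (rt in D_FAMILY_ROUTES) {
    local({
      rt <- rt
      add("D", rt, d_route_class(rt), d_route_needs(rt),
          function(row, ctx) build_d(row, ctx, rt))
      add("G", rt, d_route_class(rt), d_route_needs(rt),
          function(row, ctx) hedges_correction(build_d(row, ctx, rt)))
    })
  }
  # d (and g) from a reported correlation
  add("D", "r_n", "approx", c("r_value", "n_r"),
      function(row, ctx) d_from_r(num1(row, "r_value"), num1(row, "n_r")))
  add("G", "r_n", "approx", c("r_value", "n_r"),
      function(row, ctx) hedges_correction(d_from_r(num1(row, "r_value"),
                                                    num1(row, "n_r"))))
  # d (and g) back-converted from binary-outcome inputs
  for (rt in OR_DIRECT_ROUTES) {
    for (mth in c("hh", "cox")) {
      local({
        rt <- rt; mth <- mth
        dfn <- function(row, ctx) {
          ns <- binary_group_sizes(row, rt)
          d_from_logor(build_or(row, ctx, rt), method = mth,
                       n1 = ns$n1, n2 = ns$n2)
        }
        add("D", rt, "approx", or_route_needs(rt), dfn, method = mth)
        gneeds <- or_route_needs(rt)
        if (rt %in% c("or_ci", "logor_se")) gneeds <- c(gneeds, "n1", "n2")
        add("G", rt, "approx", gneeds,
            function(row, ctx) hedges_correction(dfn(row, ctx)), method = mth)
      })
    }
  }

  ## --- MD -------------------------------------------------------------------
  for (rt in c("means_sd", "change_scores")) {
    local({
      rt <- rt
      if (rt == "means_sd") {
        add("MD", rt, "raw", moment_needs_full(rt), function(row, ctx) {
          mo <- moments_from_row(row, rt)
          md_from_means(mo$m1, mo$m2, mo$sd1, mo$sd2, mo$n1, mo$n2, route = rt)
        })
      } else {
        add("MD", rt, "raw", d_route_needs(rt), function(row, ctx) {
          sdc1 <- change_sd(num1(row, "pre_sd1"), num1(row, "sd1"),
                            num1(row, "r_prepost"))
          sdc2 <- change_sd(num1(row, "pre_sd2"), num1(row, "sd2"),
                            num1(row, "r_prepost"))
          if (is.na(num1(row, "r_prepost"))) stop_es("r_prepost is required")
          if (sdc1 <= 1e-12 || sdc2 <= 1e-12) stop_es("change-score SD is 0")
          md_from_means(num1(row, "m1") - num1(row, "pre_m1"),
                        num1(row, "m2") - num1(row, "pre_m2"),
                        sdc1, sdc2, num1(row, "n1"), num1(row, "n2"),
                        route = "change_scores")
        })
      }
    })
  }
  add("MD", "md_se", "reported", c("md_value", "md_se"), function(row, ctx) {
    df <- if (has_val(row, c("n1", "n2"))) num1(row, "n1") + num1(row, "n2") - 2
          else NA_real_
    md_from_reported(num1(row, "md_value"), md_se = num1(row, "md_se"), df = df)
  })
  add("MD", "md_ci", "reported", c("md_value", "md_ci_lo", "md_ci_up"),
      function(row, ctx) {
        df <- if (has_val(row, c("n1", "n2"))) num1(row, "n1") + num1(row, "n2") - 2
              else NA_real_
        md_from_reported(num1(row, "md_value"), ci_lo = num1(row, "md_ci_lo"),
                         ci_up = num1(row, "md_ci_up"), df = df)
      })
  for (rt in c("means_se", "means_ci")) {
    local({
      rt <- rt
      add("MD", rt, "reported", moment_needs_full(rt), function(row, ctx) {
        mo <- moments_from_row(row, rt)
        md_from_means(mo$m1, mo$m2, mo$sd1, mo$sd2, mo$n1, mo$n2, route = rt)
      })
    })
  }
  add("MD", "ancova_means", "reported", d_route_needs("ancova_means"),
      function(row, ctx) {
        md_from_means(num1(row, "adj_m1"), num1(row, "adj_m2"),
                      num1(row, "adj_sd_pooled"), num1(row, "adj_sd_pooled"),
                      num1(row, "n1"), num1(row, "n2"), route = "ancova_means")
      })
  for (rt in D_MED_ROUTES) {
    local({
      rt <- rt
      add("MD", rt, "approx", moment_needs_full(rt), function(row, ctx) {
        mo <- moments_from_row(row, rt)
        est <- md_from_means(mo$m1, mo$m2, mo$sd1, mo$sd2, mo$n1, mo$n2,
                             route = rt)
        est$note <- MED_NOTE
        est
      })
    })
  }

  ## --- OR -------------------------------------------------------------------
  for (rt in OR_DIRECT_ROUTES) {
    local({
      rt <- rt
      add("OR", rt, if (rt %in% c("2x2", "props")) "raw" else "reported",
          or_route_needs(rt), function(row, ctx) build_or(row, ctx, rt))
    })
  }
  add("OR", "rr_ci", "approx",
      c("rr_value", "rr_ci_lo", "rr_ci_up", "baseline_risk"),
      function(row, ctx) {
        rr <- ratio_from_reported(num1(row, "rr_value"), num1(row, "rr_ci_lo"),
                                  num1(row, "rr_ci_up"), which = "RR")
        or_from_rr(rr, num1(row, "baseline_risk"))
      })
  for (rt in D_FAMILY_ROUTES) {
    for (mth in c("hh", "cox")) {
      local({
        rt <- rt; mth <- mth
        add("OR", rt, "approx", d_route_needs(rt),
            function(row, ctx) logor_from_d(build_d(row, ctx, rt), method = mth),
            method = mth)
      })
    }
  }
  for (mth in c("hh", "cox")) {
    local({
      mth <- mth
      add("OR", "r_n", "approx", c("r_value", "n_r"), function(row, ctx) {
        logor_from_d(d_from_r(num1(row, "r_value"), num1(row, "n_r")),
                     method = mth)
      }, method = mth)
    })
  }

  ## --- RR -------------------------------------------------------------------
  add("RR", "2x2", "raw", or_route_needs("2x2"), function(row, ctx) {
    logrr_from_2x2(num1(row, "a"), num1(row, "b"), num1(row, "c"),
                   num1(row, "d_cell"))
  })
  add("RR", "props", "raw", or_route_needs("props"), function(row, ctx) {
    n1 <- num1(row, "n1"); n2 <- num1(row, "n2")
    p1 <- num1(row, "p_event1"); p2 <- num1(row, "p_event2")
    est <- logrr_from_2x2(p1 * n1, (1 - p1) * n1, p2 * n2, (1 - p2) * n2)
    est$route <- "props"
    est
  })
  add("RR", "rr_ci", "reported", c("rr_value", "rr_ci_lo", "rr_ci_up"),
      function(row, ctx) {
        ratio_from_reported(num1(row, "rr_value"), num1(row, "rr_ci_lo"),
                            num1(row, "rr_ci_up"), which = "RR")
      })
  for (rt in c("or_ci", "logor_se")) {
    for (mth in OR_TO_RR_METHODS) {
      local({
        rt <- rt; mth <- mth
        needs <- or_route_needs(rt)
        if (mth %in% c("zhang_yu", "via_smd")) needs <- c(needs, "baseline_risk")
        if (mth == "two_by_two") needs <- c(needs, "baseline_risk", "n1", "n2")
        add("RR", rt, "approx", needs, function(row, ctx) {
          rr_from_or(build_or(row, ctx, rt),
                     baseline_risk = num1(row, "baseline_risk"),
                     method = mth, n1 = num1(row, "n1"), n2 = num1(row, "n2"),
                     median_baseline = ctx$median_baseline)
        }, method = mth)
      })
    }
  }

  ## --- IRR ------------------------------------------------------------------
  add("IRR", "rates", "raw", c("e1", "time1", "e2", "time2"),
      function(row, ctx) {
        logirr_from_rates(num1(row, "e1"), num1(row, "time1"),
                          num1(row, "e2"), num1(row, "time2"))
      })

  ## --- R and Z --------------------------------------------------------------
  for (ms in c("R", "Z")) {
    local({
      ms <- ms
      add(ms, "r_n", "raw", c("r_value", "n_r"), function(row, ctx) {
        z_from_r(num1(row, "r_value"), num1(row, "n_r"), measure = ms)
      })
      for (rt in D_FAMILY_ROUTES) {
        local({
          rt <- rt
          add(ms, rt, "approx", d_route_needs(rt), function(row, ctx) {
            r_from_d(build_d(row, ctx, rt), n1 = num1(row, "n1"),
                     n2 = num1(row, "n2"), measure = ms)
          })
        })
      }
      for (rt in OR_DIRECT_ROUTES) {
        for (mth in OR_TO_R_METHODS) {
          local({
            rt <- rt; mth <- mth
            add(ms, rt, "approx", or_route_needs(rt), function(row, ctx) {
              ns <- binary_group_sizes(row, rt)
              r_from_or(build_or(row, ctx, rt), method = mth,
                        n1 = ns$n1, n2 = ns$n2, measure = ms)
            }, method = mth)
          })
        }
      }
    })
  }

  ## --- VR and CVR -----------------------------------------------------------
  for (rt in c("means_sd", "means_se", "means_ci", D_MED_ROUTES)) {
    local({
      rt <- rt
      cls <- if (rt == "means_sd") "raw"
             else if (rt %in% c("means_se", "means_ci")) "reported" else "approx"
      add("VR", rt, cls, moment_needs_sd(rt), function(row, ctx) {
        s <- sd_from_row(row, rt)
        est <- lnvr_from_moments(s$sd1, s$sd2, s$n1, s$n2, route = rt)
        if (startsWith(rt, "med")) est$note <- MED_NOTE
        est
      })
      add("CVR", rt, cls, moment_needs_full(rt), function(row, ctx) {
        mo <- moments_from_row(row, rt)
        est <- lncvr_from_moments(mo$m1, mo$sd1, mo$m2, mo$sd2, mo$n1, mo$n2,
                                  route = rt)
        if (startsWith(rt, "med")) est$note <- MED_NOTE
        est
      })
    })
  }

  ## --- NNT ------------------------------------------------------------------
  add("NNT", "2x2", "raw", or_route_needs("2x2"), function(row, ctx) {
    a <- num1(row, "a"); b <- num1(row, "b")
    c_ <- num1(row, "c"); d_ <- num1(row, "d_cell")
    nnt_from_risks(a / (a + b), c_ / (c_ + d_), a + b, c_ + d_, route = "2x2")
  })
  add("NNT", "props", "raw", or_route_needs("props"), function(row, ctx) {
    est <- nnt_from_risks(num1(row, "p_event1"), num1(row, "p_event2"),
                          num1(row, "n1"), num1(row, "n2"), route = "props")
    est
  })
  for (rt in c("or_ci", "logor_se")) {
    local({
      rt <- rt
      add("NNT", rt, "approx", c(or_route_needs(rt), "baseline_risk"),
          function(row, ctx) {
            nnt_from_or(build_or(row, ctx, rt), num1(row, "baseline_risk"))
          })
    })
  }
  for (rt in D_FAMILY_ROUTES) {
    local({
      rt <- rt
      add("NNT", rt, "approx", c(d_route_needs(rt), "baseline_risk"),
          function(row, ctx) {
            nnt_from_d(build_d(row, ctx, rt), cer = num1(row, "baseline_risk"))
          })
    })
  }

  E
}

registry_entries <- function() {
  if (is.null(.es_env$registry)) .es_env$registry <- build_registry()
  .es_env$registry
}

#' The formula registry as a table
#'
#' One row per registered (measure, route, method) formula, in priority
#' order within each measure.
#'
#' @param measure Optional measure code to filter on.
#' @return data.frame with columns `measure`, `route`, `method`, `class`,
#'   `needs` (comma-joined required columns).
#' @export
es_registry <- function(measure = NULL) {
  E <- registry_entries()
  df <- do.call(rbind, lapply(E, function(e) {
    data.frame(measure = e$measure, route = e$route, method = e$method,
               class = e$class, needs = paste(e$needs, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(measure)) {
    measure <- match.arg(measure, es_measures())
    df <- df[df$measure == measure, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Input routes registered for a measure
#'
#' @param measure Optional measure code; NULL lists every distinct route id.
#' @return Character vector of route identifiers in priority order.
#' @export
es_routes <- function(measure = NULL) {
  df <- es_registry(measure)
  unique(df$route)
}

#' Main-effect-size selection approaches
#'
#' The three supported ways of picking one main estimate from overlapping
#' inputs: a user-defined hierarchy, the shipped pre-defined hierarchies, or
#' automatic selection of the extreme (smallest/largest) effect for
#' sensitivity analysis.
#'
#' @return Named character vector of length 3.
#' @export
es_selection_approaches <- function() {
  c(hierarchy = "user-defined route hierarchy",
    auto = "pre-defined hierarchy shipped per measure",
    extreme = "automatic selection of the smallest or largest effect")
}

#' Dependence modes for aggregating effect sizes
#'
#' @return Character vector of the three modes accepted by [aggregate_df()].
#' @export
es_dependence_modes <- function() c("outcomes", "times", "subgroups")

#' Names of the consistency indicators
#'
#' @return Character vector naming the five indicators computed by
#'   [consistency_indicators()].
#' @export
es_consistency_indicator_names <- function() {
  c("es_min", "es_max", "es_diff", "es_sd", "ci_overlap_pct")
}

#' Registry-scale counts
#'
#' Programmatic access to the size of the computation registry, so the
#' package's capability claims are assertable: number of measures, of
#' registered formulas (measure-route-method triples), of distinct
#' measure-route input combinations, of distinct input routes, plus the
#' cardinalities of the OR-to-RR method set, the consistency-indicator set,
#' the aggregation-mode set and the selection-approach set.
#'
#' @return Named list of integer counts.
#' @export
es_registry_counts <- function() {
  df <- es_registry()
  list(
    n_measures = length(es_measures()),
    n_formulas = nrow(df),
    n_input_combinations = nrow(unique(df[, c("measure", "route")])),
    n_routes = length(unique(df$route)),
    n_or_to_rr_methods = length(es_or_to_rr_methods()),
    n_consistency_indicators = length(es_consistency_indicator_names()),
    n_aggregation_modes = length(es_dependence_modes()),
    n_selection_approaches = length(es_selection_approaches())
  )
}

#' Pre-defined route hierarchy for a measure
#'
#' The shipped priority order over input routes used by
#' `es_selected = "auto"`. Each hierarchy ranks direct raw statistics above
#' reported estimates, above test statistics, above approximations
#' (order-statistic reconstructions, cross-measure conversions). The
#' hierarchies are stored as editable one-route-per-line text files under
#' `inst/hierarchies/`; if a file is absent the order is derived from the
#' registry.
#'
#' @param measure A measure code.
#' @return Character vector of route ids, highest priority first.
#' @export
es_default_hierarchy <- function(measure) {
  measure <- match.arg(measure, es_measures())
  path <- system.file("hierarchies", paste0(measure, ".txt"),
                      package = "esconvert")
  if (nzchar(path) && file.exists(path)) {
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines)) return(lines)
  }
  es_routes(measure)
}
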