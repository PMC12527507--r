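# shared fixture helpers: minimal schema rows built in code

row_means <- function(m1 = 103, m2 = 100, sd1 = 10, sd2 = 10, n1 = 50, n2 = 50,
                      ...) {
  as_es_dataset(data.frame(study_id = "s", m1 = m1, m2 = m2, sd1 = sd1,
                           sd2 = sd2, n1 = n1, n2 = n2, ...,
                           stringsAsFactors = FALSE))
}

row_2x2 <- function(a = 20, b = 80, c = 10, d_cell = 90, ...) {
  as_es_dataset(data.frame(study_id = "s", a = a, b = b, c = c,
                           d_cell = d_cell, ..., stringsAsFactors = FALSE))
}

# candidate set built directly from estimates, for consistency-module tests
cand_set <- function(..., measure = NULL) {
  ests <- list(...)
  measure <- measure %||% ests[[1]]$measure
  structure(list(measure = measure, candidates = ests,
                 routes_available = vapply(ests, function(e) e$route, ""),
                 notes = character(0), selected = NULL,
                 route_used = NA_character_, strategy = NA_character_),
            class = "es_candidates")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
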