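# internal helpers shared across modules

# fixed 95% CI multiplier: the normal quantile is used for every measure so
# that identity- and ratio-scale intervals are built the same way
Z95 <- 1.96

`%||%` <- function(a, b) if (is.null(a)) b else a

# a field "has a value" iff it is present and not NA
has_val <- function(row, cols) {
  all(vapply(cols, function(cl) {
    v <- row[[cl]]
    !is.null(v) && length(v) == 1L && !is.na(v)
  }, logical(1)))
}

num1 <- function(row, col) {
  v <- row[[col]]
  if (is.null(v) || length(v) == 0L) NA_real_ else as.numeric(v[1L])
}

stop_es <- function(...) stop(sprintf(...), call. = FALSE)

warn_es <- function(...) warning(sprintf(...), call. = FALSE)

# numeric first derivative (central difference), used for delta-method SEs of
# nonlinear ratio transforms
num_deriv <- function(f, x, h = 1e-5) (f(x + h) - f(x - h)) / (2 * h)

# evaluate expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
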