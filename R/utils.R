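# internal helpers

assert_finite_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a finite numeric scalar.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

assert_fraction <- function(x, name, open_upper = FALSE) {
  assert_finite_scalar(x, name)
  hi_ok <- if (open_upper) x < 1 else x <= 1
  if (x < 0 || !hi_ok) {
    abort(sprintf("`%s` must lie in [0, 1%s.", name, if (open_upper) ")" else "]"))
  }
  invisible(x)
}

# Sample from a {mean, sd, min} distribution spec (rounded when integer = TRUE)
sample_spec <- function(spec, n = 1L, integer = FALSE) {
  if (is.numeric(spec) && length(spec) == 1L) {
    return(rep(spec, n))
  }
  x <- rnorm(n, mean = spec$mean, sd = spec$sd %||% 0)
  x <- pmax(x, spec$min %||% -Inf)
  if (integer) x <- pmax(round(x), spec$min %||% 0)
  x
}

# seeds derived from a master seed stay below 2^31
derive_seed <- function(seed, k) {
  (as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483629
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
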