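# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_sporeffect <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_boundary = c(TRUE, TRUE)) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_sporeffect(sprintf("'%s' must be a single finite number", name))
  lo_ok <- if (allow_boundary[1]) x >= lower else x > lower
  hi_ok <- if (allow_boundary[2]) x <= upper else x < upper
  if (!lo_ok || !hi_ok)
    stop_sporeffect(sprintf("'%s' = %g is outside its valid range", name, x))
  invisible(x)
}

# pooled empirical logit; the closed-form solution of an intercept-only
# binomial GLM and the test oracle for saturated per-strain fits
pooled_logit <- function(y, n) qlogis(sum(y) / sum(n))

# Halton low-discrepancy sequence in (0,1)^d: deterministic multistart
# locations for the kinetic fit (no RNG involved).
halton_sequence <- function(n, dim) {
  bases <- c(2, 3, 5, 7, 11, 13)[seq_len(dim)]
  vdc <- function(i, base) {
    f <- 1
    r <- 0
    while (i > 0) {
      f <- f / base
      r <- r + f * (i %% base)
      i <- i %/% base
    }
    r
  }
  sapply(bases, function(b) vapply(seq_len(n), vdc, numeric(1), base = b))
}

# set RNG state from an explicit seed without touching callers that rely on
# the global stream when seed is NULL
set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
      stop_sporeffect("'seed' must be a single integer")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}
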