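# Internal helpers shared across modules.

# 95% Wald critical value used throughout (two-sided normal).
Z95 <- 1.959964

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards. seed = NULL leaves the
# global stream untouched (and consumes from it).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Two-sided normal p-value from an effect and its SE; safe at se == 0 and
# floored at the smallest positive double so extreme z-scores never
# underflow to an (invalid) exact zero.
pval_wald <- function(beta, se) {
  p <- pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin)
  p[se == 0 & beta == 0] <- 1
  p
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
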