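# internal helpers shared across modules

# run `code` under a temporary RNG state seeded with `seed`; restores the
# caller's stream so library code never perturbs user-level reproducibility
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a vector of sub-seeds from one master seed without consuming the
# caller's stream; values stay well inside 32-bit integer range
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

zscore_cols <- function(m) {
  mu <- colMeans(m)
  s <- apply(m, 2, stats::sd)
  out <- sweep(m, 2, mu, "-")
  ok <- s > 0
  out[, ok] <- sweep(out[, ok, drop = FALSE], 2, s[ok], "/")
  out[, !ok] <- 0 # zero-variance channel: z-score defined as the zero series
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_pos <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(what, " must be a positive finite scalar", call. = FALSE)
  invisible(x)
}
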