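# Internal helpers shared across modules.

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. Keeps every generator and training routine a
# pure function of its arguments.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic derived seed, kept inside the 32-bit integer range.
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + as.numeric(k) * 8191) %% 2147483629
}

# Row-wise softmax with the usual max-shift for numerical stability.
# max.col avoids the slow apply(); ties.method "first" keeps it deterministic.
softmax_rows <- function(s) {
  m <- s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))]
  e <- exp(s - m)
  e / rowSums(e)
}

softmax_vec <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
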