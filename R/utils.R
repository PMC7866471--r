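# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library calls never perturb user-level randomness.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic substream seeds derived from one root seed, kept < 2^31.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  streams <- c(phantoms = 11L, augment = 23L, weights = 37L,
               batching = 53L, eval = 71L)
  off <- if (is.character(stream)) streams[[stream]] else as.integer(stream)
  as.integer((as.double(seed) * 7919 + off) %% 2147483647)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Concatenate two (H, W, C, N) activation arrays along the channel axis.
cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(length(da) == 4, all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}
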