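# Internal helpers shared across modules.

# Evaluate expr under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards so package functions never disturb the session stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a master seed; keeps results
# independent across uses while staying inside 32-bit integer range.
childSeed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483647)
}

# round() uses banker's rounding; printed tables use half-up (away from zero).
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Stratified k-fold assignment: within each class, samples are permuted and
# dealt round-robin, so every fold holds both classes whenever possible.
stratifiedFolds <- function(labels, k = 10, seed = 1L) {
  labels <- as.character(labels)
  fold <- integer(length(labels))
  withSeed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

stopIfNot2Classes <- function(labels, context = "analysis") {
  tab <- table(factor(as.character(labels), levels = c("normal", "tumor")))
  if (any(tab < 2))
    stop("both classes need >= 2 samples for ", context,
         " (got tumor=", tab[["tumor"]], ", normal=", tab[["normal"]], ")")
  invisible(tab)
}
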