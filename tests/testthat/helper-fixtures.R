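# Small in-code fixtures used across test files.

# Quick one-cohort fixture: `strong` genes get +effect in tumor samples.
makeToyCohort <- function(nPerClass = 30, nGenes = 20, strong = character(),
                          effect = 3, seed = 1L, id = "toy") {
  set.seed(seed)
  genes <- paste0("g", seq_len(nGenes))
  m <- matrix(rnorm(nGenes * 2 * nPerClass, mean = 8), nGenes, 2 * nPerClass,
              dimnames = list(genes, paste0(id, "_s", seq_len(2 * nPerClass))))
  labels <- rep(c("tumor", "normal"), each = nPerClass)
  m[strong, labels == "tumor"] <- m[strong, labels == "tumor"] + effect
  CohortExperiment(m, labels, id)
}

# Independent quantile-normalization oracle: sort each column, average
# across columns, put the means back at each column's ranks (ties averaged).
oracleQuantileNormalize <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    r <- rank(m[, j], ties.method = "average")
    out[, j] <- approx(seq_along(ref), ref, xout = r)$y
  }
  out
}

# Exhaustive stump oracle: best accuracy over every candidate threshold and
# both directions, by direct prediction.
oracleStumpAccuracy <- function(x, lab) {
  xs <- sort(unique(x))
  cands <- c(xs[1] - 1, (head(xs, -1) + tail(xs, -1)) / 2,
             xs[length(xs)] + 1)
  best <- -Inf
  for (d in c("up", "down")) for (t in cands) {
    pred <- if (d == "up") ifelse(x > t, "tumor", "normal")
            else ifelse(x < t, "tumor", "normal")
    best <- max(best, mean(pred == lab))
  }
  best
}

# O(n^2) AUROC oracle: pairwise win/tie counting.
oracleAuroc <- function(scores, labels) {
  pos <- scores[labels == "tumor"]; neg <- scores[labels == "normal"]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
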