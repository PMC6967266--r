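#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t with Welch-Satterthwaite degrees of freedom, as used
#' for unpaired tumor/normal comparisons. Wraps \code{stats::t.test}; the
#' degenerate case of two constant groups is resolved by convention
#' (equal values: p = 1; unequal constant values: p = 0).
#'
#' @param x,y numeric vectors (each length >= 2).
#' @return list with \code{t} and two-sided \code{p}.
#' @export
welchTest <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("welchTest needs >= 2 observations per group")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(t = if (eq) 0 else sign(mean(x) - mean(y)) * Inf,
                p = if (eq) 1 else 0))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), p = unname(ht$p.value))
}

# Row-parallel Welch test for a genes x samples matrix; returns mean
# difference, t, df and two-sided p per gene. Same conventions as welchTest.
rowWelch <- function(m, idxT, idxN) {
  n1 <- length(idxT); n2 <- length(idxN)
  x <- m[, idxT, drop = FALSE]; y <- m[, idxN, drop = FALSE]
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  zero <- se2 == 0
  if (any(zero)) {
    same <- zero & abs(m1 - m2) < .Machine$double.eps^0.5
    p[zero] <- 0; p[same] <- 1
    t[zero] <- Inf * sign(m1[zero] - m2[zero]); t[same] <- 0
  }
  list(meanT = m1, meanN = m2, t = t, p = p)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided paired signed-rank test. Zero differences are dropped; for
#' n <= 25 remaining pairs the exact null distribution of the positive-rank
#' sum is computed by dynamic programming (valid under tied ranks, where the
#' textbook tables are not), above that a normal approximation with tie
#' correction and continuity correction is used. All differences zero gives
#' p = 1 by convention.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return list with the positive-rank-sum statistic \code{w} and two-sided
#'   \code{p}.
#' @examples
#' wilcoxonPairedTest(1:10 + 2, 1:10)$p  # 2 / 2^10
#' @export
wilcoxonPairedTest <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(w = 0, p = 1))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 25) {
    r2 <- as.integer(round(2 * r))   # doubled ranks stay integral under ties
    f <- 1
    for (rr in r2) f <- (c(f, numeric(rr)) + c(numeric(rr), f)) / 2
    v2 <- as.integer(round(2 * w))
    pLo <- sum(f[seq_len(v2 + 1L)])
    pHi <- sum(f[(v2 + 1L):length(f)])
    p <- min(1, 2 * min(pLo, pHi))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sg2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sg2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(w = unname(w), p = p)
}

#' Bonferroni family-wise adjustment
#'
#' \code{p_adj = min(1, p * m)} with m defaulting to the number of tests in
#' the vector — for cohort-level calls, the number of genes tested in that
#' cohort.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @param m number of tests in the family.
#' @return adjusted p-values, capped at 1.
#' @export
bonferroniAdjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  pmin(1, p * m)
}

#' Per-cohort differential expression calls
#'
#' Tests every gene of a cohort for tumor vs normal differential expression:
#' Welch's t for unpaired designs, the paired Wilcoxon signed-rank test when
#' pairing metadata is present (overridable via \code{test}). Raw p-values
#' are Bonferroni-adjusted over the genes tested in the cohort; a gene is
#' significant when the adjusted p falls below \code{alpha}, and its
#' direction is up exactly when the tumor - normal mean difference is
#' positive.
#'
#' @param ds a [CohortExperiment-class] with both classes present.
#' @param alpha family-wise significance level (default 0.01).
#' @param test \code{"auto"} (paired iff pairing present), \code{"welch"} or
#'   \code{"wilcoxon_paired"}.
#' @return data.frame (one row per gene, sorted by gene id) with columns
#'   gene, p_raw, p_adj, mean_tumor, mean_normal, mean_diff, direction,
#'   significant, test_used.
#' @export
callDEGs <- function(ds, alpha = 0.01,
                     test = c("auto", "welch", "wilcoxon_paired")) {
  test <- match.arg(test)
  lab <- as.character(classLabels(ds))
  stopIfNot2Classes(lab, paste0("DEG calling in '", cohortId(ds), "'"))
  if (test == "auto") test <- if (isPaired(ds)) "wilcoxon_paired" else "welch"
  m <- exprs(ds)
  idxT <- which(lab == "tumor"); idxN <- which(lab == "normal")
  meanT <- rowMeans(m[, idxT, drop = FALSE])
  meanN <- rowMeans(m[, idxN, drop = FALSE])
  if (test == "welch") {
    p <- rowWelch(m, idxT, idxN)$p
  } else {
    pairing <- samplePairing(ds)
    tumorIds <- colnames(m)[idxT]
    partner <- pairing[tumorIds]
    keep <- !is.na(partner)
    if (sum(keep) < 5)
      stop("paired test in '", cohortId(ds), "' needs >= 5 complete pairs")
    xT <- m[, tumorIds[keep], drop = FALSE]
    xN <- m[, partner[keep], drop = FALSE]
    p <- vapply(seq_len(nrow(m)), function(i)
      wilcoxonPairedTest(xT[i, ], xN[i, ])$p, numeric(1))
  }
  padj <- bonferroniAdjust(p, m = nrow(m))
  out <- data.frame(
    gene = rownames(m), p_raw = p, p_adj = padj,
    mean_tumor = meanT, mean_normal = meanN, mean_diff = meanT - meanN,
    direction = ifelse(meanT - meanN > 0, "up", "down"),
    significant = padj < alpha, test_used = test,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out[order(out$gene), , drop = FALSE]
}
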