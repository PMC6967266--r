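#' Threshold-dependent classification metrics from a confusion matrix
#'
#' Sensitivity = TP/(TP+FN) x 100, specificity = TN/(TN+FP) x 100, accuracy
#' = (TP+TN)/total x 100, and the Matthews correlation coefficient
#' ((TP x TN) - (FP x FN)) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), with MCC = 0
#' by convention when any denominator factor is zero.
#'
#' @param cm named numeric vector or list with elements TP, FP, TN, FN.
#' @return list with sens_pct, spec_pct, acc_pct, mcc.
#' @examples
#' classifierMetrics(c(TP = 262, FP = 1, TN = 242, FN = 6))
#' @export
classifierMetrics <- function(cm) {
  cm <- as.list(cm)
  TP <- cm$TP; FP <- cm$FP; TN <- cm$TN; FN <- cm$FN
  if (any(c(TP, FP, TN, FN) < 0)) stop("confusion counts must be >= 0")
  total <- TP + FP + TN + FN
  if (total == 0) stop("empty confusion matrix")
  if (TP + FN == 0 || TN + FP == 0)
    stop("both classes must be represented (TP+FN > 0 and TN+FP > 0)")
  den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (den == 0) 0 else ((TP * TN) - (FP * FN)) / den
  list(sens_pct = TP / (TP + FN) * 100,
       spec_pct = TN / (TN + FP) * 100,
       acc_pct = (TP + TN) / total * 100,
       mcc = mcc)
}

#' Reconstruct integer confusion counts from printed sensitivity/specificity
#'
#' Given two-decimal sensitivity and specificity percentages and the class
#' sizes, recovers the unique integer confusion matrix by nearest-integer
#' rounding (half away from zero).
#'
#' @param sensPct,specPct percentages in [0, 100].
#' @param nPos,nNeg class sizes (positives = tumor, negatives = normal).
#' @return named numeric vector with TP, FN, TN, FP.
#' @examples
#' reconstructConfusion(97.76, 99.59, 268, 243)  # TP 262, FN 6, TN 242, FP 1
#' @export
reconstructConfusion <- function(sensPct, specPct, nPos, nNeg) {
  if (sensPct < 0 || sensPct > 100 || specPct < 0 || specPct > 100)
    stop("percentages must lie in [0, 100]")
  TP <- roundHalfUp(sensPct * nPos / 100)
  TN <- roundHalfUp(specPct * nNeg / 100)
  c(TP = TP, FN = nPos - TP, TN = TN, FP = nNeg - TN)
}

# Tally predictions (factor-like, "tumor"/"normal") against truth labels.
confusionCounts <- function(predicted, truth) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  c(TP = sum(predicted == "tumor" & truth == "tumor"),
    FP = sum(predicted == "tumor" & truth == "normal"),
    TN = sum(predicted == "normal" & truth == "normal"),
    FN = sum(predicted == "normal" & truth == "tumor"))
}

#' Fit a direction-aware single-gene threshold classifier
#'
#' Searches all candidate thresholds — midpoints of consecutive sorted
#' unique expression values, plus sentinels just below the minimum and just
#' above the maximum (the all-cancer and no-cancer rules) — and keeps the
#' one maximizing training accuracy; ties are broken by higher MCC, then
#' lower threshold, then direction up. For direction \code{"up"} a sample
#' is called cancer when its expression is strictly above the threshold,
#' for \code{"down"} strictly below; samples exactly at the threshold fall
#' on the normal side. A constant gene yields a degenerate majority-class
#' stump, flagged in the model.
#'
#' @param expr numeric expression vector for one gene.
#' @param labels per-sample classes ("tumor"/"normal").
#' @param direction \code{"auto"} (default: try both and keep the better),
#'   \code{"up"} or \code{"down"}.
#' @param gene gene id stored in the model.
#' @return A [StumpModel-class].
#' @export
fitStump <- function(expr, labels, direction = c("auto", "up", "down"),
                     gene = "gene") {
  direction <- match.arg(direction)
  labels <- as.character(labels)
  stopIfNot2Classes(labels, "stump fitting")
  n <- length(expr)
  pos <- labels == "tumor"
  P <- sum(pos); N <- n - P
  if (length(unique(expr)) == 1L) {
    thr <- if (P >= N) expr[1] - 1 else expr[1] + 1
    return(new("StumpModel", gene = gene, threshold = thr,
               direction = "up", degenerate = TRUE))
  }
  ord <- order(expr)
  xs <- expr[ord]
  cumPos <- cumsum(pos[ord]); cumNeg <- seq_len(n) - cumPos
  # cut after position k: candidates at distinct-value boundaries + sentinels
  ks <- c(0L, which(xs[-n] != xs[-1]), n)
  thr <- numeric(length(ks))
  inner <- ks > 0L & ks < n
  thr[inner] <- (xs[ks[inner]] + xs[ks[inner] + 1L]) / 2
  thr[ks == 0L] <- xs[1] - 1
  thr[ks == n] <- xs[n] + 1
  cp <- c(0L, cumPos)[ks + 1L]; cn <- c(0L, cumNeg)[ks + 1L]
  cand <- list(
    up   = list(TP = P - cp, FP = N - cn, TN = cn, FN = cp),
    down = list(TP = cp, FP = cn, TN = N - cn, FN = P - cp)
  )
  dirs <- if (direction == "auto") c("up", "down") else direction
  acc <- mcc <- th <- dd <- NULL
  for (d in dirs) {
    cc <- cand[[d]]
    den <- sqrt(cc$TP + cc$FP) * sqrt(P) * sqrt(cc$TN + cc$FN) * sqrt(N)
    acc <- c(acc, (cc$TP + cc$TN) / n)
    mcc <- c(mcc, ifelse(den == 0, 0, (cc$TP * cc$TN - cc$FP * cc$FN) / den))
    th <- c(th, thr)
    dd <- c(dd, rep(d, length(ks)))
  }
  # accuracy desc, then MCC desc, then lower threshold, then direction up
  best <- order(-round(acc, 12), -round(mcc, 12), th, dd)[1]
  new("StumpModel", gene = gene, threshold = th[best],
      direction = dd[best], degenerate = FALSE)
}

#' Predict classes with a stump
#'
#' @param model a [StumpModel-class].
#' @param expr numeric expression vector (same gene as the model).
#' @return character vector of "tumor"/"normal" calls.
#' @export
predictStump <- function(model, expr) {
  cancer <- if (model@direction == "up") expr > model@threshold
            else expr < model@threshold
  ifelse(cancer, "tumor", "normal")
}

#' Area under the ROC curve by the Mann-Whitney identity
#'
#' AUROC equals the probability that a random positive (tumor) outscores a
#' random negative, counting ties as one half. For down-regulated genes pass
#' \code{direction = "down"} so scores are negated before computing.
#'
#' @param scores numeric scores (higher = more tumor-like for "up").
#' @param labels per-sample classes ("tumor"/"normal").
#' @param direction score orientation; \code{"down"} negates.
#' @return AUROC in [0, 1].
#' @export
aurocScore <- function(scores, labels, direction = c("up", "down")) {
  direction <- match.arg(direction)
  labels <- as.character(labels)
  pos <- labels == "tumor"
  nP <- sum(pos); nN <- sum(labels == "normal")
  if (nP == 0 || nN == 0) stop("both classes required for AUROC")
  keep <- labels %in% c("tumor", "normal")
  s <- scores[keep]; pos <- pos[keep]
  if (direction == "down") s <- -s
  r <- rank(s)
  (sum(r[pos]) - nP * (nP + 1) / 2) / (nP * nN)
}

# Mean held-out accuracy of per-fold refitted stumps (stratified CV).
cvStumpAccuracy <- function(expr, labels, k = 10, seed = 1L) {
  labels <- as.character(labels)
  fold <- stratifiedFolds(labels, k, seed)
  accs <- vapply(seq_len(k), function(f) {
    tr <- fold != f; te <- !tr
    if (!any(te) || length(unique(labels[tr])) < 2) return(NA_real_)
    m <- fitStump(expr[tr], labels[tr])
    mean(predictStump(m, expr[te]) == labels[te])
  }, numeric(1))
  mean(accs, na.rm = TRUE)
}

#' Rank genes by single-gene threshold classification performance
#'
#' Fits one stump per gene on the full training cohort, computes the
#' sensitivity/specificity/accuracy/MCC suite and the AUROC of the
#' direction-oriented raw expression, and ranks by accuracy, then MCC, then
#' AUROC (all descending), then gene id. Optionally adds mean stratified
#' 10-fold cross-validated stump accuracy.
#'
#' @param ds a [CohortExperiment-class] training cohort.
#' @param genes gene ids to rank (default: all genes of \code{ds}).
#' @param cv also report 10-fold CV accuracy (column \code{cv_acc_pct}).
#' @param seed fold seed for the CV mode.
#' @return data.frame (best gene first) with gene, threshold, direction,
#'   sens_pct, spec_pct, acc_pct, mcc, auroc, mean_tumor, mean_normal,
#'   mean_diff (+ cv_acc_pct when \code{cv}).
#' @export
rankGenes <- function(ds, genes = rownames(ds), cv = FALSE, seed = 1L) {
  missing <- setdiff(genes, rownames(ds))
  if (length(missing))
    stop("genes absent from cohort '", cohortId(ds), "': ",
         paste(missing, collapse = ", "))
  lab <- as.character(classLabels(ds))
  m <- exprs(ds)
  rows <- lapply(genes, function(g) {
    x <- m[g, ]
    mod <- fitStump(x, lab, gene = g)
    met <- classifierMetrics(confusionCounts(predictStump(mod, x), lab))
    auc <- aurocScore(x, lab, direction = mod@direction)
    mt <- mean(x[lab == "tumor"]); mn <- mean(x[lab == "normal"])
    data.frame(gene = g, threshold = mod@threshold,
               direction = mod@direction,
               sens_pct = met$sens_pct, spec_pct = met$spec_pct,
               acc_pct = met$acc_pct, mcc = met$mcc, auroc = auc,
               mean_tumor = mt, mean_normal = mn, mean_diff = mt - mn,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (cv)
    out$cv_acc_pct <- vapply(genes, function(g)
      100 * cvStumpAccuracy(m[g, ], lab, seed = seed), numeric(1))
  out <- out[order(-out$acc_pct, -out$mcc, -out$auroc, out$gene), ]
  rownames(out) <- NULL
  out
}
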