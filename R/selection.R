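# Multi-gene model families. Each family is fit through a uniform internal
# interface (fit + tumor-probability predict) so the CV, grid-search and
# wrapper code is family-agnostic. Families follow the study's set:
# ExtraTrees, Gaussian naive Bayes, KNN, random forest, (ridge) logistic
# regression and RBF-kernel SVC.

PANEL_FAMILIES <- c("extra_trees", "naive_bayes", "knn", "random_forest",
                    "logistic_regression", "svc_rbf")

# Small, standard parameter grids, searched by mean 10-fold CV AUROC.
.familyGrid <- function(family, X) {
  switch(family,
    extra_trees = list(num_trees = c(100, 500)),
    random_forest = list(ntree = c(100, 500)),
    knn = list(k = c(3, 5, 7, 11)),
    logistic_regression = list(lambda = c(0.01, 0.1, 1, 10)),
    svc_rbf = list(cost = c(0.1, 1, 10),
                   gamma = c(1 / (ncol(X) * mean(apply(X, 2, stats::var))),
                             0.01, 0.1)),
    naive_bayes = list(),
    stop("unknown model family: ", family)
  )
}

.gridPoints <- function(grid) {
  if (!length(grid)) return(list(list()))
  pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(pts)), function(i) as.list(pts[i, , drop = FALSE]))
}

.familyDefaults <- function(family, X) {
  lapply(.familyGrid(family, X), `[[`, 1)
}

# glmnet needs >= 2 predictors; pad panels of one gene with a zero column.
.padX <- function(X) {
  if (ncol(X) >= 2) return(X)
  cbind(X, `..pad` = 0)
}

.fitFamily <- function(family, X, y, params, seed = 1L) {
  y <- factor(as.character(y), levels = c("normal", "tumor"))
  switch(family,
    extra_trees = ranger::ranger(
      x = as.data.frame(X), y = y, probability = TRUE,
      num.trees = params$num_trees, splitrule = "extratrees",
      seed = as.integer(seed)),
    random_forest = withSeed(seed, randomForest::randomForest(
      x = as.data.frame(X), y = y, ntree = params$ntree)),
    naive_bayes = e1071::naiveBayes(as.data.frame(X), y),
    knn = list(train = X, cl = y, k = params$k, seed = seed),
    logistic_regression = glmnet::glmnet(
      .padX(X), y, family = "binomial", alpha = 0, lambda = params$lambda),
    svc_rbf = withSeed(seed, e1071::svm(
      X, y, kernel = "radial", cost = params$cost, gamma = params$gamma,
      probability = TRUE)),
    stop("unknown model family: ", family)
  )
}

.predictProb <- function(family, fit, X) {
  switch(family,
    extra_trees = stats::predict(fit, data = as.data.frame(X))$
      predictions[, "tumor"],
    random_forest = stats::predict(fit, as.data.frame(X),
                                   type = "prob")[, "tumor"],
    naive_bayes = stats::predict(fit, as.data.frame(X),
                                 type = "raw")[, "tumor"],
    knn = withSeed(fit$seed, {
      pr <- class::knn(fit$train, X, fit$cl, k = fit$k, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "tumor", p, 1 - p)
    }),
    logistic_regression = as.numeric(
      stats::predict(fit, newx = .padX(X), type = "response")),
    svc_rbf = attr(stats::predict(fit, X, probability = TRUE),
                   "probabilities")[, "tumor"]
  )
}

# Samples x features expression matrix for a gene panel.
.featureMatrix <- function(ds, features) {
  missing <- setdiff(features, rownames(ds))
  if (length(missing))
    stop("feature(s) absent from cohort '", cohortId(ds), "': ",
         paste(missing, collapse = ", "))
  t(exprs(ds)[features, , drop = FALSE])
}

# Mean/sd of per-fold AUROC under stratified k-fold CV.
.cvAuroc <- function(X, y, family, params, k = 10, seed = 1L) {
  y <- as.character(y)
  fold <- stratifiedFolds(y, k, seed)
  aucs <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2)
      return(NA_real_)
    fit <- .fitFamily(family, X[tr, , drop = FALSE], y[tr], params,
                      seed = childSeed(seed, f))
    prob <- .predictProb(family, fit, X[!tr, , drop = FALSE])
    aurocScore(prob, y[!tr])
  }, numeric(1))
  c(mean = mean(aucs, na.rm = TRUE), sd = stats::sd(aucs, na.rm = TRUE))
}

#' Shortlist genes: top-k by training rank, then top-k by CV stump accuracy
#'
#' Reproduces the two-stage shortlist: the \code{k10} best-ranked genes on
#' the full training cohort are re-scored by mean stratified 10-fold
#' cross-validated stump accuracy, and the best \code{k5} of those are kept.
#'
#' @param ranked a [rankGenes()] table for the training cohort.
#' @param ds the training [CohortExperiment-class].
#' @param k10,k5 sizes of the two stages (defaults 10 and 5).
#' @param seed fold seed.
#' @return character vector of \code{k5} gene ids, best CV accuracy first.
#' @export
shortlistGenes <- function(ranked, ds, k10 = 10, k5 = 5, seed = 1L) {
  if (nrow(ranked) < k10)
    stop("ranking has ", nrow(ranked), " genes; need at least k10 = ", k10)
  if (k5 > k10) stop("k5 must not exceed k10")
  top <- ranked$gene[seq_len(k10)]
  lab <- as.character(classLabels(ds))
  m <- exprs(ds)
  cvacc <- vapply(top, function(g) cvStumpAccuracy(m[g, ], lab, seed = seed),
                  numeric(1))
  top[order(-cvacc, seq_along(top))][seq_len(k5)]
}

#' Wrapper backward feature elimination scored by cross-validated AUROC
#'
#' Greedy backward elimination: at every step each feature is left out in
#' turn, the model is re-fit and scored by mean stratified 10-fold CV AUROC,
#' and the best-scoring leave-one-out subset is kept; this repeats until the
#' target panel size. Exact score ties (frequent once the AUROC saturates)
#' are broken by removing the feature ranked lowest in the input ordering,
#' which the shortlist supplies best-first. Every evaluated subset is
#' recorded in an audit log.
#'
#' @param features starting gene panel.
#' @param ds training [CohortExperiment-class].
#' @param family model family used during reduction (default logistic
#'   regression at its default penalty).
#' @param targetSize panel size to reduce to.
#' @param k CV folds. @param seed fold/model seed.
#' @param params optional fixed family parameters (defaults: first grid point).
#' @return list with \code{features} (the selected panel),
#'   \code{model_family}, \code{cv_auroc_mean}, \code{cv_auroc_sd},
#'   \code{selected_params} and \code{log} — a data.frame of every subset
#'   evaluated (step, subset, cv_auroc_mean).
#' @export
wrapperReduce <- function(features, ds, family = "logistic_regression",
                          targetSize, k = 10, seed = 1L, params = NULL) {
  family <- match.arg(family, PANEL_FAMILIES)
  if (targetSize < 1 || targetSize > length(features))
    stop("targetSize must lie in 1..", length(features))
  lab <- as.character(classLabels(ds))
  Xfull <- .featureMatrix(ds, features)
  if (is.null(params)) params <- .familyDefaults(family, Xfull)
  score <- function(sub) {
    .cvAuroc(.featureMatrix(ds, sub), lab, family, params, k, seed)
  }
  log <- list()
  cur <- features
  curScore <- score(cur)
  log[[1]] <- data.frame(step = 0L, subset = paste(cur, collapse = "+"),
                         cv_auroc_mean = curScore[["mean"]],
                         stringsAsFactors = FALSE)
  step <- 0L
  while (length(cur) > targetSize) {
    step <- step + 1L
    cands <- lapply(seq_along(cur), function(i) cur[-i])
    scores <- lapply(cands, score)
    means <- vapply(scores, `[[`, numeric(1), "mean")
    for (i in seq_along(cands))
      log[[length(log) + 1L]] <- data.frame(
        step = step, subset = paste(cands[[i]], collapse = "+"),
        cv_auroc_mean = means[i], stringsAsFactors = FALSE)
    # exact score ties are common when AUROC saturates; features arrive
    # ranked best-first from the shortlist, so a tie drops the lowest-ranked
    best <- max(which(means == max(means)))
    cur <- cands[[best]]
    curScore <- scores[[best]]
  }
  list(features = cur, model_family = family,
       cv_auroc_mean = unname(curScore[["mean"]]),
       cv_auroc_sd = unname(curScore[["sd"]]),
       selected_params = params, log = do.call(rbind, log))
}

#' Train grid-searched diagnosis models for a gene panel
#'
#' For each requested family, searches its (small, documented) parameter
#' grid by mean stratified 10-fold CV AUROC, then refits the winning
#' configuration on the full training cohort.
#'
#' @param ds training [CohortExperiment-class].
#' @param features gene panel.
#' @param families subset of \code{extra_trees}, \code{naive_bayes},
#'   \code{knn}, \code{random_forest}, \code{logistic_regression},
#'   \code{svc_rbf} (default: all six).
#' @param k CV folds. @param seed fold/model seed.
#' @return named list of [PanelModel-class] objects.
#' @export
trainModels <- function(ds, features, families = PANEL_FAMILIES,
                        k = 10, seed = 1L) {
  families <- match.arg(families, PANEL_FAMILIES, several.ok = TRUE)
  lab <- as.character(classLabels(ds))
  stopIfNot2Classes(lab, "model training")
  X <- .featureMatrix(ds, features)
  out <- lapply(families, function(fam) {
    pts <- .gridPoints(.familyGrid(fam, X))
    cvs <- lapply(pts, function(p) .cvAuroc(X, lab, fam, p, k, seed))
    means <- vapply(cvs, `[[`, numeric(1), "mean")
    best <- which.max(means)   # first max wins ties: deterministic
    fit <- .fitFamily(fam, X, lab, pts[[best]], seed = seed)
    new("PanelModel", family = fam, features = features, fit = fit,
        params = pts[[best]], cvAurocMean = unname(means[best]),
        cvAurocSd = unname(cvs[[best]][["sd"]]), seed = as.integer(seed),
        trainCohort = cohortId(ds))
  })
  names(out) <- families
  out
}

#' @describeIn trainModels tumor probability for new samples.
#' @param object a [PanelModel-class].
#' @param newdata a [CohortExperiment-class] (or genes x samples matrix)
#'   containing the model's features.
#' @param ... unused.
#' @export
setMethod("predict", "PanelModel", function(object, newdata, ...) {
  X <- if (is(newdata, "CohortExperiment")) {
    .featureMatrix(newdata, object@features)
  } else {
    missing <- setdiff(object@features, rownames(newdata))
    if (length(missing))
      stop("feature(s) absent from new data: ",
           paste(missing, collapse = ", "))
    t(newdata[object@features, , drop = FALSE])
  }
  .predictProb(object@family, object@fit, X)
})

#' Evaluate a trained model on an external cohort
#'
#' Computes the threshold-dependent metric suite (sensitivity, specificity,
#' accuracy, MCC at tumor-probability > \code{threshold}) and the
#' threshold-independent AUROC of the continuous scores, with a stratified
#' bootstrap 95 percent confidence interval for the AUROC. Samples labelled
#' \code{unknown} are excluded.
#'
#' @param model a [PanelModel-class].
#' @param dsVal validation [CohortExperiment-class]; must contain every
#'   model feature.
#' @param threshold tumor-probability cutoff for class calls (default 0.5).
#' @param nBoot bootstrap resamples for the AUROC CI (default 2000).
#' @param seed bootstrap seed.
#' @return list with sens_pct, spec_pct, acc_pct, mcc, auroc,
#'   auroc_ci (length-2), n_pos, n_neg, confusion.
#' @export
evaluateExternal <- function(model, dsVal, threshold = 0.5, nBoot = 2000,
                             seed = 1L) {
  lab <- as.character(classLabels(dsVal))
  keep <- lab %in% c("tumor", "normal")
  prob <- predict(model, dsVal)[keep]
  lab <- lab[keep]
  stopIfNot2Classes(lab, paste0("evaluation on '", cohortId(dsVal), "'"))
  pred <- ifelse(prob > threshold, "tumor", "normal")
  cm <- confusionCounts(pred, lab)
  met <- classifierMetrics(cm)
  auc <- aurocScore(prob, lab)
  iP <- which(lab == "tumor"); iN <- which(lab == "normal")
  boots <- withSeed(seed, vapply(seq_len(nBoot), function(b) {
    idx <- c(sample(iP, length(iP), replace = TRUE),
             sample(iN, length(iN), replace = TRUE))
    aurocScore(prob[idx], lab[idx])
  }, numeric(1)))
  c(met, list(auroc = auc,
              auroc_ci = unname(stats::quantile(boots, c(0.025, 0.975))),
              n_pos = length(iP), n_neg = length(iN), confusion = cm))
}
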