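test_that("shortlist with k10 = k5 = all genes orders by the CV metric", {
  ce <- makeToyCohort(nPerClass = 25, nGenes = 6,
                      strong = c("g1", "g2", "g3"), effect = 2, seed = 91)
  rk <- rankGenes(ce)
  sl <- shortlistGenes(rk, ce, k10 = 6, k5 = 6, seed = 3)
  lab <- as.character(classLabels(ce))
  cvacc <- vapply(rk$gene, function(g)
    hccpanel:::cvStumpAccuracy(exprs(ce)[g, ], lab, seed = 3), numeric(1))
  expect_identical(sl, rk$gene[order(-cvacc, seq_along(cvacc))])
  # deterministic under a fixed seed
  expect_identical(sl, shortlistGenes(rk, ce, k10 = 6, k5 = 6, seed = 3))
  expect_error(shortlistGenes(rk, ce, k10 = 10, k5 = 5), "at least k10")
})

test_that("shortlist recovers a planted strong-gene set", {
  hits <- vapply(1:20, function(r) {
    ce <- makeToyCohort(nPerClass = 30, nGenes = 40,
                        strong = paste0("g", 1:5), effect = 3,
                        seed = 700 + r)
    sl <- shortlistGenes(rankGenes(ce), ce, seed = r)
    setequal(sl, paste0("g", 1:5))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("wrapper elimination drops a pure-noise feature first", {
  drops <- vapply(1:15, function(r) {
    ce <- makeToyCohort(nPerClass = 30, nGenes = 5,
                        strong = c("g1", "g2", "g3", "g4"), effect = 3,
                        seed = 900 + r)
    wr <- wrapperReduce(c("g1", "g2", "g3", "g4", "g5"), ce,
                        targetSize = 4, seed = r)
    !("g5" %in% wr$features)
  }, logical(1))
  expect_gte(mean(drops), 0.9)
})

test_that("wrapper audit log replays to the returned subset and score", {
  ce <- makeToyCohort(nPerClass = 25, nGenes = 6,
                      strong = c("g1", "g2", "g3"), effect = 2, seed = 93)
  wr <- wrapperReduce(paste0("g", 1:5), ce, targetSize = 3, seed = 11)
  expect_length(wr$features, 3)
  final <- wr$log[wr$log$step == max(wr$log$step), ]
  # the kept subset is a best-scoring candidate of the final step
  winners <- final$subset[final$cv_auroc_mean == max(final$cv_auroc_mean)]
  expect_true(paste(wr$features, collapse = "+") %in% winners)
  expect_equal(wr$cv_auroc_mean, max(final$cv_auroc_mean))
  # every evaluated subset was logged: 1 start + 5 + 4 leave-one-out rows
  expect_equal(nrow(wr$log), 10)
  # identity case
  same <- wrapperReduce(c("g1", "g2"), ce, targetSize = 2, seed = 11)
  expect_identical(same$features, c("g1", "g2"))
})

test_that("all six families reach near-perfect CV AUROC on separable data", {
  ce <- makeToyCohort(nPerClass = 40, nGenes = 3,
                      strong = c("g1", "g2", "g3"), effect = 6, seed = 95)
  mods <- trainModels(ce, c("g1", "g2", "g3"), seed = 7)
  expect_named(mods, c("extra_trees", "naive_bayes", "knn", "random_forest",
                       "logistic_regression", "svc_rbf"))
  for (fam in names(mods))
    expect_gte(mods[[fam]]@cvAurocMean, 0.99)
})

test_that("label-shuffled training yields chance-level CV AUROC", {
  ce <- makeToyCohort(nPerClass = 50, nGenes = 3, strong = "g1",
                      effect = 3, seed = 97)
  set.seed(42)
  shuffled <- CohortExperiment(exprs(ce),
                               sample(as.character(classLabels(ce))),
                               "shuffled")
  mods <- trainModels(shuffled, c("g1", "g2", "g3"), seed = 7)
  for (fam in names(mods)) {
    expect_gte(mods[[fam]]@cvAurocMean, 0.4)
    expect_lte(mods[[fam]]@cvAurocMean, 0.6)
  }
})

test_that("training is deterministic for a fixed seed", {
  ce <- makeToyCohort(nPerClass = 25, nGenes = 3, strong = c("g1", "g2"),
                      effect = 2, seed = 99)
  a <- trainModels(ce, c("g1", "g2"), families = c("extra_trees", "svc_rbf",
                                                   "logistic_regression"),
                   seed = 5)
  b <- trainModels(ce, c("g1", "g2"), families = c("extra_trees", "svc_rbf",
                                                   "logistic_regression"),
                   seed = 5)
  for (fam in names(a)) {
    expect_identical(a[[fam]]@params, b[[fam]]@params)
    expect_identical(a[[fam]]@cvAurocMean, b[[fam]]@cvAurocMean)
  }
})

test_that("external evaluation is self-consistent on the training cohort", {
  ce <- makeToyCohort(nPerClass = 30, nGenes = 3, strong = c("g1", "g2"),
                      effect = 3, seed = 101)
  mod <- trainModels(ce, c("g1", "g2"),
                     families = "logistic_regression", seed = 5)[[1]]
  ev <- evaluateExternal(mod, ce, nBoot = 100, seed = 5)
  lab <- as.character(classLabels(ce))
  prob <- predict(mod, ce)
  expect_equal(ev$auroc, aurocScore(prob, lab))
  expect_equal(ev$acc_pct,
               100 * mean(ifelse(prob > 0.5, "tumor", "normal") == lab))
  expect_true(ev$auroc_ci[1] <= ev$auroc && ev$auroc <= ev$auroc_ci[2])
})

test_that("held-out evaluation detects planted signal and label inversion flips AUROC", {
  train <- makeToyCohort(nPerClass = 50, nGenes = 5,
                         strong = c("g1", "g2", "g3"), effect = 3, seed = 103)
  val <- makeToyCohort(nPerClass = 50, nGenes = 5,
                       strong = c("g1", "g2", "g3"), effect = 3, seed = 104,
                       id = "val")
  mod <- trainModels(train, c("g1", "g2", "g3"),
                     families = "logistic_regression", seed = 5)[[1]]
  ev <- evaluateExternal(mod, val, nBoot = 100, seed = 5)
  expect_gte(ev$auroc, 0.95)
  flipped <- CohortExperiment(
    exprs(val), ifelse(as.character(classLabels(val)) == "tumor",
                       "normal", "tumor"), "flip")
  evf <- evaluateExternal(mod, flipped, nBoot = 100, seed = 5)
  expect_equal(evf$auroc, 1 - ev$auroc, tolerance = 1e-12)
})

test_that("a missing validation feature is reported by name", {
  train <- makeToyCohort(nPerClass = 20, nGenes = 3, strong = "g1",
                         effect = 3, seed = 105)
  mod <- trainModels(train, c("g1", "g2"),
                     families = "naive_bayes", seed = 5)[[1]]
  val <- makeToyCohort(nPerClass = 10, nGenes = 1, seed = 106, id = "v")
  expect_error(evaluateExternal(mod, val), "g2")
})
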