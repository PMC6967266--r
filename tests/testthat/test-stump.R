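# Printed-table rows used as worked examples: sensitivity/specificity
# percentages on a 268 tumor / 243 non-tumor training cohort.
table2Rows <- list(
  FCN2 = c(97.76, 99.59), CLEC4M = c(97.01, 98.77), FCN3 = c(95.15, 99.18),
  CLEC1B = c(95.52, 97.94), CFP = c(96.64, 94.24), CRHBP = c(92.54, 96.71),
  PRC1 = c(91.42, 97.12), PBK = c(91.04, 93.42), DTL = c(85.82, 94.65),
  IGSF3 = c(81.34, 91.77)
)

test_that("metric suite on a reconstructed confusion matrix hits the printed values", {
  cm <- reconstructConfusion(97.76, 99.59, 268, 243)
  expect_equal(unname(cm), c(262, 6, 242, 1))
  met <- classifierMetrics(cm)
  expect_equal(round(met$acc_pct, 2), 98.63)
  expect_equal(round(met$mcc, 2), 0.97)
})

test_that("metric conventions: perfect and degenerate classifiers", {
  perfect <- classifierMetrics(c(TP = 50, FP = 0, TN = 40, FN = 0))
  expect_equal(perfect$sens_pct, 100)
  expect_equal(perfect$spec_pct, 100)
  expect_equal(perfect$acc_pct, 100)
  expect_equal(perfect$mcc, 1)
  # all-positive predictor on balanced data: a zero MCC factor => MCC 0
  allpos <- classifierMetrics(c(TP = 30, FP = 30, TN = 0, FN = 0))
  expect_equal(allpos$mcc, 0)
  expect_error(classifierMetrics(c(TP = 0, FP = 0, TN = 0, FN = 0)), "empty")
  expect_error(classifierMetrics(c(TP = 0, FP = 2, TN = 3, FN = 0)),
               "both classes")
})

test_that("confusion reconstruction is the rounding inverse of the metrics", {
  expect_equal(unname(reconstructConfusion(100, 100, 7, 9)), c(7, 0, 9, 0))
  expect_equal(unname(reconstructConfusion(95.15, 99.18, 268, 243)),
               c(255, 13, 241, 2))
  for (g in names(table2Rows)) {
    s <- table2Rows[[g]]
    met <- classifierMetrics(reconstructConfusion(s[1], s[2], 268, 243))
    expect_equal(floor(met$sens_pct * 100 + 0.5) / 100, s[1])
    expect_equal(floor(met$spec_pct * 100 + 0.5) / 100, s[2])
  }
})

test_that("stump fit equals the exhaustive threshold search", {
  set.seed(41)
  for (r in 1:200) {
    n <- sample(6:30, 1)
    x <- round(rnorm(n, 8), 1)
    lab <- sample(c("tumor", "normal"), n, replace = TRUE)
    if (min(table(factor(lab, c("tumor", "normal")))) < 2 ||
        length(unique(x)) == 1) next
    m <- fitStump(x, lab)
    acc <- mean(predictStump(m, x) == lab)
    expect_equal(acc, oracleStumpAccuracy(x, lab))
    # lower bound: never below the majority class rate
    expect_gte(acc, max(table(lab)) / n)
  }
})

test_that("separable classes give a perfect stump with an interior threshold", {
  x <- c(rnorm(20, 12), rnorm(20, 4))
  lab <- rep(c("tumor", "normal"), each = 20)
  m <- fitStump(x, lab)
  expect_equal(mean(predictStump(m, x) == lab), 1)
  expect_gt(m@threshold, max(x[lab == "normal"]))
  expect_lt(m@threshold, min(x[lab == "tumor"]))
  expect_equal(m@direction, "up")
  # a sample exactly at the threshold falls on the normal side
  expect_equal(predictStump(m, m@threshold), "normal")
  down <- fitStump(-x, lab)
  expect_equal(down@direction, "down")
  expect_equal(predictStump(down, down@threshold), "normal")
})

test_that("a constant gene yields a flagged majority-class stump", {
  m <- fitStump(rep(5, 10), rep(c("tumor", "normal"), c(7, 3)))
  expect_true(m@degenerate)
  expect_true(all(predictStump(m, rep(5, 4)) == "tumor"))
})

test_that("AUROC equals the pairwise Mann-Whitney oracle", {
  scores <- c(1, 2, 2, 3, 5, 5)
  labels <- c("normal", "normal", "tumor", "normal", "tumor", "tumor")
  expect_equal(aurocScore(scores, labels), oracleAuroc(scores, labels))
  set.seed(43)
  for (r in 1:20) {
    s <- sample(1:6, 12, replace = TRUE)
    l <- sample(c("tumor", "normal"), 12, replace = TRUE)
    if (length(unique(l)) < 2) next
    expect_equal(aurocScore(s, l), oracleAuroc(s, l))
    # invariance under strictly monotone transforms
    expect_equal(aurocScore(exp(s / 2), l), aurocScore(s, l))
  }
  # perfect separation and the null
  expect_equal(aurocScore(c(5, 6, 1, 2), c("tumor", "tumor", "normal", "normal")), 1)
  set.seed(44)
  expect_equal(aurocScore(rnorm(4000), sample(c("tumor", "normal"), 4000,
                                              replace = TRUE)),
               0.5, tolerance = 0.05)
  expect_error(aurocScore(1:3, rep("tumor", 3)), "both classes")
})

test_that("down-regulated genes are scored on negated expression", {
  x <- c(2, 3, 9, 10); l <- c("tumor", "tumor", "normal", "normal")
  expect_equal(aurocScore(x, l, direction = "down"), 1)
  expect_equal(aurocScore(x, l, direction = "up"), 0)
})

test_that("gene ranking puts a planted gene first and matches a re-fit oracle", {
  firsts <- vapply(1:50, function(r) {
    ce <- makeToyCohort(nPerClass = 25, nGenes = 25, strong = "g1",
                        effect = 3, seed = 500 + r)
    rankGenes(ce)$gene[1] == "g1"
  }, logical(1))
  expect_gte(mean(firsts), 0.95)

  ce <- makeToyCohort(nPerClass = 30, nGenes = 10, strong = c("g1", "g2"),
                      effect = 2, seed = 71)
  rk <- rankGenes(ce)
  lab <- as.character(classLabels(ce))
  oracleAcc <- vapply(rownames(ce), function(g)
    oracleStumpAccuracy(exprs(ce)[g, ], lab), numeric(1))
  expect_equal(rk$acc_pct, unname(100 * oracleAcc[rk$gene]))
  expect_false(is.unsorted(rev(rk$acc_pct)))
})

test_that("duplicated genes rank adjacently with ties broken by id", {
  ce <- makeToyCohort(nPerClass = 20, nGenes = 6, strong = "g1",
                      effect = 3, seed = 81)
  m <- exprs(ce)
  m2 <- rbind(m, g1copy = m["g1", ])
  ce2 <- CohortExperiment(m2, as.character(classLabels(ce)), "dup")
  rk <- rankGenes(ce2)
  i <- which(rk$gene %in% c("g1", "g1copy"))
  expect_equal(diff(i), 1)
  expect_equal(rk$gene[i[1]], "g1")
})
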