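test_that("mean dichotomization splits strictly above the mean", {
  g <- dichotomizeByMean(c(1, 2, 3, 4))
  expect_identical(as.character(g), c("low", "low", "high", "high"))
  # symmetric values: balanced groups; the mean itself falls to low
  g2 <- dichotomizeByMean(c(-2, -1, 0, 1, 2))
  expect_equal(sum(g2 == "high"), 2)
  set.seed(7)
  x <- rnorm(50)
  expect_identical(as.character(dichotomizeByMean(x)),
                   ifelse(x > mean(x), "high", "low"))
  expect_error(dichotomizeByMean(rep(3, 10)), "constant")
})

test_that("KM curves start at 1 and are non-increasing; identical groups give chi2 ~ 0", {
  set.seed(9)
  tm <- rexp(60); ev <- rbinom(60, 1, 0.8)
  res <- kmLogrank(rep(c("a", "b"), 30), c(tm, tm)[1:60], c(ev, ev)[1:60])
  expect_true(all(res$km$surv <= 1 + 1e-12))
  for (grp in split(seq_along(res$km$surv),
                    rep(seq_along(res$km$strata), res$km$strata)))
    expect_false(is.unsorted(rev(res$km$surv[grp])))
  # duplicated halves: same survival experience in both groups
  dup <- kmLogrank(rep(c("a", "b"), each = 60), rep(tm, 2), rep(ev, 2))
  expect_lt(dup$chi2, 1e-10)
  expect_error(kmLogrank(rep("a", 10), rexp(10), rep(1, 10)), "two groups")
})

test_that("log-rank p agrees with the Cox score test on tie-free data", {
  set.seed(11)
  for (r in 1:5) {
    grp <- rep(c("low", "high"), each = 25)
    tm <- rexp(50, rate = ifelse(grp == "high", 0.15, 0.1))
    ev <- as.integer(tm < quantile(tm, 0.85))
    lr <- kmLogrank(grp, tm, ev)
    cox <- survival::coxph(survival::Surv(tm, ev) ~ grp)
    expect_equal(lr$p, unname(summary(cox)$sctest["pvalue"]),
                 tolerance = 1e-6)
  }
})

test_that("log-rank holds its level under the null and detects a planted HR of 2", {
  set.seed(13)
  rej <- vapply(1:200, function(r) {
    tm <- rexp(200, 0.1)
    cens <- rexp(200, 0.04)
    kmLogrank(rep(c("a", "b"), 100), pmin(tm, cens),
              as.integer(tm <= cens))$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.10)

  power <- vapply(1:20, function(r) {
    grp <- rep(c("low", "high"), each = 250)
    tm <- rexp(500, rate = ifelse(grp == "high", 0.2, 0.1))
    cens <- rexp(500, 0.043)  # ~30% censoring
    kmLogrank(grp, pmin(tm, cens), as.integer(tm <= cens))$p < 0.05
  }, logical(1))
  expect_gte(mean(power), 0.9)
})

test_that("univariate Cox recovers a planted group hazard ratio of 2", {
  set.seed(17)
  grp <- factor(rep(c("low", "high"), each = 250), c("low", "high"))
  tm <- rexp(500, rate = ifelse(grp == "high", 0.2, 0.1))
  cens <- rexp(500, 0.043)
  fit <- coxUnivariate(grp, pmin(tm, cens), as.integer(tm <= cens),
                       name = "group")
  expect_gt(fit$HR, 1.7); expect_lt(fit$HR, 2.3)
  expect_true(fit$ci_low <= fit$HR && fit$HR <= fit$ci_high)
  expect_equal(fit$n_high + fit$n_low, 500)
  expect_error(coxUnivariate(rep(1, 50), rexp(50), rep(1, 50)), "constant")
})

test_that("multivariate Cox reduces to univariate and ignores variable order", {
  set.seed(19)
  x <- rnorm(200)
  tm <- rexp(200, 0.1 * exp(0.7 * x))
  ev <- rep(1L, 200)
  uni <- coxUnivariate(x, tm, ev, name = "x")
  multi <- coxMultivariate(list(x = x), tm, ev, screen = FALSE)
  expect_equal(multi$HR, uni$HR, tolerance = 1e-10)
  expect_equal(multi$p, uni$p, tolerance = 1e-10)

  y <- rnorm(200)
  ab <- coxMultivariate(list(x = x, y = y), tm, ev, screen = FALSE)
  ba <- coxMultivariate(list(y = y, x = x), tm, ev, screen = FALSE)
  expect_equal(ab[ab$variable == "x", "HR"], ba[ba$variable == "x", "HR"],
               tolerance = 1e-12)
})

test_that("collinear covariates are rejected by name", {
  set.seed(23)
  x <- rnorm(100); tm <- rexp(100); ev <- rep(1L, 100)
  expect_error(coxMultivariate(list(a = x, b = 2 * x), tm, ev,
                               screen = FALSE),
               "collinear.*a.*b")
})

test_that("only a truly prognostic stage survives multivariate adjustment", {
  set.seed(29)
  hits <- vapply(1:10, function(r) {
    n <- 400
    stage <- sample(1:4, n, replace = TRUE)
    g1 <- rnorm(n); g2 <- rnorm(n); g3 <- rnorm(n)
    tm <- rexp(n, rate = 0.05 * exp(log(1.8) * (stage - mean(stage))))
    cens <- rexp(n, 0.02)
    time <- pmin(tm, cens); ev <- as.integer(tm <= cens)
    res <- coxMultivariate(list(stage = stage, g1 = g1, g2 = g2, g3 = g3),
                           time, ev, screen = FALSE)
    stageSig <- res$ci_low[res$variable == "stage"] > 1
    geneSig <- sum(res$ci_low[res$variable != "stage"] > 1 |
                   res$ci_high[res$variable != "stage"] < 1)
    stageSig && geneSig <= 1
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("survivalScreen links dichotomized expression to outcome", {
  ce <- makeToyCohort(nPerClass = 300, nGenes = 3, seed = 31)
  st <- simulateSurvival(survivalSimSpec(nPatients = 300, censorRate = 0.3,
                                         logHr = c(g1 = log(2)), seed = 33),
                         ce, genes = c("g1", "g2"))
  res <- survivalScreen(st, c("g1", "g2"))
  expect_lt(res$p[res$variable == "g1"], 0.05)
  expect_gt(res$HR[res$variable == "g1"], 1)
  expect_lt(res$logrank_p[res$variable == "g1"], 0.05)
  expect_error(survivalScreen(st, "g9"), "g9")
})

test_that("univariate screening feeds the multivariate model", {
  set.seed(37)
  n <- 300
  x <- rnorm(n)          # prognostic
  z <- rnorm(n)          # noise
  tm <- rexp(n, 0.1 * exp(0.8 * x))
  res <- coxMultivariate(list(x = x, z = z), tm, rep(1L, n), screen = TRUE)
  expect_true("x" %in% res$variable)
  expect_false("z" %in% res$variable)
})
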