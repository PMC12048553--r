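# independent confusion-matrix oracle for classification metrics
oracleMetrics <- function(truth, pred, k) {
  per <- lapply(seq_len(k), function(c) {
    tp <- sum(truth == c & pred == c)
    fp <- sum(truth != c & pred == c)
    fn <- sum(truth == c & pred != c)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    list(prec = prec, rec = rec, f1 = f1, n = sum(truth == c))
  })
  w <- vapply(per, `[[`, numeric(1), "n") / length(truth)
  list(per = per, wf1 = sum(w * vapply(per, `[[`, numeric(1), "f1")))
}

test_that("classification metrics match hand-worked confusion matrices", {
  # perfect predictions
  m <- classificationMetrics(c(1, 2, 3, 1), c(1, 2, 3, 1), 3)
  expect_equal(m$weightedF1, 1)
  expect_equal(m$perClass$f1[1:3], rep(1, 3))
  # confusion [[2,1],[1,2]]: both classes precision = recall = f1 = 2/3
  truth <- c(1, 1, 1, 2, 2, 2)
  pred <- c(1, 1, 2, 2, 2, 1)
  m2 <- classificationMetrics(truth, pred, 2)
  expect_equal(m2$perClass$precision, c(2 / 3, 2 / 3))
  expect_equal(m2$perClass$recall, c(2 / 3, 2 / 3))
  expect_equal(m2$weightedF1, 2 / 3)
  # everything wrong
  expect_equal(classificationMetrics(c(1, 2), c(2, 1), 2)$weightedF1, 0)
  # abstentions: excluded by default (and counted), or scored as errors
  m3 <- classificationMetrics(c(1, 2), c(1, NA), 2)
  expect_equal(m3$nAbstained, 1)
  expect_equal(m3$weightedF1, 1)
  m4 <- classificationMetrics(c(1, 2), c(1, NA), 2, abstain = "error")
  expect_lt(m4$weightedF1, 1)
})

test_that("metrics equal the brute-force oracle on random label vectors", {
  for (seed in 1:200) {
    k <- 2 + seed %% 4
    n <- 30
    truth <- withr::with_seed(seed, sample(k, n, replace = TRUE))
    pred <- withr::with_seed(seed + 9999, sample(k, n, replace = TRUE))
    m <- classificationMetrics(truth, pred, k)
    o <- oracleMetrics(truth, pred, k)
    expect_equal(m$weightedF1, o$wf1)
    # weights over observed classes sum to 1
    w <- m$perClass$support / sum(m$perClass$support)
    expect_equal(sum(w), 1)
  }
})

test_that("regression metrics implement the standard definitions", {
  r <- regressionMetrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$mse, 0); expect_equal(r$pearson, 1)
  expect_equal(regressionMetrics(c(1, 2, 3), c(3, 2, 1))$pearson, -1)
  r2 <- regressionMetrics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(r2$mse, 1 / 3); expect_equal(r2$mae, 1 / 3)
  # abstentions are excluded and counted
  r3 <- regressionMetrics(c(1, 2, 3, 4), c(1, 2, 3, NA))
  expect_equal(r3$n, 3); expect_equal(r3$nAbstained, 1)
  # zero-variance input leaves correlations undefined
  expect_true(is.na(regressionMetrics(c(1, 1, 1), c(1, 2, 3))$pearson))
})

test_that("homophily-performance correlation needs >= 3 receptors", {
  expect_error(homophilyPerformance(c(0.5, 0.9), c(0.4, 0.8)), "3 receptors")
  hp <- homophilyPerformance(c(0.2, 0.5, 0.8, 0.9), c(0.2, 0.5, 0.8, 0.9))
  expect_equal(hp$correlation, 1)
  # graded synthetic homophily: receptors whose mean-predictor quality
  # varies must correlate positively with a model tracking the same signal
  withr::with_seed(42, {
    proxy <- runif(10, 0.3, 0.95)
    model <- proxy * 0.8 + rnorm(10, 0, 0.05)
  })
  hp2 <- homophilyPerformance(proxy, model)
  expect_gt(hp2$correlation, 0)
  expect_lt(hp2$pValue, 0.05)
})

test_that("enrichment reproduces a hand-filled 2x2 table", {
  # 100 DTIs, 10 experimental hits; predictor flags 20 of which 6 are hits
  ids <- sprintf("c%03d", 1:100)
  expHit <- c(rep(TRUE, 10), rep(FALSE, 90))
  predHit <- c(rep(TRUE, 6), rep(FALSE, 4), rep(TRUE, 14), rep(FALSE, 76))
  predicted <- data.frame(
    compound_id = ids, receptor_id = "R",
    predicted_class = ifelse(predHit, "Agonist", "No effect"),
    predicted_pki = ifelse(predHit, 8, 5))
  experimental <- data.frame(compound_id = ids, receptor_id = "R",
                             z = ifelse(expHit, 4, 0))
  e <- enrichment(predicted, experimental)
  expect_equal(e$precision, 0.3)
  expect_equal(e$specificity, 76 / 90)
  expect_equal(e$baselineHitRate, 0.10)
  expect_equal(e$enrichedHitRate, 0.30)
  expect_equal(sum(e$confusion), e$nMatched)
  # a tight predicted class with weak affinity is not a predicted hit
  predicted$predicted_pki[1] <- 6.9  # Ki above 100 nM
  e2 <- enrichment(predicted, experimental)
  expect_equal(sum(e2$confusion[1, ]), 19)
  # all-negative predictions against all-negative experiments: specificity 1
  pNeg <- data.frame(compound_id = ids, receptor_id = "R",
                     predicted_class = "No effect", predicted_pki = 5)
  eNeg <- enrichment(pNeg, transform(experimental, z = 0))
  expect_equal(eNeg$specificity, 1)
  # unmatched keys are reported, never dropped silently
  e3 <- enrichment(predicted[1:50, ], experimental)
  expect_equal(length(e3$unmatched$experimentalOnly), 50)
})

test_that("receptor distances honour co-occurrence and correlation", {
  ids <- sprintf("c%02d", 1:12)
  a <- stats::setNames(rep(c("Agonist", "Antagonist", "No effect"), 4), ids)
  # identical label vectors over >= 5 co-occurring compounds -> distance 0
  expect_equal(receptorDistance(a, a), 0)
  # fewer than 5 co-occurring compounds -> maximum distance
  expect_equal(receptorDistance(a[1:3], a[1:3]), 1)
  # independent labels at large n -> distance near 1
  big <- sprintf("c%04d", 1:1000)
  x <- withr::with_seed(8, stats::setNames(sample(c("A", "B", "C"), 1000,
                                                  replace = TRUE), big))
  y <- withr::with_seed(9, stats::setNames(sample(c("A", "B", "C"), 1000,
                                                  replace = TRUE), big))
  expect_gt(receptorDistance(x, y), 0.9)
  # cosine distance on embeddings
  expect_equal(receptorDistance(c(1, 0), c(1, 0), metric = "cosine"), 0)
  expect_equal(receptorDistance(c(1, 0), c(0, 1), metric = "cosine"), 1)
  expect_equal(receptorDistance(c(1, 0), c(-1, 0), metric = "cosine"), 2)
})
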