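test_that("stratified splitting matches fractions within rounding", {
  ids <- sprintf("S%03d", 1:100)
  lab <- rep(c("mut", "wt"), 50)
  sp <- stratifiedSplit(ids, lab, seed = 7)
  expect_equal(unname(table(sp$set)[c("training", "development", "test")]),
               c(60L, 20L, 20L), ignore_attr = TRUE)
  expect_identical(sp, stratifiedSplit(ids, lab, seed = 7))
  expect_false(identical(sp, stratifiedSplit(ids, lab, seed = 8)))

  # 10 positives / 90 negatives -> 6/2/2 positives by cumulative rounding
  lab2 <- c(rep("pos", 10), rep("neg", 90))
  sp2 <- stratifiedSplit(ids, lab2, seed = 1)
  posSets <- table(sp2$set[lab2 == "pos"])
  expect_equal(unname(posSets[c("training", "development", "test")]),
               c(6L, 2L, 2L), ignore_attr = TRUE)

  expect_error(stratifiedSplit(ids[1:5], c("a", "a", "a", "b", "b")),
               "at least 3")
})

test_that("the refit grid evaluates all combinations and breaks ties sparsely", {
  sim <- makeBinaryCohort(nSamples = 40, nProbes = 8, nInformative = 4,
                          deltaBeta = 0.45, missingRate = 0, seed = 13)
  X <- assayValues(betaToM(sim$beta))
  y <- unname(sim$labels)

  one <- gridRefit(X, y, rownames(X)[1:4], alphaGrid = 0.3,
                   lambdaGrid = 0.7, seed = 2)
  expect_equal(c(one$alpha, one$lambda), c(0.3, 0.7))
  expect_equal(dim(one$cvAccuracy), c(1L, 1L))

  g <- gridRefit(X, y, rownames(X), alphaGrid = c(0.2, 0.8),
                 lambdaGrid = seq(0, 1, by = 0.25), seed = 2)
  expect_equal(dim(g$cvAccuracy), c(2L, 5L))
  # separable toy attains the attainable maximum
  expect_equal(max(g$cvAccuracy), 1)
  # the winner is the largest lambda (then alpha) among the maxima
  top <- which(g$cvAccuracy == 1, arr.ind = TRUE)
  expect_equal(g$lambda, max(seq(0, 1, by = 0.25)[top[, 2]]))
  expect_error(gridRefit(X, y, character(0)), "empty")
})

test_that("default refit grid has 10 x 101 combinations", {
  # arithmetic on the documented grids, asserted via the function formals
  a <- eval(formals(gridRefit)$alphaGrid)
  l <- eval(formals(gridRefit)$lambdaGrid)
  expect_length(a, 10)
  expect_length(l, 101)
})

test_that("final-model fitting honours the published configuration", {
  sim <- makeBinaryCohort(nSamples = 60, nProbes = 120, nInformative = 10,
                          deltaBeta = 0.4, missingRate = 0, seed = 17)
  X <- assayValues(betaToM(sim$beta))
  y <- unname(sim$labels)
  ranked <- rownames(X)

  m <- fitFinal(X, y, ranked, alteration = "IDH", mode = "paper")
  expect_equal(length(m@probes), 100L)
  expect_equal(m@alpha, 0)
  expect_equal(m@lambda, 1)

  m2 <- fitFinal(X, y, ranked, alteration = "chr1p19q", mode = "paper")
  expect_equal(length(m2@probes), 100L)
  expect_equal(m2@lambda, 0.1)

  expect_equal(paperModeConfig("TERTp")$nProbes, 1000L)
  expect_equal(paperModeConfig("ATRX")$nProbes, 500L)

  # a zero-variance probe carries no information: coefficient 0
  Xz <- X
  Xz["cg000001", ] <- 1.7
  mz <- fitFinal(Xz, y, ranked[1:20], alpha = 0.5, lambda = 0.05)
  expect_lt(abs(mz@coefficients[which(mz@probes == "cg000001")]), 1e-8)
})

test_that("prediction follows the logistic link and is monotone", {
  m0 <- modelFixture(c("p1", "p2"), c(0, 0), intercept = 0)
  X <- matrix(c(1, 2, -1, 0), 2, 2,
              dimnames = list(c("p1", "p2"), c("s1", "s2")))
  pr <- predictBinary(m0, X)
  expect_equal(pr$probability, c(0.5, 0.5))

  # coef 2, value 1, intercept -1 -> logistic(1)
  m1 <- modelFixture("p1", 2, intercept = -1)
  X1 <- matrix(1, 1, 1, dimnames = list("p1", "s1"))
  expect_equal(predictBinary(m1, X1)$probability, 1 / (1 + exp(-1)),
               tolerance = 1e-12)
  # single coef 1, value 0 -> 0.5, call positive at threshold
  X0 <- matrix(0, 1, 1, dimnames = list("p1", "s1"))
  pr0 <- predictBinary(modelFixture("p1", 1), X0)
  expect_equal(pr0$probability, 0.5)
  expect_equal(pr0$call, 1L)  # probability >= threshold is positive

  # monotone in a positively weighted probe
  grid <- matrix(seq(-3, 3, length.out = 7), 1, 7,
                 dimnames = list("p1", paste0("s", 1:7)))
  expect_true(all(diff(predictBinary(m1, grid)$probability) > 0))

  expect_error(predictBinary(m1, matrix(0, 1, 1,
                                        dimnames = list("px", "s1"))),
               "p1")
})

## exhaustive pairwise AUC oracle
aucOracle <- function(scores, truth) {
  pos <- which(truth); neg <- which(!truth)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

test_that("evaluation metrics match hand cases and the pairwise AUC oracle", {
  pred <- data.frame(sample_id = paste0("s", 1:4),
                     probability = c(0.9, 0.8, 0.4, 0.3),
                     call = c(1L, 1L, 0L, 0L))
  truth <- setNames(c(1, 0, 1, 0), pred$sample_id)
  ev <- evaluateBinary(pred, truth)
  expect_equal(ev$accuracy, 0.5)
  # AUC by exhaustive pair enumeration: pairs (.9,.8) (.9,.3) (.4,.8)
  # (.4,.3) -> 3 of 4 concordant
  expect_equal(ev$auc, 0.75)
  expect_equal(ev$auc, aucOracle(pred$probability, truth == 1))
  expect_equal(unname(ev$confusion), c(1L, 1L, 1L, 1L))

  perfect <- data.frame(sample_id = paste0("s", 1:4),
                        probability = c(0.9, 0.8, 0.2, 0.1),
                        call = c(1L, 1L, 0L, 0L))
  ev2 <- evaluateBinary(perfect, setNames(c(1, 1, 0, 0),
                                          perfect$sample_id))
  expect_equal(ev2$accuracy, 1)
  expect_equal(ev2$auc, 1)
  # anti-ranked probabilities
  ev3 <- evaluateBinary(perfect, setNames(c(0, 0, 1, 1),
                                          perfect$sample_id))
  expect_equal(ev3$auc, 0)

  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:50, 1)
    scores <- round(runif(n), 2)  # rounding forces ties
    truth <- runif(n) < 0.5
    if (!any(truth) || all(truth)) next
    expect_equal(rocAUC(scores, truth), aucOracle(scores, truth))
  }

  one <- evaluateBinary(pred, setNames(rep(1, 4), pred$sample_id))
  expect_true(is.na(one$auc))
  expect_equal(one$accuracy, 0.5)
})

test_that("development-set selection prefers accuracy then parsimony", {
  sim <- makeBinaryCohort(nSamples = 80, nProbes = 60, nInformative = 8,
                          deltaBeta = 0.45, missingRate = 0, seed = 23)
  X <- assayValues(betaToM(sim$beta))
  y <- unname(sim$labels)
  tr <- 1:50; dev <- 51:80
  inf <- sim$truth$informative
  noise <- setdiff(rownames(X), inf)[1:8]

  # informative candidate beats the noise-only candidate
  cands <- list(list(probes = inf, alpha = 0.5, lambda = 0.05),
                list(probes = noise, alpha = 0.5, lambda = 0.05))
  sel <- selectFinalModel(cands, X[, tr], y[tr], X[, dev], y[dev])
  expect_equal(sel$chosen, 1L)
  expect_gt(sel$devAccuracy[1], sel$devAccuracy[2])

  # single candidate is returned as-is; equal-accuracy tie -> fewer probes
  single <- selectFinalModel(cands[1], X[, tr], y[tr], X[, dev], y[dev])
  expect_equal(single$chosen, 1L)
  tie <- list(list(probes = inf, alpha = 0.5, lambda = 0.05),
              list(probes = inf[1:4], alpha = 0.5, lambda = 0.05))
  selTie <- selectFinalModel(tie, X[, tr], y[tr], X[, dev], y[dev])
  if (selTie$devAccuracy[1] == selTie$devAccuracy[2])
    expect_equal(selTie$chosen, 2L)
})

test_that("the end-to-end pipeline is deterministic under a fixed seed", {
  sim <- makeBinaryCohort(nSamples = 60, nProbes = 60, nInformative = 8,
                          deltaBeta = 0.45, missingRate = 0, seed = 29)
  X <- assayValues(betaToM(sim$beta))
  y <- unname(sim$labels)
  r1 <- trainBinaryPipeline(X, y, sizes = 10L, seed = 5, nLambda = 15L)
  r2 <- trainBinaryPipeline(X, y, sizes = 10L, seed = 5, nLambda = 15L)
  expect_identical(r1$model@coefficients, r2$model@coefficients)
  expect_identical(annotationTable(r1$ranking),
                   annotationTable(r2$ranking))
  expect_identical(r1$testEval, r2$testEval)
})
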