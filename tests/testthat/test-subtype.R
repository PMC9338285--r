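test_that("subtype probabilities follow the (1-p) normalization", {
  expect_equal(unname(subtypeProbability(c(0, 1, 1))), c(1, 0, 0))
  expect_equal(unname(subtypeProbability(c(0.5, 0.5, 0.5))), rep(1 / 3, 3))
  expect_equal(unname(subtypeProbability(c(0.1, 0.4, 0.7))),
               c(0.9, 0.6, 0.3) / 1.8, tolerance = 1e-15)
  # degenerate all-rejected input falls back to uniform
  expect_equal(unname(subtypeProbability(c(1, 1, 1))), rep(1 / 3, 3))
  expect_error(subtypeProbability(c(-0.1, 0.5, 0.5)), "\\[0,1\\]")

  set.seed(2)
  m <- matrix(runif(30), 10, 3, dimnames = list(NULL, c("CL", "MES", "PN")))
  pr <- subtypeProbability(m)
  expect_equal(unname(rowSums(pr)), rep(1, 10), tolerance = 1e-12)
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("probability deviation is a bounded squared distance", {
  expect_equal(probabilityDeviation(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5)), 0)
  expect_equal(probabilityDeviation(c(1, 0, 0), rep(1 / 3, 3)), 6 / 9,
               tolerance = 1e-15)
  expect_equal(probabilityDeviation(c(1, 0, 0), c(0, 1, 0)), 2)
  # symmetry and [0,2] bound over random probability vectors
  set.seed(3)
  for (i in 1:20) {
    a <- runif(3); a <- a / sum(a)
    b <- runif(3); b <- b / sum(b)
    expect_equal(probabilityDeviation(a, b), probabilityDeviation(b, a))
    expect_gte(probabilityDeviation(a, b), 0)
    expect_lte(probabilityDeviation(a, b), 2)
  }
  expect_error(probabilityDeviation(c(1, 0), c(1, 0, 0)), "shapes")
})

test_that("the gene-branch probe filter applies its cascade with reasons", {
  set.seed(4)
  n <- 20
  ranks <- seq_len(n)
  v <- rbind(
    island_corr   = 0.02 * ranks + 0.2,   # monotone with gene A
    island_anti   = 0.8 - 0.02 * ranks,   # perfectly anti-correlated
    island_nogene = rep(0.5, n) + runif(n, 0, 0.01),
    not_island    = 0.02 * ranks + 0.2,
    island_flat   = 0.02 * ranks + 0.2,   # gene C expression constant
    island_weak   = rep(0.5, n),          # filled below: |rho| ~ 0.05
    island_miss   = c(rep(NA, 5), runif(n - 5, 0.3, 0.6)))
  samples <- sprintf("S%02d", 1:n)
  colnames(v) <- samples
  ## construct a weak-correlation probe: tiny monotone component
  set.seed(9)
  repeat {
    x <- runif(n)
    r <- suppressWarnings(cor(x, ranks, method = "spearman"))
    if (abs(r) < 0.1 && abs(r) > 0.01) break
  }
  v["island_weak", ] <- x
  b <- BetaMatrix(v)
  man <- manifestFixture(
    rownames(v),
    cpg_relation = c("CpG island", "CpG island", "CpG island", "N_shore",
                     "CpG island", "CpG island", "CpG island"),
    gene_symbols = list("GA", "GA", character(0), "GA", "GC", "GB", "GD"))
  expr <- rbind(GA = as.numeric(ranks), GB = as.numeric(ranks),
                GC = rep(2, n), GD = as.numeric(ranks))
  colnames(expr) <- samples
  res <- geneBranchProbeFilter(b, man, expr)
  expect_setequal(res$retained, c("island_corr", "island_anti"))
  expect_equal(unname(res$rho["island_anti"]), -1)
  reasons <- setNames(res$reasons$reason, res$reasons$probe_id)
  expect_equal(unname(reasons["island_nogene"]), "no-gene")
  expect_equal(unname(reasons["not_island"]), "not-cpg-island")
  expect_equal(unname(reasons["island_flat"]), "undefined-correlation")
  expect_equal(unname(reasons["island_weak"]), "low-correlation")
  expect_equal(unname(reasons["island_miss"]), "high-missing")
})

test_that("entropy metrics match direct entropy arithmetic", {
  # perfect dependence: probe equal to a balanced binary relabeling of y
  y <- rep(c("A", "B"), each = 4)
  xPerfect <- rep(c(0.1, 0.9), each = 4)
  X <- rbind(perfect = xPerfect, const = rep(0.5, 8))
  colnames(X) <- paste0("s", 1:8)
  er <- entropyRank(X, y, nBins = 2)
  expect_equal(er$info_gain[er$probe_id == "perfect"], 1)
  expect_equal(er$sym_uncertainty[er$probe_id == "perfect"], 1)
  expect_equal(er$info_gain[er$probe_id == "const"], 0)
  expect_equal(er$sym_uncertainty[er$probe_id == "const"], 0)
  expect_equal(er$probe_id[er$rank == 1], "perfect")

  # 2 bins x 2 classes with counts 3,1 / 1,3: IG = 1 - H(0.25)
  xMixed <- c(0.1, 0.1, 0.1, 0.1, 0.9, 0.9, 0.9, 0.9)
  yMixed <- c("A", "A", "A", "B", "A", "B", "B", "B")
  Xm <- rbind(mixed = xMixed); colnames(Xm) <- paste0("s", 1:8)
  erM <- entropyRank(Xm, yMixed, nBins = 2)
  h25 <- -(0.25 * log2(0.25) + 0.75 * log2(0.75))
  expect_equal(erM$info_gain, 1 - h25, tolerance = 1e-9)
  expect_equal(erM$gain_ratio, (1 - h25) / 1, tolerance = 1e-9)
  expect_equal(erM$sym_uncertainty, 2 * (1 - h25) / 2, tolerance = 1e-9)

  # metrics are invariant under monotone transforms of probe values
  set.seed(6)
  Xr <- matrix(runif(200), 5, 40,
               dimnames = list(paste0("p", 1:5), paste0("s", 1:40)))
  yr <- rep(c("A", "B"), 20)
  e1 <- entropyRank(Xr, yr)
  e2 <- entropyRank(qlogis(Xr * 0.98 + 0.01), yr)
  expect_equal(e1$info_gain, e2$info_gain, tolerance = 1e-12)
  expect_true(all(e1$sym_uncertainty >= 0 & e1$sym_uncertainty <= 1))
  expect_true(all(e1$info_gain <= 1 + 1e-12))  # <= H(Y) = 1 bit
})

test_that("quantile subsets are nested with ceiling sizes", {
  rk <- data.frame(probe_id = sprintf("p%03d", 1:278), rank = 1:278)
  qs <- quantileSubsets(rk)
  expect_length(qs$top100pct, 278)
  expect_length(qs$top50pct, 139)
  expect_length(qs$top10pct, 28)
  for (i in 2:length(qs))
    expect_true(all(qs[[i]] %in% qs[[i - 1]]))
  rk10 <- data.frame(probe_id = paste0("p", 1:10), rank = 1:10)
  expect_equal(quantileSubsets(rk10, 0.1)$top10pct, "p1")
})

test_that("the learner harness records dummy and oracle learners correctly", {
  sub <- makeSubtypeCohort(nSamples = 30, nProbes = 40, nInformativePerClass = 10, seed = 8)
  X <- assayValues(sub$beta)
  yProbs <- subtypeProbability(sub$pvals)
  dummy <- list(
    fit = function(X, y) sort(unique(y)),
    predictProb = function(model, X) {
      out <- matrix(0, nrow(X), length(model),
                    dimnames = list(NULL, model))
      out[, 1] <- 1  # always the first class
      out
    })
  oracle <- list(
    fit = function(X, y) NULL,
    predictProb = local({
      probs <- yProbs; Xall <- t(X)
      function(model, Xnew) {
        idx <- match(apply(Xnew, 1, paste, collapse = ","),
                     apply(Xall, 1, paste, collapse = ","))
        probs[idx, , drop = FALSE]
      }
    }))
  res <- evaluateLearners(X, sub$labels, yProbs,
                          list(dummy = dummy, oracle = oracle),
                          list(all = rownames(X)), repeats = 2, folds = 3,
                          seed = 5)
  # single-class dummy on a balanced 3-class cohort: 2/3 misclassified
  expect_equal(res$misclassification[res$learner == "dummy"],
               rep(2 / 3, 2), tolerance = 0.01)
  # the oracle reproduces the reference probabilities: deviation 0
  expect_equal(res$deviation[res$learner == "oracle"], rep(0, 2),
               tolerance = 1e-12)
  # oracle argmax equals the true label by construction of the cohort
  expect_equal(res$misclassification[res$learner == "oracle"], rep(0, 2))

  # determinism and learner-order invariance
  res2 <- evaluateLearners(X, sub$labels, yProbs,
                           list(oracle = oracle, dummy = dummy),
                           list(all = rownames(X)), repeats = 2, folds = 3,
                           seed = 5)
  for (l in c("dummy", "oracle"))
    expect_equal(res$misclassification[res$learner == l],
                 res2$misclassification[res2$learner == l])

  # a failing learner yields NA cells, not an aborted run
  broken <- list(fit = function(X, y) stop("boom"),
                 predictProb = function(m, X) NULL)
  res3 <- evaluateLearners(X, sub$labels, yProbs,
                           list(broken = broken, dummy = dummy),
                           list(all = rownames(X)), repeats = 1, folds = 3,
                           seed = 5)
  expect_true(all(is.na(res3$misclassification[res3$learner == "broken"])))
  expect_false(anyNA(res3$misclassification[res3$learner == "dummy"]))
})

test_that("the shipped learner set honours the fit/predictProb interface", {
  sub <- makeSubtypeCohort(nSamples = 36, nProbes = 30, nInformativePerClass = 8, seed = 12)
  X <- assayValues(sub$beta)
  lr <- subtypeLearners(ntree = 50)
  expect_named(lr, c("random_forest", "multinomial_enet", "knn",
                     "naive_bayes", "lda"))
  Xs <- t(X)
  tr <- seq_len(24); te <- 25:36
  for (nm in names(lr)) {
    set.seed(1)
    mod <- lr[[nm]]$fit(Xs[tr, ], sub$labels[tr])
    p <- lr[[nm]]$predictProb(mod, Xs[te, ])
    expect_equal(dim(p), c(12L, 3L), info = nm)
    expect_equal(unname(rowSums(p)), rep(1, 12), tolerance = 1e-6,
                 info = nm)
  }
})

test_that("random-forest subtype model is seeded, accurate and complete", {
  sub <- makeSubtypeCohort(seed = 31)
  X <- assayValues(betaToM(sub$beta))
  tr <- seq_len(100); te <- 101:150
  m1 <- trainSubtypeFinal(X[, tr], sub$labels[tr], seed = 3, ntree = 300)
  m2 <- trainSubtypeFinal(X[, tr], sub$labels[tr], seed = 3, ntree = 300)
  p1 <- predictSubtype(m1, X[, te]); p2 <- predictSubtype(m2, X[, te])
  expect_identical(p1, p2)
  probs <- as.matrix(p1[, paste0(m1@classes, "_prob")])
  expect_equal(unname(rowSums(probs)), rep(1, length(te)),
               tolerance = 1e-12)
  expect_gte(mean(p1$call == sub$labels[te]), 0.9)
  expect_error(predictSubtype(m1, X[1:5, te]), "missing")
  expect_error(trainSubtypeFinal(X, rep(c("CL", "MES"), 75)), "three")
})
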