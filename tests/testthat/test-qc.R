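test_that("static probe filter applies the four rules and keeps order", {
  man <- manifestFixture(
    sprintf("cg%03d", 1:10),
    chromosome = c("chr1", "chr2", "chrY", "chr4", "chr5", "chr6", "chr7",
                   "chr8", "chr9", "chr10"),
    snp_hit = c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                FALSE, FALSE),
    multi_hit = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
                  FALSE, FALSE),
    on_epic = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE,
                TRUE))
  res <- filterProbesStatic(man, "EPIC")
  expect_equal(res$retained, sprintf("cg%03d", c(1, 7, 8, 9, 10)))
  expect_equal(unname(res$removed["cg003"]), "non-autosomal")
  expect_equal(unname(res$removed["cg002"]), "snp-hit")
  expect_equal(unname(res$removed["cg004"]), "multi-hit")
  expect_equal(unname(res$removed["cg006"]), "off-platform")

  # chrX probes are non-autosomal too; a clean manifest passes untouched
  manX <- manifestFixture(c("cgA", "cgB"), chromosome = c("chrX", "chr3"))
  resX <- filterProbesStatic(manX, "EPIC")
  expect_equal(unname(resX$removed["cgA"]), "non-autosomal")
  clean <- manifestFixture(sprintf("cg%03d", 1:4))
  expect_equal(filterProbesStatic(clean, "EPIC")$retained,
               sprintf("cg%03d", 1:4))
})

test_that("cell masking uses beadcount <= 3 and detection p > 0.05", {
  v <- matrix(0.5, 3, 3)
  b <- betaFixture(v)
  detP <- matrix(0, 3, 3, dimnames = dimnames(assayValues(b)))
  bead <- matrix(10, 3, 3, dimnames = dimnames(assayValues(b)))
  # boundary: beadcount exactly 3 masked, 4 kept; detP exactly 0.05 kept
  bead[1, 1] <- 3; bead[1, 2] <- 4
  detP[2, 1] <- 0.05; detP[2, 2] <- 0.051
  # one overlapping failure: both rules hit the same cell
  bead[3, 3] <- 2; detP[3, 3] <- 0.9
  res <- maskLowQuality(b, detP, bead)
  masked <- is.na(assayValues(res$beta))
  expect_equal(sum(masked), 3L)
  expect_true(masked[1, 1] && masked[2, 2] && masked[3, 3])
  expect_false(masked[1, 2] || masked[2, 1])
  expect_equal(sum(res$maskedCells), 3L)  # overlap counted once

  # all-passing detection p is the identity
  res0 <- maskLowQuality(b, matrix(0, 3, 3,
                                   dimnames = dimnames(assayValues(b))))
  expect_identical(assayValues(res0$beta), assayValues(b))
  expect_error(maskLowQuality(b, matrix(0, 2, 2)), "axes")
})

test_that("missingness drops use strict inequality on both axes", {
  v <- matrix(0.5, 3, 10)
  v[1, 1:2] <- NA   # 2/10 = 0.2 > 0.1 -> dropped
  v[2, 1] <- NA     # 1/10 = 0.1, not > 0.1 -> kept
  b <- betaFixture(v)
  res <- dropMissingProbes(b)
  expect_equal(res$removed, "cg001")
  expect_equal(probeIDs(res$beta), c("cg002", "cg003"))

  v <- matrix(0.5, 100, 3)
  v[1:6, 1] <- NA   # 6% > 5% -> dropped
  v[1:5, 2] <- NA   # exactly 5% -> kept
  b <- betaFixture(v)
  res <- dropMissingSamples(b)
  expect_equal(res$removed, "S01")
  expect_equal(sampleIDs(res$beta), c("S02", "S03"))

  full <- betaFixture(matrix(0.4, 4, 4))
  expect_identical(assayValues(dropMissingProbes(full)$beta),
                   assayValues(full))
})

## Independent exhaustive-search oracle: all pairwise distances computed by
## explicit loops, neighbours picked by full sort.
knnOracle <- function(v, k) {
  out <- v
  p <- nrow(v)
  for (i in seq_len(p)) for (j in which(is.na(v[i, ]))) {
    d <- rep(Inf, p)
    for (q in seq_len(p)) {
      if (q == i) next
      ok <- which(!is.na(v[i, ]) & !is.na(v[q, ]))
      if (length(ok) == 0) next
      d[q] <- sqrt(sum((v[i, ok] - v[q, ok])^2) * ncol(v) / length(ok))
    }
    elig <- which(!is.na(v[, j]) & is.finite(d))
    nb <- elig[order(d[elig], elig)][seq_len(min(k, length(elig)))]
    out[i, j] <- mean(v[nb, j])
  }
  out
}

test_that("KNN imputation matches the exhaustive-neighbour oracle exactly", {
  # constant matrix: imputed with the constant
  v <- matrix(0.3, 4, 4); v[2, 3] <- NA
  expect_equal(assayValues(knnImpute(betaFixture(v), k = 2))[2, 3], 0.3)

  # k = 1 with an identical duplicate row copies the duplicate
  v <- matrix(runif(12, 0.2, 0.8), 3, 4)
  v[3, ] <- v[1, ]
  v[1, 2] <- NA
  b <- betaFixture(v)
  expect_equal(assayValues(knnImpute(b, k = 1))[1, 2], v[3, 2])

  # random instances up to 20x20 agree with the oracle exactly
  for (seed in 1:3) {
    set.seed(seed)
    p <- sample(6:20, 1); n <- sample(4:20, 1)
    v <- matrix(runif(p * n), p, n)
    v[sample(p * n, round(0.15 * p * n))] <- NA
    v[rowSums(!is.na(v)) == 0, 1] <- 0.5  # keep every probe observed once
    b <- betaFixture(v)
    got <- assayValues(knnImpute(b, k = 2))
    expect_identical(got, {
      o <- knnOracle(assayValues(b), 2); dimnames(o) <- dimnames(got); o
    })
  }

  # probe with no observed value is a named error
  v <- matrix(0.5, 3, 3); v[2, ] <- NA
  expect_error(knnImpute(betaFixture(v)), "cg002")
})

test_that("the QC cascade removes one offender per rule and is idempotent", {
  set.seed(1)
  n <- 20
  probes <- sprintf("cg%03d", 1:8)
  v <- matrix(runif(8 * n, 0.3, 0.7), 8, n,
              dimnames = list(probes, sprintf("S%02d", 1:n)))
  man <- manifestFixture(
    probes,
    chromosome = c("chrX", rep("chr2", 7)),
    snp_hit = c(FALSE, TRUE, rep(FALSE, 6)),
    multi_hit = c(FALSE, FALSE, TRUE, rep(FALSE, 5)),
    on_epic = c(TRUE, TRUE, TRUE, FALSE, rep(TRUE, 4)))
  detP <- matrix(0, 8, n, dimnames = dimnames(v))
  bead <- matrix(10, 8, n, dimnames = dimnames(v))
  detP[5, 1:3] <- 0.5            # probe 5: 3/20 = 15% missing -> dropped
  bead[6:8, 4] <- 3              # sample 4 loses 3/5 remaining probes
  res <- runQCPipeline(v_to_beta <- betaFixture(v), man, detP, bead)
  rep <- res$report
  expect_equal(unname(rep@removedProbes[c("cg001", "cg002", "cg003",
                                          "cg004", "cg005")]),
               c("non-autosomal", "snp-hit", "multi-hit", "off-platform",
                 "high-missing-probe"))
  expect_equal(unname(rep@removedSamples["S04"]), "high-missing-sample")
  expect_equal(sum(is.na(assayValues(res$beta))), 0L)
  expect_equal(rep@maskedCells[["detection-p"]], 3L)
  expect_equal(rep@maskedCells[["beadcount"]], 3L)

  # idempotence: rerunning on the cleaned output changes nothing
  res2 <- runQCPipeline(res$beta, man)
  expect_identical(assayValues(res2$beta), assayValues(res$beta))
  expect_length(res2$report@removedProbes, 0L)
  expect_length(res2$report@removedSamples, 0L)

  # clean input: identity and an empty report
  clean <- betaFixture(matrix(0.5, 3, 5))
  res3 <- runQCPipeline(clean)
  expect_identical(assayValues(res3$beta), assayValues(clean))
  expect_length(res3$report@removedProbes, 0L)
})
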