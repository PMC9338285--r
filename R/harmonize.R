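## Cross-platform (HM27K/HM450K-style) harmonization utilities and the
## three-step admixture harness for evaluating batch-adjustment methods:
## (1) cluster a single-platform dataset into a gold standard, (2) cluster
## platform admixtures, (3) repeat with an adjustment applied and compare
## memberships against the gold standard.

#' Merge two platforms on their shared probes
#'
#' Rows are the probe-id intersection (in the first matrix's order); columns
#' are the union of the (disjoint) sample sets. Per-sample platform
#' provenance is returned alongside.
#'
#' @param bA,bB BetaMatrix objects with disjoint sample ids
#' @param platforms length-2 labels recorded per sample
#' @return list: beta (merged BetaMatrix), platform (named character per
#'   sample)
#' @export
intersectPlatforms <- function(bA, bB, platforms = c("HM450K", "HM27K")) {
  stopifnot(is(bA, "BetaMatrix"), is(bB, "BetaMatrix"))
  if (length(intersect(sampleIDs(bA), sampleIDs(bB))))
    stop("sample ids must be disjoint between platforms")
  shared <- intersect(probeIDs(bA), probeIDs(bB))
  if (length(shared) == 0L) stop("no probes shared between the platforms")
  merged <- cbind(assayValues(bA)[shared, , drop = FALSE],
                  assayValues(bB)[shared, , drop = FALSE])
  prov <- setNames(rep(platforms, c(ncol(assayValues(bA)),
                                    ncol(assayValues(bB)))),
                   colnames(merged))
  list(beta = BetaMatrix(merged), platform = prov)
}

#' Top probes by median absolute deviation
#'
#' @param b a BetaMatrix (or plain matrix)
#' @param n number of probes to keep; must not exceed the probe count
#' @return probe ids of the n largest-MAD probes, ties broken by probe id
#' @export
madTopProbes <- function(b, n) {
  v <- .asMatrixInput(b)
  if (n > nrow(v)) stop("n exceeds probe count (", nrow(v), ")")
  m <- apply(v, 1L, mad, na.rm = TRUE)
  rownames(v)[order(-m, rownames(v))][seq_len(n)]
}

## One multiplicative-update Frobenius NMF run; returns per-sample cluster
## as the argmax basis coefficient.
.nmfRun <- function(V, k, maxIter = 200L, tol = 1e-6) {
  p <- nrow(V); n <- ncol(V)
  W <- matrix(runif(p * k, 0.1, 1), p, k)
  H <- matrix(runif(k * n, 0.1, 1), k, n)
  eps <- 1e-12
  prev <- Inf
  for (it in seq_len(maxIter)) {
    H <- H * (crossprod(W, V) / (crossprod(W, W %*% H) + eps))
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    if (it %% 10L == 0L) {
      obj <- sum((V - W %*% H)^2)
      if (is.finite(prev) && abs(prev - obj) <= tol * max(prev, eps)) break
      prev <- obj
    }
  }
  ## weight coefficients by basis-column norms so argmax is scale-invariant
  apply(H * sqrt(colSums(W^2)), 2L, which.max)
}

#' Consensus non-negative matrix factorization clustering
#'
#' Runs \code{nRuns} multiplicative-update Frobenius NMF factorizations from
#' seeded random initializations, assigns each sample per run to its argmax
#' basis component, accumulates the co-clustering frequency into a consensus
#' matrix, and cuts average-linkage hierarchical clustering of
#' (1 - consensus) into k groups for the final membership.
#'
#' @param b BetaMatrix or non-negative matrix (probes by samples)
#' @param k cluster count (>= 2)
#' @param nRuns number of NMF restarts (default 30)
#' @param seed integer seed
#' @param maxIter,tol NMF stopping rule (200 iterations or 1e-6 relative
#'   objective change)
#' @return a \linkS4class{ClusterMembership}
#' @export
consensusNMF <- function(b, k, nRuns = 30L, seed = 1L, maxIter = 200L,
                         tol = 1e-6) {
  V <- .asMatrixInput(b)
  stopifnot(k >= 2L, nRuns >= 1L)
  if (anyNA(V)) stop("matrix must be complete")
  if (any(V < 0)) stop("NMF requires non-negative values")
  n <- ncol(V)
  co <- matrix(0, n, n, dimnames = list(colnames(V), colnames(V)))
  for (r in seq_len(nRuns)) {
    set.seed(.subSeed(seed, r))
    cl <- .nmfRun(V, k, maxIter, tol)
    co <- co + outer(cl, cl, "==")
  }
  consensus <- co / nRuns
  hc <- hclust(as.dist(1 - consensus), method = "average")
  memb <- cutree(hc, k = k)
  new("ClusterMembership", membership = setNames(as.integer(memb),
                                                 colnames(V)),
      k = as.integer(k), consensus = consensus)
}

#' Simulate a platform admixture from a paired cohort
#'
#' Both matrices must profile the same individuals on shared probes. Each
#' individual is contributed by exactly one platform; a seeded draw without
#' replacement puts round(fracA * n) individuals on platform A and the rest
#' on platform B.
#'
#' @param bA,bB BetaMatrix objects with identical sample ids (one per
#'   individual) and shared probes
#' @param fracA fraction of individuals drawn from platform A
#' @param seed integer seed
#' @return list: beta (merged BetaMatrix on the shared probes, original
#'   sample order), platform (named character, "A" or "B" per sample)
#' @export
makeAdmixture <- function(bA, bB, fracA, seed = 1L) {
  stopifnot(is(bA, "BetaMatrix"), is(bB, "BetaMatrix"),
            fracA >= 0, fracA <= 1)
  ids <- sampleIDs(bA)
  if (!setequal(ids, sampleIDs(bB)))
    stop("individual missing from one platform: ",
         c(setdiff(ids, sampleIDs(bB)), setdiff(sampleIDs(bB), ids))[1L])
  shared <- intersect(probeIDs(bA), probeIDs(bB))
  if (!length(shared)) stop("no shared probes")
  set.seed(seed)
  nA <- round(fracA * length(ids))
  fromA <- ids[sample.int(length(ids), nA)]
  vA <- assayValues(bA)[shared, , drop = FALSE]
  vB <- assayValues(bB)[shared, , drop = FALSE]
  out <- vB[, ids, drop = FALSE]
  out[, fromA] <- vA[, fromA]
  plat <- setNames(ifelse(ids %in% fromA, "A", "B"), ids)
  list(beta = BetaMatrix(out), platform = plat)
}

#' Best label-matching agreement between two cluster memberships
#'
#' The maximum agreement fraction over all one-to-one relabelings of the
#' second membership onto the first (exhaustive over permutations; cluster
#' counts up to 7 are supported). Symmetric, permutation-invariant, and 1
#' iff the memberships are identical up to relabeling.
#'
#' @param a,b \linkS4class{ClusterMembership} objects (or named integer
#'   vectors) on the same samples
#' @return agreement fraction in \[0,1\]
#' @export
membershipConcordance <- function(a, b) {
  ma <- if (is(a, "ClusterMembership")) a@membership else a
  mb <- if (is(b, "ClusterMembership")) b@membership else b
  if (!setequal(names(ma), names(mb)))
    stop("memberships cover different sample sets")
  mb <- mb[names(ma)]
  labs <- sort(unique(c(ma, mb)))
  if (length(labs) > 7L) stop("more than 7 cluster labels not supported")
  perms <- .permutations(length(labs))
  best <- 0
  for (i in seq_len(nrow(perms))) {
    relab <- labs[perms[i, ]][match(mb, labs)]
    best <- max(best, mean(ma == relab))
  }
  best
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Reference moment-matching batch adjustment
#'
#' For each probe, values of platform-B samples are rescaled to match the
#' mean and standard deviation of platform-A samples for that probe, then
#' clamped to \[0,1\]. A simple, transparent adjustment used as the built-in
#' baseline in the evaluation harness; any callable with the same signature
#' can replace it.
#'
#' @param b a BetaMatrix
#' @param platform named character per sample ("A"/"B")
#' @return an adjusted BetaMatrix on the same axes
#' @export
momentMatchAdjust <- function(b, platform) {
  v <- assayValues(b)
  pa <- names(platform)[platform == "A"]
  pb <- names(platform)[platform == "B"]
  if (!length(pa) || !length(pb)) return(b)
  for (i in seq_len(nrow(v))) {
    mA <- mean(v[i, pa]); sA <- sd(v[i, pa])
    mB <- mean(v[i, pb]); sB <- sd(v[i, pb])
    if (is.na(sB) || sB == 0) next
    if (is.na(sA)) sA <- sB
    v[i, pb] <- pmin(1, pmax(0, (v[i, pb] - mB) / sB * sA + mA))
  }
  BetaMatrix(v)
}

#' Admixture evaluation harness for batch-adjustment methods
#'
#' Builds the gold standard by consensus-NMF clustering of the platform-A
#' (bias-free) dataset on its top-MAD probes — asserting first that the two
#' probe counts in \code{nTop} give concordant gold standards — then, for
#' each admixture fraction, clusters the admixed dataset with and without
#' the adjustment and reports membership concordance against the gold
#' standard.
#'
#' @param adjust NULL (identity) or a function(BetaMatrix, platform) ->
#'   BetaMatrix on the same axes
#' @param bA,bB paired BetaMatrix objects (same individuals)
#' @param k cluster count
#' @param fracs admixture fractions of platform A (default 0.25/0.5/0.75)
#' @param nTop length-2 MAD probe counts for the gold standard (the first is
#'   used downstream)
#' @param nRuns NMF restarts
#' @param seed integer seed
#' @return list: gold (ClusterMembership), table (data.frame: frac,
#'   adjusted, concordance), goldConcordance (between the two nTop gold
#'   standards)
#' @export
evaluateAdjustment <- function(adjust, bA, bB, k, fracs = c(0.25, 0.5, 0.75),
                               nTop = c(1000L, 2000L), nRuns = 30L,
                               seed = 1L) {
  stopifnot(is.null(adjust) || is.function(adjust), length(nTop) == 2L)
  nTop <- pmin(nTop, nrow(assayValues(bA)))
  gold1 <- consensusNMF(BetaMatrix(
    assayValues(bA)[madTopProbes(bA, nTop[1L]), , drop = FALSE]), k,
    nRuns, .subSeed(seed, 1L))
  gold2 <- consensusNMF(BetaMatrix(
    assayValues(bA)[madTopProbes(bA, nTop[2L]), , drop = FALSE]), k,
    nRuns, .subSeed(seed, 2L))
  goldConc <- membershipConcordance(gold1, gold2)
  rows <- list()
  for (i in seq_along(fracs)) {
    adm <- makeAdmixture(bA, bB, fracs[i], .subSeed(seed, 10L + i))
    for (adj in c(FALSE, TRUE)) {
      bb <- adm$beta
      if (adj && !is.null(adjust)) bb <- adjust(bb, adm$platform)
      sel <- madTopProbes(bb, nTop[1L])
      cl <- consensusNMF(BetaMatrix(
        assayValues(bb)[sel, , drop = FALSE]), k, nRuns,
        .subSeed(seed, 100L + i))
      rows[[length(rows) + 1L]] <- data.frame(
        frac = fracs[i], adjusted = adj,
        concordance = membershipConcordance(gold1, cl))
    }
  }
  list(gold = gold1, goldConcordance = goldConc,
       table = do.call(rbind, rows))
}
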