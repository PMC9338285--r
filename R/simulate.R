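## Seeded synthetic cohort generators. They emulate the statistical structure
## the pipeline assumes — bimodal methylation-like baselines, planted
## differential probes of stated effect size, detection/beadcount artifacts,
## and an Infinium-II-style dynamic-range compression — so every stage is
## testable without access-restricted array data.

.clampBeta <- function(x, lo = 0.001, hi = 0.999) {
  x[] <- pmin(hi, pmax(lo, x))  # pmin/pmax would drop dim attributes
  x
}

#' Generate a synthetic probe manifest
#'
#' Probes are spread over the 22 autosomes plus X/Y; CpG-island relation,
#' gene structure, gene symbols, platform flags, SNP/multi-mapping flags and
#' probe chemistry are drawn at configurable rates.
#'
#' @param nProbes number of probes (>= 1)
#' @param seed integer seed
#' @param rates named list overriding any of: sexChrom (fraction on X/Y),
#'   snpHit, multiHit, onEpic, onHm27k, typeII, noGene
#' @return a \linkS4class{ProbeManifest} with probe ids cg000001..
#' @export
makeManifest <- function(nProbes, seed = 1L, rates = list()) {
  stopifnot(nProbes >= 1L)
  r <- modifyList(list(sexChrom = 0.05, snpHit = 0.05, multiHit = 0.03,
                       onEpic = 0.92, onHm27k = 0.08, typeII = 0.72,
                       noGene = 0.2), rates)
  set.seed(seed)
  chromW <- c(rep((1 - r$sexChrom) / 22, 22), r$sexChrom * 0.7,
              r$sexChrom * 0.3)
  chrom <- sample(.CHROMOSOMES, nProbes, replace = TRUE, prob = chromW)
  cpg <- sample(.CPG_RELATIONS, nProbes, replace = TRUE,
                prob = c(0.35, 0.05, 0.05, 0.15, 0.15, 0.25))
  struct <- sample(.GENE_STRUCTURES, nProbes, replace = TRUE,
                   prob = c(0.10, 0.15, 0.35, 0.05, 0.10, 0.10, 0.15))
  pool <- sprintf("GENE%04d", seq_len(max(10L, nProbes %/% 5L)))
  genes <- lapply(seq_len(nProbes), function(i) {
    if (runif(1) < r$noGene) character(0) else
      sample(pool, sample(1:3, 1L, prob = c(0.75, 0.2, 0.05)))
  })
  df <- data.frame(
    probe_id = sprintf("cg%06d", seq_len(nProbes)),
    chromosome = chrom,
    position = sample.int(2e8, nProbes, replace = TRUE),
    cpg_relation = cpg, gene_structure = struct,
    on_hm27k = runif(nProbes) < r$onHm27k,
    on_hm450k = TRUE,
    on_epic = runif(nProbes) < r$onEpic,
    snp_hit = runif(nProbes) < r$snpHit,
    multi_hit = runif(nProbes) < r$multiHit,
    infinium_type = ifelse(runif(nProbes) < r$typeII, "II", "I"),
    stringsAsFactors = FALSE)
  df$gene_symbols <- genes
  new("ProbeManifest", table = df)
}

#' Generate a two-class beta-value cohort with planted differential probes
#'
#' Non-informative probes share a class-independent bimodal baseline
#' (mixture of Beta(2,8) and Beta(8,2) probe means); informative probes
#' shift their mean by deltaBeta between the two classes (random sign).
#' Per-cell Gaussian noise is added and values clamped to (0,1). Detection
#' artifacts are injected at \code{missingRate}: failing cells get
#' detection p ~ U(0.05, 1), passing cells ~ U(0, 0.01); a small fraction
#' of cells additionally receives beadcount <= 3.
#'
#' @param nSamples,nProbes cohort dimensions (defaults 300 x 2000)
#' @param nInformative number of planted differential probes (default 50)
#' @param deltaBeta planted mean difference on the beta scale (default 0.3)
#' @param missingRate detection-failure cell rate (default 0.01)
#' @param beadLowRate low-beadcount cell rate (default 0.002)
#' @param noiseSD per-cell Gaussian noise sd (default 0.05)
#' @param seed integer seed
#' @return list: beta (BetaMatrix), labels (0/1 per sample), detectionP,
#'   beadcount (matrices), truth (list: informative, deltaBeta, labels,
#'   failingCells, seed)
#' @export
makeBinaryCohort <- function(nSamples = 300L, nProbes = 2000L,
                             nInformative = 50L, deltaBeta = 0.3,
                             missingRate = 0.01, beadLowRate = 0.002,
                             noiseSD = 0.05, seed = 1L) {
  stopifnot(nInformative <= nProbes, deltaBeta >= 0, deltaBeta < 1,
            missingRate >= 0, missingRate <= 1)
  set.seed(seed)
  probes <- sprintf("cg%06d", seq_len(nProbes))
  samples <- sprintf("S%04d", seq_len(nSamples))
  labels <- rep(0:1, length.out = nSamples)[sample.int(nSamples)]
  hyper <- runif(nProbes) < 0.5
  base <- ifelse(hyper, rbeta(nProbes, 8, 2), rbeta(nProbes, 2, 8))
  inf <- sample.int(nProbes, nInformative)
  ## informative baselines kept central enough that the shift survives
  ## clamping
  base[inf] <- runif(nInformative, 0.15, 1 - 0.15 - deltaBeta)
  sign <- sample(c(-1, 1), nProbes, replace = TRUE)
  mu <- matrix(base, nProbes, nSamples)
  shift <- matrix(0, nProbes, nSamples)
  shift[inf, labels == 1L] <- deltaBeta
  ## random per-probe direction: half the planted probes hypo- rather than
  ## hyper-methylated in the positive class
  flip <- inf[sign[inf] < 0]
  mu[flip, ] <- mu[flip, ] + deltaBeta
  shift[flip, ] <- -shift[flip, ]
  v <- .clampBeta(mu + shift + matrix(rnorm(nProbes * nSamples, 0, noiseSD),
                                      nProbes, nSamples))
  dimnames(v) <- list(probes, samples)
  nc <- nProbes * nSamples
  detP <- matrix(runif(nc, 0, 0.01), nProbes, nSamples,
                 dimnames = dimnames(v))
  failing <- which(runif(nc) < missingRate)
  detP[failing] <- runif(length(failing), 0.05, 1)
  bead <- matrix(4L + rpois(nc, 14), nProbes, nSamples,
                 dimnames = dimnames(v))
  lowBead <- which(runif(nc) < beadLowRate)
  bead[lowBead] <- sample(1:3, length(lowBead), replace = TRUE)
  list(beta = BetaMatrix(v), labels = setNames(labels, samples),
       detectionP = detP, beadcount = bead,
       truth = list(informative = probes[inf], deltaBeta = deltaBeta,
                    labels = setNames(labels, samples),
                    failingCells = failing, lowBeadCells = lowBead,
                    seed = seed))
}

#' Generate a three-class (CL/MES/PN) subtype cohort
#'
#' Each class owns a block of informative probes shifted by deltaBeta in
#' its samples; empirical per-subtype p-values are drawn low (U(0, 0.05))
#' for the true class and high (U(0.6, 1)) for the others, emulating
#' permutation tests that confidently reject the wrong subtypes.
#'
#' @param nSamples,nProbes cohort dimensions (defaults 150 x 600)
#' @param nInformativePerClass planted probes per class (default 30)
#' @param deltaBeta planted shift on the beta scale (default 0.3)
#' @param noiseSD per-cell noise sd (default 0.05)
#' @param seed integer seed
#' @return list: beta (BetaMatrix), labels (CL/MES/PN per sample), pvals
#'   (samples-by-3 matrix, columns CL/MES/PN), truth (list: informative per
#'   class, deltaBeta, seed)
#' @export
makeSubtypeCohort <- function(nSamples = 150L, nProbes = 600L,
                              nInformativePerClass = 30L, deltaBeta = 0.3,
                              noiseSD = 0.05, seed = 1L) {
  stopifnot(3L * nInformativePerClass <= nProbes, nSamples >= 9L)
  set.seed(seed)
  probes <- sprintf("cg%06d", seq_len(nProbes))
  samples <- sprintf("S%04d", seq_len(nSamples))
  labels <- rep(.SUBTYPES, length.out = nSamples)[sample.int(nSamples)]
  hyper <- runif(nProbes) < 0.5
  base <- ifelse(hyper, rbeta(nProbes, 8, 2), rbeta(nProbes, 2, 8))
  blocks <- split(sample.int(nProbes, 3L * nInformativePerClass),
                  rep(.SUBTYPES, each = nInformativePerClass))
  for (cl in .SUBTYPES)
    base[blocks[[cl]]] <- runif(nInformativePerClass, 0.15,
                                1 - 0.15 - deltaBeta)
  mu <- matrix(base, nProbes, nSamples)
  for (cl in .SUBTYPES)
    mu[blocks[[cl]], labels == cl] <- mu[blocks[[cl]], labels == cl] +
      deltaBeta
  v <- .clampBeta(mu + matrix(rnorm(nProbes * nSamples, 0, noiseSD),
                              nProbes, nSamples))
  dimnames(v) <- list(probes, samples)
  pv <- matrix(runif(3L * nSamples, 0.6, 1), nSamples, 3L,
               dimnames = list(samples, .SUBTYPES))
  for (cl in .SUBTYPES)
    pv[labels == cl, cl] <- runif(sum(labels == cl), 0, 0.05)
  list(beta = BetaMatrix(v), labels = setNames(labels, samples), pvals = pv,
       truth = list(informative = blocks, deltaBeta = deltaBeta,
                    seed = seed))
}

#' Derive a paired two-platform dataset with Infinium-II-style bias
#'
#' Platform A reproduces the cohort (plus independent noise); platform B
#' compresses the dynamic range of the probes assigned type II chemistry:
#' beta' = 0.5 + c (beta - 0.5), c in (0,1], plus independent noise. At
#' c = 1 and zero noise the platforms are identical.
#'
#' @param beta a BetaMatrix (the underlying biology, one column per
#'   individual)
#' @param compressionC dynamic-range compression factor c (default 0.6)
#' @param typeIIFraction fraction of probes assigned type II on platform B
#'   (default 0.72), ignored when typeII is given
#' @param typeII optional explicit character vector of type-II probe ids
#' @param noiseSD independent per-platform noise sd (default 0.01)
#' @param seed integer seed
#' @return list: platformA, platformB (BetaMatrix, same axes), typeII
#'   (probe ids compressed on platform B), compressionC
#' @export
makePlatformPair <- function(beta, compressionC = 0.6,
                             typeIIFraction = 0.72, typeII = NULL,
                             noiseSD = 0.01, seed = 1L) {
  stopifnot(is(beta, "BetaMatrix"), compressionC > 0, compressionC <= 1)
  v <- assayValues(beta)
  set.seed(seed)
  if (is.null(typeII))
    typeII <- rownames(v)[runif(nrow(v)) < typeIIFraction]
  vA <- .clampBeta(v + matrix(rnorm(length(v), 0, noiseSD), nrow(v)))
  vB <- v
  vB[typeII, ] <- 0.5 + compressionC * (vB[typeII, ] - 0.5)
  vB <- .clampBeta(vB + matrix(rnorm(length(v), 0, noiseSD), nrow(v)))
  dimnames(vA) <- dimnames(vB) <- dimnames(v)
  list(platformA = BetaMatrix(vA), platformB = BetaMatrix(vB),
       typeII = typeII, compressionC = compressionC)
}

#' Exact inverse of the type-II compression bias
#'
#' Returns an adjustment callable for
#' \code{\link{evaluateAdjustment}} that inverts
#' beta' = 0.5 + c (beta - 0.5) on the given probes of platform-B samples.
#' Used as the oracle adjustment in tests of the harness.
#'
#' @param typeII probe ids that were compressed
#' @param compressionC the compression factor used
#' @return function(BetaMatrix, platform) -> BetaMatrix
#' @export
oracleInverseAdjustment <- function(typeII, compressionC) {
  function(b, platform) {
    v <- assayValues(b)
    pb <- names(platform)[platform == "B"]
    rows <- intersect(typeII, rownames(v))
    v[rows, pb] <- .clampBeta(0.5 + (v[rows, pb] - 0.5) / compressionC)
    BetaMatrix(v)
  }
}
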