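## Probe/sample quality-control cascade for the binary-alteration branch:
## static manifest filters -> cell masking -> probe missingness -> sample
## missingness -> KNN imputation. Masked cells count toward the missingness
## thresholds; both drop rules use strict inequality ("more than").

#' Static manifest-driven probe filter
#'
#' Retains probes that are autosomal, not SNP-proximal, uniquely mapping and
#' present on the target platform. Order is preserved.
#'
#' @param manifest a \linkS4class{ProbeManifest}
#' @param targetPlatform "EPIC" (default), "HM450K" or "HM27K"
#' @return list with \code{retained} (probe ids) and \code{removed}
#'   (named character, probe id -> reason code among "non-autosomal",
#'   "snp-hit", "multi-hit", "off-platform")
#' @export
filterProbesStatic <- function(manifest, targetPlatform = "EPIC") {
  stopifnot(is(manifest, "ProbeManifest"),
            targetPlatform %in% .PLATFORMS)
  tb <- annotationTable(manifest)
  flag <- switch(targetPlatform, EPIC = tb$on_epic, HM450K = tb$on_hm450k,
                 HM27K = tb$on_hm27k)
  reason <- rep(NA_character_, nrow(tb))
  reason[!flag] <- "off-platform"
  reason[tb$multi_hit] <- "multi-hit"
  reason[tb$snp_hit] <- "snp-hit"
  reason[!(tb$chromosome %in% .AUTOSOMES)] <- "non-autosomal"
  keep <- is.na(reason)
  if (!any(keep)) warning("static probe filter removed every probe")
  list(retained = tb$probe_id[keep],
       removed = setNames(reason[!keep], tb$probe_id[!keep]))
}

#' Mask unreliable cells by detection p-value and beadcount
#'
#' Cells with detection p > 0.05 or beadcount <= 3 are set missing; all other
#' cells are untouched. Either auxiliary matrix may be absent.
#'
#' @param b a \linkS4class{BetaMatrix}
#' @param detectionP optional same-shape matrix of detection p-values
#' @param beadcount optional same-shape matrix of bead counts
#' @param maxDetectionP,minBeadcount thresholds (defaults 0.05 and 3;
#'   failure is strictly above / at-or-below respectively)
#' @return list with \code{beta} (masked BetaMatrix) and \code{maskedCells}
#'   (named integer counts per reason)
#' @export
maskLowQuality <- function(b, detectionP = NULL, beadcount = NULL,
                           maxDetectionP = 0.05, minBeadcount = 3) {
  stopifnot(is(b, "BetaMatrix"))
  v <- assayValues(b)
  checkAxes <- function(m, what) {
    if (!identical(dim(m), dim(v)) ||
        !identical(rownames(m), rownames(v)) ||
        !identical(colnames(m), colnames(v)))
      stop(what, " matrix does not share axes with the beta matrix")
  }
  masked <- c(`detection-p` = 0L, beadcount = 0L)
  if (!is.null(detectionP)) {
    checkAxes(detectionP, "detection-p")
    fail <- !is.na(detectionP) & detectionP > maxDetectionP & !is.na(v)
    masked["detection-p"] <- sum(fail)
    v[fail] <- NA_real_
  }
  if (!is.null(beadcount)) {
    checkAxes(beadcount, "beadcount")
    fail <- !is.na(beadcount) & beadcount <= minBeadcount & !is.na(v)
    masked["beadcount"] <- sum(fail)
    v[fail] <- NA_real_
  }
  list(beta = BetaMatrix(v), maskedCells = masked)
}

#' Drop probes with too many missing values
#'
#' A probe is removed iff its missing fraction across samples is strictly
#' greater than \code{maxFrac} ("more than 10 percent"); a probe at exactly
#' the threshold is kept.
#'
#' @param b a \linkS4class{BetaMatrix}
#' @param maxFrac missingness threshold in \[0,1\], default 0.10
#' @return list with \code{beta} and \code{removed} (probe ids)
#' @export
dropMissingProbes <- function(b, maxFrac = 0.10) {
  stopifnot(is(b, "BetaMatrix"), maxFrac >= 0, maxFrac <= 1)
  v <- assayValues(b)
  frac <- rowMeans(is.na(v))
  drop <- frac > maxFrac
  list(beta = BetaMatrix(v[!drop, , drop = FALSE]),
       removed = rownames(v)[drop])
}

#' Drop samples with too many missing values
#'
#' Mirror of \code{\link{dropMissingProbes}} on the sample axis: removal iff
#' the missing fraction across probes is strictly greater than
#' \code{maxFrac} (default 0.05).
#'
#' @param b a \linkS4class{BetaMatrix}
#' @param maxFrac missingness threshold in \[0,1\], default 0.05
#' @return list with \code{beta} and \code{removed} (sample ids)
#' @export
dropMissingSamples <- function(b, maxFrac = 0.05) {
  stopifnot(is(b, "BetaMatrix"), maxFrac >= 0, maxFrac <= 1)
  v <- assayValues(b)
  frac <- colMeans(is.na(v))
  drop <- frac > maxFrac
  list(beta = BetaMatrix(v[, !drop, drop = FALSE]),
       removed = colnames(v)[drop])
}

## Scaled Euclidean distance between two probe rows over mutually observed
## samples: sqrt(sum (xi-yi)^2 * total/observed). No shared samples -> Inf.
.probeDistance <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n == 0L) return(Inf)
  sqrt(sum((x[ok] - y[ok])^2) * length(x) / n)
}

#' K-nearest-neighbour imputation over probe rows
#'
#' Each missing cell is replaced by the unweighted mean of the values, in
#' that sample, of the k nearest probes (Euclidean distance over mutually
#' observed samples, rescaled by the shared-coordinate count). Only probes
#' observed in the target sample are eligible neighbours; if fewer than k
#' exist, all of them are used. Observed cells are never altered.
#'
#' @param b a \linkS4class{BetaMatrix}; every probe must have at least one
#'   observed value
#' @param k neighbour count, default 10
#' @return a complete \linkS4class{BetaMatrix}
#' @export
knnImpute <- function(b, k = 10L) {
  stopifnot(is(b, "BetaMatrix"), k >= 1L)
  v <- assayValues(b)
  empty <- rownames(v)[rowSums(!is.na(v)) == 0L]
  if (length(empty))
    stop("probe(s) with no observed values cannot be imputed: ",
         paste(empty, collapse = ", "))
  if (!anyNA(v)) return(b)
  orig <- v  # distances and neighbour values use the pre-imputation matrix
  obs <- !is.na(orig)
  miss_rows <- which(rowSums(obs) < ncol(orig))
  for (i in miss_rows) {
    ## vectorized scaled Euclidean distance from probe i to every probe,
    ## over mutually observed samples (same arithmetic as .probeDistance)
    ok_i <- obs[i, ]
    diff2 <- sweep(orig[, ok_i, drop = FALSE], 2L, orig[i, ok_i])^2
    cnt <- rowSums(obs[, ok_i, drop = FALSE])
    sumsq <- rowSums(diff2, na.rm = TRUE)
    d <- ifelse(cnt == 0L, Inf, sqrt(sumsq * ncol(orig) / cnt))
    d[i] <- Inf
    for (j in which(is.na(orig[i, ]))) {
      cand <- which(!is.na(orig[, j]) & is.finite(d))
      if (length(cand) == 0L)
        stop("no eligible neighbour for probe ", rownames(v)[i],
             " in sample ", colnames(v)[j])
      ord <- cand[order(d[cand], cand)]
      nb <- ord[seq_len(min(k, length(ord)))]
      v[i, j] <- mean(orig[nb, j])
    }
  }
  BetaMatrix(v)
}

#' Run the full probe/sample QC cascade
#'
#' Applies, in fixed order: static manifest filters, detection-p/beadcount
#' cell masking, probe-missingness drop (> \code{maxProbeMissing}), sample-
#' missingness drop (> \code{maxSampleMissing}) and KNN imputation. The
#' returned matrix is complete; the report enumerates every removal with a
#' single primary reason. Re-running the cascade on its own output (without
#' auxiliary matrices) is the identity.
#'
#' @param b a \linkS4class{BetaMatrix}
#' @param manifest optional \linkS4class{ProbeManifest}; probes absent from
#'   it are removed with reason "unannotated"
#' @param detectionP,beadcount optional same-shape auxiliary matrices
#' @param targetPlatform platform flag for the static filter
#' @param maxProbeMissing,maxSampleMissing missingness thresholds
#' @param knnK imputation neighbour count; set NA to skip imputation
#' @return list with \code{beta} and \code{report} (a
#'   \linkS4class{QCReport})
#' @export
runQCPipeline <- function(b, manifest = NULL, detectionP = NULL,
                          beadcount = NULL, targetPlatform = "EPIC",
                          maxProbeMissing = 0.10, maxSampleMissing = 0.05,
                          knnK = 10L) {
  stopifnot(is(b, "BetaMatrix"))
  removedProbes <- character(0)
  v <- assayValues(b)
  if (!is.null(manifest)) {
    st <- filterProbesStatic(manifest, targetPlatform)
    unann <- setdiff(rownames(v), probeIDs(manifest))
    removedProbes <- c(setNames(rep("unannotated", length(unann)), unann),
                       st$removed[names(st$removed) %in% rownames(v)])
    keep <- intersect(rownames(v), st$retained)
    v <- v[keep, , drop = FALSE]
    if (!is.null(detectionP))
      detectionP <- detectionP[keep, , drop = FALSE]
    if (!is.null(beadcount))
      beadcount <- beadcount[keep, , drop = FALSE]
  }
  mk <- maskLowQuality(BetaMatrix(v), detectionP, beadcount)
  dp <- dropMissingProbes(mk$beta, maxProbeMissing)
  removedProbes <- c(removedProbes,
                     setNames(rep("high-missing-probe", length(dp$removed)),
                              dp$removed))
  ds <- dropMissingSamples(dp$beta, maxSampleMissing)
  removedSamples <- setNames(rep("high-missing-sample", length(ds$removed)),
                             ds$removed)
  out <- if (is.na(knnK)) ds$beta else knnImpute(ds$beta, knnK)
  report <- new("QCReport", removedProbes = removedProbes,
                removedSamples = removedSamples,
                maskedCells = mk$maskedCells,
                params = list(targetPlatform = targetPlatform,
                              maxProbeMissing = maxProbeMissing,
                              maxSampleMissing = maxSampleMissing,
                              knnK = knnK))
  list(beta = out, report = report)
}

#' Write a QC report as TSV (one row per removal/masking reason)
#'
#' @param report a \linkS4class{QCReport}
#' @param path destination file
#' @return invisibly, the path
#' @export
writeQCReport <- function(report, path) {
  block <- function(ids, axis, reasons, values)
    data.frame(id = ids, axis = rep_len(axis, length(ids)),
               reason = reasons, value = values, stringsAsFactors = FALSE)
  df <- rbind(
    block(names(report@removedProbes), "probe",
          unname(report@removedProbes),
          rep(NA_real_, length(report@removedProbes))),
    block(names(report@removedSamples), "sample",
          unname(report@removedSamples),
          rep(NA_real_, length(report@removedSamples))),
    block(rep("*", length(report@maskedCells)), "cell",
          names(report@maskedCells), as.numeric(report@maskedCells)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
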