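## Signature characterization: Wilcoxon top-probe selection, genomic-context
## enrichment with proportion tests, multi-set overlap counts, and the
## nine-group molecular grouping from the four predicted alteration calls.

#' Top differential probes by Wilcoxon rank-sum test
#'
#' Two-sided rank-sum p-value per probe between the two label groups; the n
#' smallest p-values win, ties broken by larger absolute median difference,
#' then probe id.
#'
#' @param X probes-by-samples matrix (or Beta/MValueMatrix)
#' @param labels binary group label per sample
#' @param n number of probes to return (0 gives an empty set)
#' @return data.frame: probe_id, p_value, median_diff, ordered best first
#' @export
wilcoxonTopProbes <- function(X, labels, n) {
  X <- .asMatrixInput(X)
  if (n > nrow(X)) stop("n exceeds probe count (", nrow(X), ")")
  y <- .binaryResponse(labels)
  if (!all(c(0L, 1L) %in% y)) stop("both classes must be non-empty")
  g1 <- y == 1L
  pv <- apply(X, 1L, function(x)
    suppressWarnings(wilcox.test(x[g1], x[!g1])$p.value))
  md <- apply(X, 1L, function(x) median(x[g1]) - median(x[!g1]))
  ord <- order(pv, -abs(md), rownames(X))
  out <- data.frame(probe_id = rownames(X)[ord], p_value = pv[ord],
                    median_diff = md[ord], stringsAsFactors = FALSE,
                    row.names = NULL)
  out[seq_len(n), , drop = FALSE]
}

## Two-sided exact binomial p-value: the probability mass of all outcomes no
## more likely than the observed count (the standard point-probability rule).
.exactBinomP <- function(x, n, p0) {
  if (p0 == 0) return(as.numeric(x == 0))
  if (p0 == 1) return(as.numeric(x == n))
  d <- dbinom(x, n, p0)
  min(1, sum(dbinom(0:n, n, p0)[dbinom(0:n, n, p0) <= d * (1 + 1e-7)]))
}

#' Genomic-context enrichment of a probe signature
#'
#' Per category of the chosen annotation (chromosome, CpG-island relation or
#' gene structure): the signature count, the background count, the
#' normalized proportion (sig/bg per category, renormalized to sum to 1
#' across categories), and a two-sided one-sample proportion test of the
#' signature's share of that category against the background share.
#' \code{method = "exact"} uses the exact binomial test (the default);
#' \code{"prop"} uses the chi-square proportion test with continuity
#' correction. Categories absent from the background are skipped with a
#' note attribute.
#'
#' @param signature probe ids, a subset of the manifest
#' @param manifest a \linkS4class{ProbeManifest} (its probes are the
#'   background)
#' @param by "chromosome", "cpg_relation" or "gene_structure"
#' @param method "exact" or "prop"
#' @return data.frame: category, sig_n, bg_n, norm_prop, p_value
#' @export
contextEnrichment <- function(signature, manifest,
                              by = c("chromosome", "cpg_relation",
                                     "gene_structure"),
                              method = c("exact", "prop")) {
  by <- match.arg(by)
  method <- match.arg(method)
  stopifnot(is(manifest, "ProbeManifest"))
  tb <- annotationTable(manifest)
  missing <- setdiff(signature, tb$probe_id)
  if (length(missing))
    stop("signature probe absent from manifest: ", missing[1L])
  cats <- unique(tb[[by]])
  inSig <- tb$probe_id %in% signature
  nSig <- sum(inSig); nBg <- nrow(tb)
  rows <- lapply(cats, function(cat) {
    bg <- sum(tb[[by]] == cat)
    sg <- sum(inSig & tb[[by]] == cat)
    p0 <- bg / nBg
    p <- if (method == "exact") .exactBinomP(sg, nSig, p0) else
      suppressWarnings(prop.test(sg, nSig, p = p0)$p.value)
    data.frame(category = cat, sig_n = sg, bg_n = bg,
               ratio = if (bg > 0) sg / bg else NA_real_, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tot <- sum(out$ratio, na.rm = TRUE)
  out$norm_prop <- if (tot > 0) out$ratio / tot else NA_real_
  out$ratio <- NULL
  out[, c("category", "sig_n", "bg_n", "norm_prop", "p_value")]
}

#' Gene frequency of a probe signature
#'
#' Counts each signature probe toward its first-listed gene only; probes
#' with no gene annotation accumulate in an "(unmapped)" bucket reported
#' separately.
#'
#' @param signature probe ids
#' @param manifest a \linkS4class{ProbeManifest}
#' @return data.frame: gene, n_probes, sorted by descending count then gene
#' @export
mapSignatureGenes <- function(signature, manifest) {
  tb <- annotationTable(manifest)
  idx <- match(signature, tb$probe_id)
  if (anyNA(idx)) stop("signature probe absent from manifest: ",
                       signature[is.na(idx)][1L])
  first <- vapply(tb$gene_symbols[idx], function(g)
    if (length(g)) g[1L] else "(unmapped)", character(1))
  cnt <- table(first)
  out <- data.frame(gene = names(cnt), n_probes = as.integer(cnt),
                    stringsAsFactors = FALSE)
  out[order(-out$n_probes, out$gene), , drop = FALSE]
}

#' Venn region counts over named probe sets
#'
#' One count per non-empty membership pattern; region counts sum to the size
#' of the union. Region keys join member set names with "&".
#'
#' @param signatures named list of >= 2 probe-id vectors
#' @return named integer vector of region counts (regions with zero members
#'   included)
#' @export
overlapCounts <- function(signatures) {
  stopifnot(length(signatures) >= 2L, !is.null(names(signatures)))
  nm <- names(signatures)
  universe <- unique(unlist(signatures))
  memb <- vapply(signatures, function(s) universe %in% s,
                 logical(length(universe)))
  if (length(universe) == 1L) memb <- matrix(memb, nrow = 1L,
                                             dimnames = list(NULL, nm))
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), length(nm)))[-1L, ,
                                                                 drop = FALSE]
  counts <- apply(patterns, 1L, function(pat)
    sum(apply(memb, 1L, function(row) all(row == pat))))
  keys <- apply(patterns, 1L, function(pat) paste(nm[as.logical(pat)],
                                                  collapse = "&"))
  setNames(as.integer(counts), keys)
}

#' Group samples by their predicted four-alteration profile
#'
#' Maps each sample's (IDH, chr1p19q, ATRX, TERTp) call tuple to a group.
#' With \code{config = NULL} the realized tuples are enumerated in
#' lexicographic order and labelled Grp1..GrpK; a config data.frame (columns
#' IDH, chr1p19q, ATRX, TERTp, group) pins the published tuple-to-group
#' table instead. Samples with any "unknown" call are flagged unassigned
#' (group NA).
#'
#' @param calls data.frame with columns sample_id, IDH, chr1p19q, ATRX,
#'   TERTp; values "positive"/"negative"/"unknown"
#' @param config optional tuple-to-group table as above
#' @return list: assignment (data.frame sample_id, group), groups
#'   (data.frame group, IDH, chr1p19q, ATRX, TERTp, n)
#' @export
assignUnidGroups <- function(calls, config = NULL) {
  need <- c("sample_id", "IDH", "chr1p19q", "ATRX", "TERTp")
  miss <- setdiff(need, names(calls))
  if (length(miss)) stop("missing calls column: ", miss[1L])
  keyOf <- function(df) paste(df$IDH, df$chr1p19q, df$ATRX, df$TERTp,
                              sep = "|")
  known <- calls$IDH != "unknown" & calls$chr1p19q != "unknown" &
    calls$ATRX != "unknown" & calls$TERTp != "unknown"
  key <- keyOf(calls)
  if (is.null(config)) {
    u <- sort(unique(key[known]))
    config <- do.call(rbind, lapply(seq_along(u), function(i) {
      parts <- strsplit(u[i], "|", fixed = TRUE)[[1L]]
      data.frame(IDH = parts[1L], chr1p19q = parts[2L], ATRX = parts[3L],
                 TERTp = parts[4L], group = paste0("Grp", i),
                 stringsAsFactors = FALSE)
    }))
  }
  if (anyDuplicated(keyOf(config)))
    stop("group config tuples must be mutually exclusive")
  grp <- config$group[match(key, keyOf(config))]
  grp[!known] <- NA_character_
  groups <- config
  groups$n <- as.integer(table(factor(grp, levels = config$group)))
  list(assignment = data.frame(sample_id = calls$sample_id, group = grp,
                               stringsAsFactors = FALSE),
       groups = groups[, c("group", "IDH", "chr1p19q", "ATRX", "TERTp",
                           "n")])
}
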