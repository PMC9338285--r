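#' @import methods
#' @importFrom stats median mad quantile rnorm runif rbeta rpois sd cor
#'   setNames p.adjust wilcox.test binom.test prop.test dbinom predict
#'   hclust cutree as.dist plogis qlogis
#' @importFrom utils read.delim write.table head modifyList
NULL

## Closed vocabularies shared by the manifest reader, the QC cascade and the
## enrichment analytics.
.CPG_RELATIONS <- c("CpG island", "N_shelf", "S_shelf", "N_shore", "S_shore",
                    "unknown")
.GENE_STRUCTURES <- c("TSS200", "TSS1500", "Body", "3'-UTR", "5'-UTR",
                      "1st Exon", "unknown")
.CHROMOSOMES <- c(paste0("chr", 1:22), "chrX", "chrY")
.AUTOSOMES <- paste0("chr", 1:22)
.PLATFORMS <- c("HM27K", "HM450K", "EPIC")
.ALTERATIONS <- c("IDH", "TERTp", "ATRX", "chr1p19q")
.SUBTYPES <- c("CL", "MES", "PN")
.MODEL_SCHEMA_VERSION <- "1.0"

#' BetaMatrix: probes-by-samples methylation beta values
#'
#' Container for Infinium array beta values (methylated-signal fractions).
#' Rows are probes, columns are samples; non-missing entries must lie in
#' \[0, 1\]. Missing entries (\code{NA}) are permitted and are what the QC
#' cascade masks and later imputes.
#'
#' @slot values numeric matrix with unique rownames (probe ids) and unique
#'   colnames (sample ids)
#' @exportClass BetaMatrix
setClass("BetaMatrix", representation(values = "matrix"))

setValidity("BetaMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must carry probe rownames and sample colnames")
  if (anyDuplicated(rownames(v)))
    return(sprintf("duplicate probe id: %s",
                   rownames(v)[duplicated(rownames(v))][1L]))
  if (anyDuplicated(colnames(v)))
    return(sprintf("duplicate sample id: %s",
                   colnames(v)[duplicated(colnames(v))][1L]))
  ok <- is.na(v) | (v >= 0 & v <= 1)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    return(sprintf("beta value out of [0,1] at probe '%s', sample '%s'",
                   rownames(v)[bad[1L]], colnames(v)[bad[2L]]))
  }
  TRUE
})

#' MValueMatrix: probes-by-samples M-values
#'
#' Log2-odds transform of a \linkS4class{BetaMatrix}. Non-missing entries
#' must be finite; axes mirror the source beta matrix.
#'
#' @slot values numeric matrix with unique probe rownames / sample colnames
#' @exportClass MValueMatrix
setClass("MValueMatrix", representation(values = "matrix"))

setValidity("MValueMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must carry probe rownames and sample colnames")
  if (anyDuplicated(rownames(v)) || anyDuplicated(colnames(v)))
    return("duplicate probe or sample id")
  if (any(!is.na(v) & !is.finite(v)))
    return("non-finite M-value present")
  TRUE
})

#' ProbeManifest: per-probe genomic and platform annotation
#'
#' Drives the static QC filters (autosome / SNP / multi-mapping / platform)
#' and the genomic-context enrichment analytics. The annotation table has one
#' row per probe with columns \code{probe_id}, \code{chromosome},
#' \code{position}, \code{cpg_relation}, \code{gene_structure},
#' \code{gene_symbols} (list column, possibly empty, order meaningful),
#' \code{on_hm27k}, \code{on_hm450k}, \code{on_epic}, \code{snp_hit},
#' \code{multi_hit}, \code{infinium_type}.
#'
#' @slot table data.frame as described above
#' @exportClass ProbeManifest
setClass("ProbeManifest", representation(table = "data.frame"))

setValidity("ProbeManifest", function(object) {
  tb <- object@table
  need <- c("probe_id", "chromosome", "position", "cpg_relation",
            "gene_structure", "gene_symbols", "on_hm27k", "on_hm450k",
            "on_epic", "snp_hit", "multi_hit", "infinium_type")
  miss <- setdiff(need, names(tb))
  if (length(miss)) return(sprintf("missing manifest column: %s", miss[1L]))
  if (anyDuplicated(tb$probe_id))
    return(sprintf("duplicate probe id: %s",
                   tb$probe_id[duplicated(tb$probe_id)][1L]))
  if (!all(tb$chromosome %in% .CHROMOSOMES))
    return(sprintf("unknown chromosome label: %s",
                   setdiff(tb$chromosome, .CHROMOSOMES)[1L]))
  if (!all(tb$cpg_relation %in% .CPG_RELATIONS))
    return(sprintf("unknown cpg_relation: %s",
                   setdiff(tb$cpg_relation, .CPG_RELATIONS)[1L]))
  if (!all(tb$gene_structure %in% .GENE_STRUCTURES))
    return(sprintf("unknown gene_structure: %s",
                   setdiff(tb$gene_structure, .GENE_STRUCTURES)[1L]))
  if (!all(tb$infinium_type %in% c("I", "II")))
    return("infinium_type must be 'I' or 'II'")
  TRUE
})

#' SampleAnnotation: per-sample labels for training and evaluation
#'
#' One row per sample: binary alteration labels (\code{IDH}, \code{TERTp},
#' \code{ATRX}, \code{chr1p19q}) in \{positive, negative, unknown\} where
#' positive means mutant / co-deleted, an expression-subtype label in
#' \{CL, PN, MES, unknown\}, optional per-subtype empirical p-values
#' (\code{pval_CL}, \code{pval_MES}, \code{pval_PN}) and the array platform.
#'
#' @slot table data.frame as described above
#' @exportClass SampleAnnotation
setClass("SampleAnnotation", representation(table = "data.frame"))

setValidity("SampleAnnotation", function(object) {
  tb <- object@table
  need <- c("sample_id", "IDH", "TERTp", "ATRX", "chr1p19q", "subtype",
            "platform")
  miss <- setdiff(need, names(tb))
  if (length(miss)) return(sprintf("missing annotation column: %s", miss[1L]))
  if (anyDuplicated(tb$sample_id)) return("duplicate sample id")
  lab <- c("positive", "negative", "unknown")
  for (a in .ALTERATIONS)
    if (!all(tb[[a]] %in% lab))
      return(sprintf("invalid %s label", a))
  if (!all(tb$subtype %in% c(.SUBTYPES, "unknown")))
    return("invalid subtype label")
  if (!all(tb$platform %in% .PLATFORMS))
    return("invalid platform label")
  for (p in c("pval_CL", "pval_MES", "pval_PN"))
    if (p %in% names(tb)) {
      v <- tb[[p]]
      if (any(!is.na(v) & (v < 0 | v > 1)))
        return(sprintf("%s outside [0,1]", p))
    }
  TRUE
})

#' BinaryModelSpec: a fitted penalized logistic model for one alteration
#'
#' Self-contained description of a binary predictor: the probe set, the
#' elastic-net mixing weight alpha and penalty strength lambda it was fitted
#' with, per-probe coefficients on the standardized M-value scale, the
#' training standardization parameters, the intercept and the decision
#' threshold. Serializes to versioned JSON via \code{\link{saveModel}}.
#'
#' @slot alteration character, one of IDH / TERTp / ATRX / chr1p19q (or a
#'   custom label)
#' @slot probes character vector of probe ids
#' @slot alpha numeric in \[0,1\]
#' @slot lambda numeric >= 0
#' @slot coefficients numeric, one per probe (standardized scale)
#' @slot intercept numeric scalar
#' @slot threshold decision probability threshold in (0,1)
#' @slot center,scale per-probe training standardization parameters
#' @slot seed integer training seed (NA if not applicable)
#' @exportClass BinaryModelSpec
setClass("BinaryModelSpec",
         representation(alteration = "character", probes = "character",
                        alpha = "numeric", lambda = "numeric",
                        coefficients = "numeric", intercept = "numeric",
                        threshold = "numeric", center = "numeric",
                        scale = "numeric", seed = "integer"))

setValidity("BinaryModelSpec", function(object) {
  p <- length(object@probes)
  if (length(object@coefficients) != p)
    return("one coefficient required per probe")
  if (length(object@center) != p || length(object@scale) != p)
    return("standardization parameters must match probe count")
  if (object@alpha < 0 || object@alpha > 1) return("alpha outside [0,1]")
  if (object@lambda < 0) return("lambda must be >= 0")
  if (object@threshold <= 0 || object@threshold >= 1)
    return("threshold outside (0,1)")
  if (anyDuplicated(object@probes)) return("duplicate probe in model")
  TRUE
})

#' SelectionRanking: stability-selection percentages and probe ranks
#'
#' @slot table data.frame with columns \code{probe_id}, \code{overall_pct},
#'   one \code{pct_alpha_*} column per mixing weight, and \code{rank}
#'   (1 = most frequently selected)
#' @slot metadata list: alphas, chosen lambda per alpha, folds, seed
#' @exportClass SelectionRanking
setClass("SelectionRanking",
         representation(table = "data.frame", metadata = "list"))

setValidity("SelectionRanking", function(object) {
  tb <- object@table
  if (!all(c("probe_id", "overall_pct", "rank") %in% names(tb)))
    return("ranking table needs probe_id, overall_pct and rank")
  if (any(tb$overall_pct < 0 | tb$overall_pct > 100))
    return("selection percentage outside [0,100]")
  if (!setequal(tb$rank, seq_len(nrow(tb))))
    return("rank must be a permutation of 1..n")
  TRUE
})

#' QCReport: record of every removal and masking the QC cascade performed
#'
#' @slot removedProbes named character: probe id -> primary reason code
#' @slot removedSamples named character: sample id -> primary reason code
#' @slot maskedCells named integer: masking reason -> cell count
#' @slot params list of the thresholds the cascade ran with
#' @exportClass QCReport
setClass("QCReport",
         representation(removedProbes = "character",
                        removedSamples = "character",
                        maskedCells = "integer", params = "list"))

setValidity("QCReport", function(object) {
  if (anyDuplicated(names(object@removedProbes)))
    return("probe removed with more than one primary reason")
  if (anyDuplicated(names(object@removedSamples)))
    return("sample removed with more than one primary reason")
  if (any(object@maskedCells < 0)) return("negative masked-cell count")
  TRUE
})

#' SubtypeModel: random-forest expression-subtype classifier descriptor
#'
#' @slot forest fitted randomForest object
#' @slot probes character vector of probe ids the forest expects
#' @slot classes subtype labels in training order
#' @slot seed integer training seed
#' @slot params list (ntree, mtry, input scale used)
#' @exportClass SubtypeModel
setClass("SubtypeModel",
         representation(forest = "ANY", probes = "character",
                        classes = "character", seed = "integer",
                        params = "list"))

#' ClusterMembership: consensus-clustering result
#'
#' @slot membership named integer vector, sample id -> cluster index in 1..k
#' @slot k integer cluster count
#' @slot consensus samples-by-samples co-clustering frequency matrix,
#'   symmetric with unit diagonal
#' @exportClass ClusterMembership
setClass("ClusterMembership",
         representation(membership = "integer", k = "integer",
                        consensus = "matrix"))

setValidity("ClusterMembership", function(object) {
  m <- object@membership
  if (any(m < 1L | m > object@k)) return("membership index outside 1..k")
  cm <- object@consensus
  if (nrow(cm) != length(m) || ncol(cm) != length(m))
    return("consensus matrix dimension mismatch")
  if (any(cm < -1e-12 | cm > 1 + 1e-12)) return("consensus outside [0,1]")
  if (max(abs(cm - t(cm))) > 1e-12) return("consensus matrix not symmetric")
  if (max(abs(diag(cm) - 1)) > 1e-12) return("consensus diagonal must be 1")
  TRUE
})
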