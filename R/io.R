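## Readers, writers and value transforms. Matrices are stored probes-in-rows,
## samples-in-columns; readers accept `transpose = TRUE` for files written the
## other way round. The missing-token set is explicit and case-sensitive.

.MISSING_TOKENS <- c("NA", "NaN", "")

#' Construct a BetaMatrix from a numeric matrix
#'
#' @param values numeric probes-by-samples matrix; rownames are probe ids,
#'   colnames sample ids. Non-missing entries must lie in \[0,1\].
#' @return a \linkS4class{BetaMatrix}
#' @examples
#' m <- matrix(runif(6), 3, 2,
#'             dimnames = list(paste0("cg", 1:3), c("s1", "s2")))
#' BetaMatrix(m)
#' @export
BetaMatrix <- function(values) new("BetaMatrix", values = values)

#' Construct an MValueMatrix from a numeric matrix
#' @param values numeric probes-by-samples matrix of finite M-values
#' @return an \linkS4class{MValueMatrix}
#' @export
MValueMatrix <- function(values) new("MValueMatrix", values = values)

#' Read a beta-value matrix from a delimited text file
#'
#' The first row holds sample ids, the first column probe ids. Cells must be
#' numeric in \[0,1\] or one of the missing tokens \code{"NA"}, \code{"NaN"},
#' \code{""}. Duplicated ids or out-of-range values abort with the offending
#' coordinate named.
#'
#' @param path file path
#' @param sep field delimiter, default tab
#' @param transpose set TRUE when the file stores samples in rows
#' @return a \linkS4class{BetaMatrix}
#' @export
readBetaMatrix <- function(path, sep = "\t", transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, sep = sep, header = TRUE, row.names = NULL,
                    check.names = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE)
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate row id: ", ids[duplicated(ids)][1L])
  cn <- colnames(raw)[-1L]
  if (anyDuplicated(cn))
    stop("duplicate column id: ", cn[duplicated(cn)][1L])
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  cells[cells %in% .MISSING_TOKENS] <- NA_character_
  vals <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells),
                                  dimnames = list(ids, cn)))
  bad <- is.na(vals) & !is.na(cells)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at row '%s', column '%s'",
                 ids[w[1L]], cn[w[2L]]))
  }
  if (transpose) vals <- t(vals)
  out <- is.na(vals) | (vals >= 0 & vals <= 1)
  if (!all(out)) {
    w <- which(!out, arr.ind = TRUE)[1L, ]
    stop(sprintf("beta value %g out of [0,1] at probe '%s', sample '%s'",
                 vals[w[1L], w[2L]], rownames(vals)[w[1L]],
                 colnames(vals)[w[2L]]))
  }
  BetaMatrix(vals)
}

#' Write a beta or M-value matrix as tab-separated text
#'
#' Full \code{\%.17g} precision so that a read/write round-trip preserves
#' values and axis order exactly.
#'
#' @param x a BetaMatrix or MValueMatrix
#' @param path destination file
#' @param sep field delimiter
#' @return invisibly, the path
#' @export
writeBetaMatrix <- function(x, path, sep = "\t") {
  v <- assayValues(x)
  txt <- matrix(sprintf("%.17g", v), nrow = nrow(v))
  txt[is.na(v)] <- "NA"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("probe_id", colnames(v)), collapse = sep), con)
  writeLines(paste(rownames(v), apply(txt, 1L, paste, collapse = sep),
                   sep = sep), con)
  invisible(path)
}

#' Beta to M-value transform
#'
#' M = log2((beta + epsilon) / (1 - beta + epsilon)). The offset keeps the
#' transform finite on clamped betas; the default 1e-6 barely moves mid-range
#' values. Missing entries stay missing.
#'
#' @param b a \linkS4class{BetaMatrix}
#' @param epsilon non-negative offset; must be > 0 if any beta is exactly
#'   0 or 1
#' @return an \linkS4class{MValueMatrix} on the same axes
#' @export
betaToM <- function(b, epsilon = 1e-6) {
  stopifnot(is(b, "BetaMatrix"), epsilon >= 0)
  v <- assayValues(b)
  if (epsilon == 0 && any(v %in% c(0, 1)))
    stop("beta value of exactly 0 or 1 requires epsilon > 0 (M would be infinite)")
  MValueMatrix(log2((v + epsilon) / (1 - v + epsilon)))
}

#' M-value to beta transform (epsilon = 0 convention)
#'
#' Inverse of \code{\link{betaToM}} at epsilon 0:
#' beta = 2^M / (2^M + 1).
#'
#' @param m an \linkS4class{MValueMatrix}
#' @return a \linkS4class{BetaMatrix} on the same axes
#' @export
mToBeta <- function(m) {
  stopifnot(is(m, "MValueMatrix"))
  v <- assayValues(m)
  BetaMatrix(1 / (1 + 2^(-v)))
}

## Alias tables for vocabulary normalization in the manifest reader. Keys are
## matched after case-folding and stripping of underscores/spaces.
.CPG_ALIASES <- setNames(
  c("CpG island", "CpG island", "N_shelf", "S_shelf", "N_shore", "S_shore",
    "unknown", "unknown", "unknown", "unknown"),
  c("island", "cpgisland", "nshelf", "sshelf", "nshore", "sshore",
    "opensea", "none", "", "unknown"))
.STRUCT_ALIASES <- setNames(
  c("TSS200", "TSS1500", "Body", "3'-UTR", "3'-UTR", "5'-UTR", "5'-UTR",
    "1st Exon", "1st Exon", "unknown", "unknown", "unknown"),
  c("tss200", "tss1500", "body", "3'utr", "3utr", "5'utr", "5utr",
    "1stexon", "firstexon", "", "unknown", "intergenic"))

.normVocab <- function(x, aliases, canon, what) {
  key <- gsub("[ _-]", "", tolower(x))
  canon_key <- gsub("[ _-]", "", tolower(canon))
  out <- canon[match(key, canon_key)]
  ali <- aliases[key]
  out[is.na(out) & !is.na(ali)] <- ali[is.na(out) & !is.na(ali)]
  if (anyNA(out))
    stop(sprintf("unknown %s label: %s", what, x[is.na(out)][1L]))
  out
}

.normChrom <- function(x) {
  x <- ifelse(grepl("^chr", x), x, paste0("chr", x))
  bad <- setdiff(x, .CHROMOSOMES)
  if (length(bad)) stop("unknown chromosome label: ", bad[1L])
  x
}

.parseLogical <- function(x, default) {
  if (is.null(x)) return(default)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Read a probe manifest from tab-separated text
#'
#' Required columns: \code{probe_id}, \code{chromosome}, \code{position},
#' \code{cpg_relation}, \code{gene_structure}. Optional: \code{gene_symbols}
#' (semicolon-separated, order meaningful), platform flags \code{on_hm27k}
#' (default FALSE), \code{on_hm450k} (default TRUE), \code{on_epic} (default
#' TRUE), \code{snp_hit} / \code{multi_hit} (default FALSE) and
#' \code{infinium_type} (default "II"). Category labels are normalized
#' through a fixed alias table (e.g. "Island" to "CpG island"); anything
#' unmappable is an error.
#'
#' @param path file path
#' @return a \linkS4class{ProbeManifest}
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tb <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  need <- c("probe_id", "chromosome", "position", "cpg_relation",
            "gene_structure")
  miss <- setdiff(need, names(tb))
  if (length(miss)) stop("missing required manifest column: ", miss[1L])
  genes <- if ("gene_symbols" %in% names(tb)) tb$gene_symbols else
    rep("", nrow(tb))
  genes[is.na(genes)] <- ""
  df <- data.frame(
    probe_id = tb$probe_id,
    chromosome = .normChrom(tb$chromosome),
    position = as.integer(tb$position),
    cpg_relation = .normVocab(tb$cpg_relation, .CPG_ALIASES, .CPG_RELATIONS,
                              "cpg_relation"),
    gene_structure = .normVocab(tb$gene_structure, .STRUCT_ALIASES,
                                .GENE_STRUCTURES, "gene_structure"),
    on_hm27k = .parseLogical(tb$on_hm27k, rep(FALSE, nrow(tb))),
    on_hm450k = .parseLogical(tb$on_hm450k, rep(TRUE, nrow(tb))),
    on_epic = .parseLogical(tb$on_epic, rep(TRUE, nrow(tb))),
    snp_hit = .parseLogical(tb$snp_hit, rep(FALSE, nrow(tb))),
    multi_hit = .parseLogical(tb$multi_hit, rep(FALSE, nrow(tb))),
    infinium_type = if (is.null(tb$infinium_type)) rep("II", nrow(tb)) else
      tb$infinium_type,
    stringsAsFactors = FALSE)
  df$gene_symbols <- lapply(strsplit(genes, ";", fixed = TRUE),
                            function(g) g[nzchar(g)])
  new("ProbeManifest", table = df)
}

#' Read a sample annotation table from tab-separated text
#'
#' Required column \code{sample_id}; optional alteration labels (IDH, TERTp,
#' ATRX, chr1p19q; default "unknown"), \code{subtype}, per-subtype empirical
#' p-values \code{pval_CL} / \code{pval_MES} / \code{pval_PN} and
#' \code{platform} (default HM450K).
#'
#' @param path file path
#' @return a \linkS4class{SampleAnnotation}
#' @export
readAnnotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tb <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(tb))
    stop("missing required annotation column: sample_id")
  n <- nrow(tb)
  df <- data.frame(sample_id = as.character(tb$sample_id),
                   stringsAsFactors = FALSE)
  for (a in .ALTERATIONS) {
    v <- if (is.null(tb[[a]])) rep("unknown", n) else as.character(tb[[a]])
    v[is.na(v)] <- "unknown"
    df[[a]] <- v
  }
  st <- if (is.null(tb$subtype)) rep("unknown", n) else
    as.character(tb$subtype)
  st[is.na(st)] <- "unknown"
  df$subtype <- st
  for (p in c("pval_CL", "pval_MES", "pval_PN"))
    if (!is.null(tb[[p]])) df[[p]] <- as.numeric(tb[[p]])
  df$platform <- if (is.null(tb$platform)) rep("HM450K", n) else
    as.character(tb$platform)
  new("SampleAnnotation", table = df)
}

#' Serialize a fitted model to versioned JSON
#'
#' \linkS4class{BinaryModelSpec} objects are stored completely (probes,
#' hyperparameters, coefficients, standardization, threshold, seed), so that
#' \code{\link{loadModel}} reproduces identical predictions without
#' retraining. \linkS4class{SubtypeModel} objects embed the serialized
#' forest.
#'
#' @param model a BinaryModelSpec or SubtypeModel
#' @param path destination file
#' @return invisibly, the path
#' @export
saveModel <- function(model, path) {
  ## numerics are stored as %.17g strings: exact IEEE-754 round trip, so a
  ## reloaded model reproduces bit-identical predictions
  num <- function(x) sprintf("%.17g", x)
  if (is(model, "BinaryModelSpec")) {
    validObject(model)
    payload <- list(
      schema_version = .MODEL_SCHEMA_VERSION, model_type = "binary",
      alteration = model@alteration, probes = model@probes,
      alpha = num(model@alpha), lambda = num(model@lambda),
      coefficients = num(model@coefficients),
      intercept = num(model@intercept),
      threshold = num(model@threshold), center = num(model@center),
      scale = num(model@scale), seed = model@seed)
  } else if (is(model, "SubtypeModel")) {
    payload <- list(
      schema_version = .MODEL_SCHEMA_VERSION, model_type = "subtype",
      probes = model@probes, classes = model@classes, seed = model@seed,
      params = model@params,
      forest_b64 = jsonlite::base64_enc(serialize(model@forest, NULL)))
  } else stop("unsupported model class: ", class(model)[1L])
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a model serialized by \code{\link{saveModel}}
#'
#' @param path JSON file written by \code{saveModel}
#' @return a BinaryModelSpec or SubtypeModel
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(js$schema_version) ||
      !identical(js$schema_version, .MODEL_SCHEMA_VERSION))
    stop("model schema version mismatch: expected ", .MODEL_SCHEMA_VERSION,
         ", found ", if (is.null(js$schema_version)) "none" else
           js$schema_version)
  if (identical(js$model_type, "binary")) {
    m <- new("BinaryModelSpec",
             alteration = js$alteration, probes = as.character(js$probes),
             alpha = as.numeric(js$alpha), lambda = as.numeric(js$lambda),
             coefficients = as.numeric(js$coefficients),
             intercept = as.numeric(js$intercept),
             threshold = as.numeric(js$threshold),
             center = as.numeric(js$center), scale = as.numeric(js$scale),
             seed = as.integer(js$seed))
    validObject(m)
    m
  } else if (identical(js$model_type, "subtype")) {
    new("SubtypeModel",
        forest = unserialize(jsonlite::base64_dec(js$forest_b64)),
        probes = as.character(js$probes), classes = as.character(js$classes),
        seed = as.integer(js$seed), params = as.list(js$params))
  } else stop("unknown model_type in ", path)
}
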