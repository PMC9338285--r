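## Small fixture builders shared across test files. Everything is generated
## in code; no data files.

betaFixture <- function(values, probes = NULL, samples = NULL) {
  if (is.null(probes)) probes <- sprintf("cg%03d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(values)))
  dimnames(values) <- list(probes, samples)
  BetaMatrix(values)
}

manifestFixture <- function(probe_id,
                            chromosome = rep("chr1", length(probe_id)),
                            cpg_relation = rep("CpG island",
                                               length(probe_id)),
                            gene_structure = rep("Body", length(probe_id)),
                            gene_symbols = NULL,
                            on_hm27k = FALSE, on_hm450k = TRUE,
                            on_epic = TRUE, snp_hit = FALSE,
                            multi_hit = FALSE, infinium_type = "II") {
  n <- length(probe_id)
  df <- data.frame(probe_id = probe_id, chromosome = chromosome,
                   position = seq_len(n) * 1000L,
                   cpg_relation = cpg_relation,
                   gene_structure = gene_structure,
                   on_hm27k = rep_len(on_hm27k, n),
                   on_hm450k = rep_len(on_hm450k, n),
                   on_epic = rep_len(on_epic, n),
                   snp_hit = rep_len(snp_hit, n),
                   multi_hit = rep_len(multi_hit, n),
                   infinium_type = rep_len(infinium_type, n),
                   stringsAsFactors = FALSE)
  df$gene_symbols <- if (is.null(gene_symbols))
    replicate(n, character(0), simplify = FALSE) else gene_symbols
  new("ProbeManifest", table = df)
}

## hand-built binary model with trivial standardization, for prediction
## arithmetic tests
modelFixture <- function(probes, coefficients, intercept = 0,
                         threshold = 0.5, alpha = 0.5, lambda = 1) {
  new("BinaryModelSpec", alteration = "IDH", probes = probes,
      alpha = alpha, lambda = lambda, coefficients = coefficients,
      intercept = intercept, threshold = threshold,
      center = rep(0, length(probes)), scale = rep(1, length(probes)),
      seed = NA_integer_)
}

## Path of the installed CLI script and a runner for it.
cliScript <- function() system.file("cli", "unid.R", package = "uniD")

runCLI <- function(...) {
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- system2(rscript, c(cliScript(), ...), stdout = TRUE,
                 stderr = TRUE)
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L)
    stop("CLI failed: ", paste(out, collapse = "\n"))
  invisible(out)
}
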