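## Expression-subtype (CL/PN/MES) branch: reference probability construction
## from per-subtype empirical p-values, CpG-island/gene/correlation probe
## filtering, entropy-metric rank-sum probe ranking, a pluggable multi-learner
## CV harness, and the random-forest final model.

#' Per-sample subtype probabilities from empirical p-values
#'
#' Prob(subtype s) = (1 - p_s) / sum_t (1 - p_t). When every p-value equals
#' 1 the denominator vanishes and the uniform distribution (1/3 each) is
#' returned: no evidence favours any subtype.
#'
#' @param pvals numeric vector of 3 p-values (order CL, MES, PN; names kept
#'   if given) or a samples-by-3 matrix/data.frame with columns CL, MES, PN
#' @return probabilities of the same shape, rows summing to 1
#' @export
subtypeProbability <- function(pvals) {
  one <- function(p) {
    if (any(p < 0 | p > 1)) stop("empirical p-value outside [0,1]")
    w <- 1 - p
    s <- sum(w)
    if (s == 0) rep(1 / 3, 3L) else w / s
  }
  if (is.matrix(pvals) || is.data.frame(pvals)) {
    m <- as.matrix(pvals)
    stopifnot(ncol(m) == 3L)
    out <- t(apply(m, 1L, one))
    colnames(out) <- if (is.null(colnames(m))) .SUBTYPES else colnames(m)
    out
  } else {
    stopifnot(length(pvals) == 3L)
    out <- one(as.numeric(pvals))
    names(out) <- if (is.null(names(pvals))) .SUBTYPES else names(pvals)
    out
  }
}

#' Sum of squared probability deviations between two subtype distributions
#'
#' sum over subtypes of (real - predicted)^2; zero iff identical, at most 2,
#' symmetric in its arguments. Matrices are compared row-wise.
#'
#' @param real,predicted probability vectors of equal length, or matrices of
#'   equal shape
#' @return non-negative scalar, or vector of per-row deviations
#' @export
probabilityDeviation <- function(real, predicted) {
  r <- if (is.null(dim(real))) rbind(real) else as.matrix(real)
  q <- if (is.null(dim(predicted))) rbind(predicted) else
    as.matrix(predicted)
  if (!all(dim(r) == dim(q))) stop("probability shapes differ")
  unname(rowSums((r - q)^2))
}

#' Probe filter for the expression-subtype branch
#'
#' Retains probes that (in order of precedence of the recorded reason) have
#' missing values in fewer than \code{maxMissingSamples} samples, lie on a
#' CpG island, map to at least one gene, have that (first-listed) gene
#' present in the expression matrix, and show absolute Spearman correlation
#' >= \code{minAbsRho} between methylation and the gene's expression.
#' Undefined correlations (constant vectors) drop the probe with reason
#' "undefined-correlation" rather than erroring.
#'
#' @param b a \linkS4class{BetaMatrix}
#' @param manifest a \linkS4class{ProbeManifest} covering the probes
#' @param expr genes-by-samples expression matrix sharing sample ids with b
#' @param minAbsRho correlation threshold (default 0.1; inclusive)
#' @param maxMissingSamples missingness cutoff (default 5; a probe missing
#'   in >= this many samples is dropped)
#' @return list: retained (probe ids, input order), reasons (data.frame
#'   probe_id, reason for every dropped probe), rho (named vector for
#'   retained probes)
#' @export
geneBranchProbeFilter <- function(b, manifest, expr, minAbsRho = 0.1,
                                  maxMissingSamples = 5L) {
  stopifnot(is(b, "BetaMatrix"), is(manifest, "ProbeManifest"))
  v <- assayValues(b)
  tb <- annotationTable(manifest)
  idx <- match(rownames(v), tb$probe_id)
  if (anyNA(idx)) stop("probe absent from manifest: ",
                       rownames(v)[is.na(idx)][1L])
  shared <- intersect(colnames(v), colnames(expr))
  if (length(shared) < 3L) stop("need >= 3 samples shared with expression")
  reason <- rep(NA_character_, nrow(v))
  rho <- rep(NA_real_, nrow(v))
  firstGene <- vapply(tb$gene_symbols[idx], function(g)
    if (length(g)) g[1L] else NA_character_, character(1))
  nMiss <- rowSums(is.na(v))
  reason[is.na(reason) & nMiss >= maxMissingSamples] <- "high-missing"
  reason[is.na(reason) & tb$cpg_relation[idx] != "CpG island"] <-
    "not-cpg-island"
  reason[is.na(reason) & is.na(firstGene)] <- "no-gene"
  reason[is.na(reason) & !is.na(firstGene) &
           !(firstGene %in% rownames(expr))] <- "gene-not-in-expression"
  for (i in which(is.na(reason))) {
    r <- suppressWarnings(cor(v[i, shared], expr[firstGene[i], shared],
                              method = "spearman",
                              use = "pairwise.complete.obs"))
    if (is.na(r)) reason[i] <- "undefined-correlation"
    else if (abs(r) < minAbsRho) reason[i] <- "low-correlation"
    else rho[i] <- r
  }
  keep <- is.na(reason)
  list(retained = rownames(v)[keep],
       reasons = data.frame(probe_id = rownames(v)[!keep],
                            reason = reason[!keep],
                            stringsAsFactors = FALSE),
       rho = setNames(rho[keep], rownames(v)[keep]))
}

.entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

.equalFreqBins <- function(x, nBins) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = nBins + 1),
                        names = FALSE))
  if (length(br) < 2L) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

#' Entropy-metric probe ranking (information gain / gain ratio /
#' symmetrical uncertainty)
#'
#' Probe values are discretized by equal-frequency binning; per probe,
#' IG = H(Y) - H(Y|X) in bits, GR = IG / H(X) and SU = 2 IG / (H(X) + H(Y))
#' (both defined as 0 when their denominator vanishes, i.e. for constant
#' probes). Probes get a rank per metric (1 = highest, ties take the
#' minimum rank), the three ranks are summed, and the final order is by
#' ascending rank sum with ties broken by probe id.
#'
#' @param X complete probes-by-samples matrix (beta or M scale; the metrics
#'   are invariant to monotone transforms under equal-frequency binning)
#' @param y class label per sample (>= 2 classes)
#' @param nBins equal-frequency bin count (default 10)
#' @return data.frame: probe_id, info_gain, gain_ratio, sym_uncertainty,
#'   rank_ig, rank_gr, rank_su, rank_sum, rank (1 = best)
#' @export
entropyRank <- function(X, y, nBins = 10L) {
  X <- .asMatrixInput(X)
  if (anyNA(X)) stop("X must be complete")
  y <- as.character(y)
  if (length(unique(y)) < 2L) stop("y needs at least two classes")
  hy <- .entropy(table(y))
  n <- length(y)
  met <- t(apply(X, 1L, function(x) {
    bins <- .equalFreqBins(x, nBins)
    hx <- .entropy(table(bins))
    hyx <- 0
    for (bn in unique(bins)) {
      sel <- bins == bn
      hyx <- hyx + sum(sel) / n * .entropy(table(y[sel]))
    }
    ig <- max(0, hy - hyx)
    c(ig = ig,
      gr = if (hx > 0) ig / hx else 0,
      su = if (hx + hy > 0) 2 * ig / (hx + hy) else 0)
  }))
  rk <- function(v) rank(-v, ties.method = "min")
  tb <- data.frame(probe_id = rownames(X), info_gain = met[, "ig"],
                   gain_ratio = met[, "gr"], sym_uncertainty = met[, "su"],
                   rank_ig = rk(met[, "ig"]), rank_gr = rk(met[, "gr"]),
                   rank_su = rk(met[, "su"]), stringsAsFactors = FALSE,
                   row.names = NULL)
  tb$rank_sum <- tb$rank_ig + tb$rank_gr + tb$rank_su
  ord <- order(tb$rank_sum, tb$probe_id)
  tb$rank <- integer(nrow(tb))
  tb$rank[ord] <- seq_len(nrow(tb))
  tb[order(tb$rank), , drop = FALSE]
}

#' Nested top-quantile probe subsets from an entropy ranking
#'
#' Subset sizes are ceiling(q * N) for each requested quantile; subsets are
#' nested under the ranking's deterministic order.
#'
#' @param ranking data.frame from \code{\link{entropyRank}}
#' @param quantiles fractions in (0,1\], default 100\% down to 10\%
#' @return named list of probe-id vectors
#' @export
quantileSubsets <- function(ranking, quantiles = seq(1, 0.1, by = -0.1)) {
  stopifnot(nrow(ranking) >= 1L, all(quantiles > 0), all(quantiles <= 1))
  ordered <- ranking$probe_id[order(ranking$rank)]
  setNames(lapply(quantiles, function(q)
    ordered[seq_len(ceiling(q * length(ordered)))]),
    paste0("top", round(100 * quantiles), "pct"))
}

#' Core subtype learner set
#'
#' Each learner is a list with \code{fit(X, y)} and
#' \code{predictProb(model, X)} (X samples-by-features; predictProb returns
#' a samples-by-classes probability matrix with columns in
#' \code{sort(unique(y))} order). Ships random forest, penalized multinomial
#' logistic, k-nearest-neighbour, naive Bayes and linear discriminant;
#' any learner honouring this interface can be added to the harness.
#'
#' @param ntree random-forest tree count for the harness (default 200)
#' @param knnK neighbour count for the k-NN learner
#' @return named list of learners
#' @export
subtypeLearners <- function(ntree = 200L, knnK = 5L) {
  list(
    random_forest = list(
      fit = function(X, y) randomForest::randomForest(
        x = X, y = factor(y, levels = sort(unique(y))), ntree = ntree),
      predictProb = function(model, X)
        unclass(predict(model, newdata = X, type = "prob"))),
    multinomial_enet = list(
      fit = function(X, y) {
        lev <- sort(unique(y))
        fit <- suppressWarnings(glmnet::glmnet(
          X, factor(y, levels = lev), family = "multinomial", alpha = 0,
          lambda = c(1, 0.1, 0.01)))
        list(fit = fit, lev = lev)
      },
      predictProb = function(model, X) {
        p <- predict(model$fit, newx = X, s = 0.01, type = "response")
        matrix(p[, , 1L], nrow = nrow(X), dimnames = list(NULL, model$lev))
      }),
    knn = list(
      fit = function(X, y) list(X = X, y = y, lev = sort(unique(y))),
      predictProb = function(model, X) {
        k <- min(knnK, nrow(model$X))
        out <- matrix(0, nrow(X), length(model$lev),
                      dimnames = list(NULL, model$lev))
        for (i in seq_len(nrow(X))) {
          d <- sqrt(colSums((t(model$X) - X[i, ])^2))
          nb <- order(d, seq_along(d))[seq_len(k)]
          tab <- table(factor(model$y[nb], levels = model$lev))
          out[i, ] <- tab / sum(tab)
        }
        out
      }),
    naive_bayes = list(
      fit = function(X, y) e1071::naiveBayes(
        x = as.data.frame(X), y = factor(y, levels = sort(unique(y)))),
      predictProb = function(model, X)
        predict(model, newdata = as.data.frame(X), type = "raw")),
    lda = list(
      fit = function(X, y) suppressWarnings(MASS::lda(X, grouping = factor(
        y, levels = sort(unique(y))))),
      predictProb = function(model, X) predict(model, X)$posterior))
}

#' Multi-learner, multi-subset cross-validation harness
#'
#' For every (learner, probe subset, repeat) triple: seeded stratified
#' k-fold CV, with each sample's class probabilities predicted from the fold
#' that holds it out. Records the misclassification rate (argmax vs true
#' label) and the mean per-sample sum of squared probability deviations
#' against the reference probabilities. A failing learner yields NA metrics
#' for that cell and the run continues. Results are independent of learner
#' ordering.
#'
#' @param X complete probes-by-samples matrix
#' @param yLabels true subtype label per sample
#' @param yProbs samples-by-classes reference probability matrix (columns
#'   in sorted class order)
#' @param learners named list as from \code{\link{subtypeLearners}}
#' @param subsets named list of probe-id vectors
#' @param repeats CV repetitions (default 100)
#' @param folds fold count (default 5)
#' @param seed integer master seed
#' @return data.frame: learner, subset, repeat_id, misclassification,
#'   deviation
#' @export
evaluateLearners <- function(X, yLabels, yProbs, learners, subsets,
                             repeats = 100L, folds = 5L, seed = 1L) {
  X <- .asMatrixInput(X)
  yLabels <- as.character(yLabels)
  lev <- sort(unique(yLabels))
  yProbs <- as.matrix(yProbs)
  out <- expand.grid(learner = names(learners), subset = names(subsets),
                     repeat_id = seq_len(repeats),
                     stringsAsFactors = FALSE)
  out$misclassification <- NA_real_
  out$deviation <- NA_real_
  for (r in seq_len(repeats)) {
    foldID <- makeCVFolds(yLabels, folds, .subSeed(seed, r))
    for (s in names(subsets)) {
      Xs <- t(X[subsets[[s]], , drop = FALSE])
      for (l in names(learners)) {
        prob <- matrix(NA_real_, nrow(Xs), length(lev),
                       dimnames = list(NULL, lev))
        ok <- TRUE
        for (f in seq_len(folds)) {
          tr <- foldID != f
          res <- tryCatch({
            mod <- learners[[l]]$fit(Xs[tr, , drop = FALSE], yLabels[tr])
            p <- learners[[l]]$predictProb(mod, Xs[!tr, , drop = FALSE])
            prob[!tr, ] <- as.matrix(p)[, lev, drop = FALSE]
            TRUE
          }, error = function(e) FALSE)
          if (!isTRUE(res)) { ok <- FALSE; break }
        }
        if (ok) {
          call <- lev[max.col(prob, ties.method = "first")]
          row <- out$learner == l & out$subset == s & out$repeat_id == r
          out$misclassification[row] <- mean(call != yLabels)
          out$deviation[row] <-
            mean(probabilityDeviation(yProbs[, lev, drop = FALSE], prob))
        }
      }
    }
  }
  out
}

#' Fit the final random-forest subtype model
#'
#' 500 trees, sqrt(p) features per split, deterministic under the seed.
#' Trained on the union of training and development samples in the released
#' configuration (all retained ranked probes).
#'
#' @param X complete probes-by-samples matrix
#' @param y subtype label per sample (all three classes must be present)
#' @param probes probe ids to use (default: all rows of X)
#' @param seed integer seed
#' @param ntree tree count (default 500)
#' @return a \linkS4class{SubtypeModel}
#' @export
trainSubtypeFinal <- function(X, y, probes = NULL, seed = 1L,
                              ntree = 500L) {
  X <- .asMatrixInput(X)
  if (is.null(probes)) probes <- rownames(X)
  y <- as.character(y)
  lev <- sort(unique(y))
  if (length(lev) < 3L)
    stop("all three subtype classes must be represented, found: ",
         paste(lev, collapse = ", "))
  set.seed(seed)
  forest <- randomForest::randomForest(
    x = t(X[probes, , drop = FALSE]), y = factor(y, levels = lev),
    ntree = ntree, mtry = floor(sqrt(length(probes))))
  new("SubtypeModel", forest = forest, probes = probes, classes = lev,
      seed = as.integer(seed),
      params = list(ntree = ntree, mtry = floor(sqrt(length(probes)))))
}

#' Predict expression subtype with class probabilities
#'
#' The call is the argmax class (first class in training order on exact
#' ties); probabilities are the forest vote fractions and sum to 1.
#'
#' @param model a \linkS4class{SubtypeModel}
#' @param X probes-by-samples matrix containing all model probes
#' @return data.frame: sample_id, one probability column per class, call
#' @export
predictSubtype <- function(model, X) {
  stopifnot(is(model, "SubtypeModel"))
  X <- .asMatrixInput(X)
  miss <- setdiff(model@probes, rownames(X))
  if (length(miss))
    stop("model probes missing from matrix: ", paste(miss, collapse = ", "))
  prob <- unclass(predict(model@forest,
                          newdata = t(X[model@probes, , drop = FALSE]),
                          type = "prob"))
  prob <- prob[, model@classes, drop = FALSE]
  out <- data.frame(sample_id = colnames(X), stringsAsFactors = FALSE)
  for (cl in model@classes) out[[paste0(cl, "_prob")]] <- unname(prob[, cl])
  out$call <- model@classes[max.col(prob, ties.method = "first")]
  out
}
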