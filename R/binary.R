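## Binary-alteration classifiers: stratified 60/20/20 split, per-probe-set
## (alpha, lambda) grid refit scored by CV accuracy on the training set,
## final-candidate selection on the development set, and prediction with the
## logistic link.

#' Published final-model configuration per alteration
#'
#' The pinned probe-set size and elastic-net hyperparameters of the released
#' binary predictors: 100 / 1000 / 500 / 100 probes for IDH, TERTp, ATRX
#' and chr1p19q, alpha 0 throughout, lambda 1 for the three mutations and
#' 0.1 for the co-deletion.
#'
#' @param alteration one of "IDH", "TERTp", "ATRX", "chr1p19q"
#' @return list: nProbes, alpha, lambda
#' @export
paperModeConfig <- function(alteration) {
  switch(match.arg(alteration, .ALTERATIONS),
         IDH = list(nProbes = 100L, alpha = 0, lambda = 1),
         TERTp = list(nProbes = 1000L, alpha = 0, lambda = 1),
         ATRX = list(nProbes = 500L, alpha = 0, lambda = 1),
         chr1p19q = list(nProbes = 100L, alpha = 0, lambda = 0.1))
}

#' Stratified training/development/test split
#'
#' Within each class, samples are shuffled and apportioned to the three sets
#' so counts match the fractions to the nearest integer (cumulative-rounding
#' rule). Reproducible under the seed.
#'
#' @param samples sample ids
#' @param labels stratification label per sample; every class needs >= 3
#'   members
#' @param fractions length-3 fractions (training, development, test) summing
#'   to 1
#' @param seed integer seed
#' @return data.frame: sample_id, set in \{training, development, test\}
#' @export
stratifiedSplit <- function(samples, labels, fractions = c(0.6, 0.2, 0.2),
                            seed = 1L) {
  stopifnot(length(samples) == length(labels),
            abs(sum(fractions) - 1) < 1e-9, length(fractions) == 3L)
  if (min(table(labels)) < 3L)
    stop("every class needs at least 3 members to fill the three sets")
  sets <- c("training", "development", "test")
  assign <- character(length(samples))
  set.seed(seed)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    counts <- diff(c(0L, round(cumsum(fractions) * length(idx))))
    assign[idx] <- rep(sets, counts)
  }
  data.frame(sample_id = samples, set = assign, stringsAsFactors = FALSE)
}

#' Refit grid search over (alpha, lambda) for one probe set
#'
#' Evaluates every combination of the alpha grid (default 0.1 to 1, step
#' 0.1) and lambda grid (default 0 to 5, step 0.05; 1010 combinations) by
#' stratified CV accuracy on the training samples, restricted to the given
#' probe set. Ties go to the larger lambda, then the larger alpha.
#'
#' @param X probes-by-samples training matrix or MValueMatrix
#' @param y binary response
#' @param probeSet non-empty subset of rownames(X)
#' @param alphaGrid,lambdaGrid search grids
#' @param folds CV fold count
#' @param seed fold seed
#' @return list: alpha, lambda, cvAccuracy (alpha x lambda matrix), foldID
#' @export
gridRefit <- function(X, y, probeSet, alphaGrid = seq(0.1, 1, by = 0.1),
                      lambdaGrid = seq(0, 5, by = 0.05), folds = 5L,
                      seed = 1L) {
  X <- .asMatrixInput(X)
  if (length(probeSet) == 0L) stop("empty probe set")
  miss <- setdiff(probeSet, rownames(X))
  if (length(miss)) stop("probe set not in matrix: ", miss[1L])
  Xs <- X[probeSet, , drop = FALSE]
  y01 <- .binaryResponse(y)
  foldID <- makeCVFolds(y01, folds, seed)
  acc <- matrix(NA_real_, length(alphaGrid), length(lambdaGrid),
                dimnames = list(paste0("alpha_", alphaGrid),
                                paste0("lambda_", lambdaGrid)))
  for (a in seq_along(alphaGrid))
    acc[a, ] <- colMeans(.cvAccuracyGrid(Xs, y01, alphaGrid[a], lambdaGrid,
                                         foldID))
  best <- which(acc == max(acc), arr.ind = TRUE)
  ## ties -> larger lambda, then larger alpha
  best <- best[order(-lambdaGrid[best[, 2L]], -alphaGrid[best[, 1L]]), ,
               drop = FALSE]
  list(alpha = alphaGrid[best[1L, 1L]], lambda = lambdaGrid[best[1L, 2L]],
       cvAccuracy = acc, foldID = foldID)
}

#' Fit the final penalized logistic model for one alteration
#'
#' In "auto" mode the supplied probes/alpha/lambda are used as given; in
#' "paper" mode they are pinned to the published configuration for the
#' alteration (the probe set is truncated to the published size, which must
#' be available).
#'
#' @param X probes-by-samples matrix or MValueMatrix (training samples,
#'   ranked-probe rows available)
#' @param y binary response
#' @param probes ordered probe ids (best first)
#' @param alpha,lambda elastic-net hyperparameters (auto mode)
#' @param alteration label stored in the model
#' @param mode "auto" or "paper"
#' @param threshold decision probability threshold
#' @param seed integer seed recorded in the model
#' @return a \linkS4class{BinaryModelSpec}
#' @export
fitFinal <- function(X, y, probes, alpha = 0, lambda = 1,
                     alteration = "IDH", mode = c("auto", "paper"),
                     threshold = 0.5, seed = NA_integer_) {
  mode <- match.arg(mode)
  if (mode == "paper") {
    cfg <- paperModeConfig(alteration)
    if (length(probes) < cfg$nProbes)
      stop("paper mode needs ", cfg$nProbes, " ranked probes, got ",
           length(probes))
    probes <- probes[seq_len(cfg$nProbes)]
    alpha <- cfg$alpha
    lambda <- cfg$lambda
  }
  fit <- fitElasticNetLogistic(.asMatrixInput(X)[probes, , drop = FALSE],
                               y, alpha, lambda)
  new("BinaryModelSpec", alteration = alteration, probes = probes,
      alpha = alpha, lambda = lambda, coefficients = unname(fit$coefficients),
      intercept = fit$intercept, threshold = threshold,
      center = unname(fit$center), scale = unname(fit$scale),
      seed = as.integer(seed))
}

#' Choose the final model among probe-set-size candidates
#'
#' Each candidate (probes + tuned alpha/lambda) is refit on the full
#' training set and scored by accuracy on the development set; the most
#' accurate wins, ties going to the candidate with fewer probes.
#'
#' @param candidates list of lists with elements probes, alpha, lambda
#' @param Xtrain,ytrain training matrix and response
#' @param Xdev,ydev development matrix and response
#' @param alteration,threshold,seed passed to \code{\link{fitFinal}}
#' @return list: model (\linkS4class{BinaryModelSpec}), devAccuracy (per
#'   candidate), chosen (index)
#' @export
selectFinalModel <- function(candidates, Xtrain, ytrain, Xdev, ydev,
                             alteration = "IDH", threshold = 0.5,
                             seed = NA_integer_) {
  stopifnot(length(candidates) >= 1L)
  models <- lapply(candidates, function(cand)
    fitFinal(Xtrain, ytrain, cand$probes, cand$alpha, cand$lambda,
             alteration = alteration, threshold = threshold, seed = seed))
  devAcc <- vapply(models, function(m) {
    pred <- predictBinary(m, Xdev)
    mean(pred$call == .binaryResponse(ydev))
  }, numeric(1))
  sizes <- vapply(candidates, function(cand) length(cand$probes), integer(1))
  best <- which(devAcc == max(devAcc))
  chosen <- best[which.min(sizes[best])]
  list(model = models[[chosen]], devAccuracy = devAcc, chosen = chosen)
}

#' Predict alteration status from a fitted binary model
#'
#' probability = logistic(intercept + sum coef * standardized value); the
#' call is positive (1) iff probability >= the model threshold.
#'
#' @param model a \linkS4class{BinaryModelSpec}
#' @param X probes-by-samples matrix, BetaMatrix (transformed to M-values
#'   first is the caller's responsibility) or MValueMatrix containing all
#'   model probes
#' @return data.frame: sample_id, probability, call (0/1)
#' @export
predictBinary <- function(model, X) {
  stopifnot(is(model, "BinaryModelSpec"))
  X <- .asMatrixInput(X)
  miss <- setdiff(model@probes, rownames(X))
  if (length(miss))
    stop("model probes missing from matrix: ", paste(miss, collapse = ", "))
  Xs <- t(X[model@probes, , drop = FALSE])
  Xs <- sweep(sweep(Xs, 2L, model@center), 2L, model@scale, "/")
  eta <- drop(Xs %*% model@coefficients) + model@intercept
  prob <- .logistic(eta)
  data.frame(sample_id = colnames(X), probability = unname(prob),
             call = as.integer(prob >= model@threshold),
             stringsAsFactors = FALSE)
}

#' Accuracy, AUC and confusion counts for binary predictions
#'
#' AUC is the Mann-Whitney probability (ties get 0.5 credit); it is NA when
#' only one class is present in the truth, while accuracy is still computed.
#'
#' @param predictions data.frame from \code{\link{predictBinary}} (columns
#'   sample_id, probability, call)
#' @param truth named binary truth vector (names = sample ids) or unnamed
#'   vector aligned with predictions
#' @return list: accuracy, auc, confusion (2x2 table counts: tp, fp, fn, tn)
#' @export
evaluateBinary <- function(predictions, truth) {
  if (!is.null(names(truth))) {
    miss <- setdiff(predictions$sample_id, names(truth))
    if (length(miss)) stop("truth missing for sample: ", miss[1L])
    truth <- truth[predictions$sample_id]
  } else if (length(truth) != nrow(predictions))
    stop("truth length does not match predictions")
  ## one-class truth is allowed here: accuracy is still defined, AUC is NA
  y <- if (is.numeric(truth) || is.logical(truth)) as.integer(truth) else
    as.integer(as.character(truth) == sort(unique(as.character(truth)))[
      min(2L, length(unique(truth)))])
  if (!all(y %in% c(0L, 1L))) stop("truth must be binary")
  call <- predictions$call
  list(accuracy = mean(call == y),
       auc = rocAUC(predictions$probability, y == 1L),
       confusion = c(tp = sum(call == 1L & y == 1L),
                     fp = sum(call == 1L & y == 0L),
                     fn = sum(call == 0L & y == 1L),
                     tn = sum(call == 0L & y == 0L)))
}

#' End-to-end binary-alteration training pipeline
#'
#' Runs the whole supervised path on a complete M-value matrix: stratified
#' 60/20/20 split, stability selection on the training set, per-size
#' (alpha, lambda) grid refit, development-set candidate selection, final
#' fit, and test-set evaluation. Fully deterministic under the seed.
#'
#' @param X complete probes-by-samples M-value matrix (or MValueMatrix)
#' @param y binary response per sample
#' @param sizes candidate probe-set sizes (default 100)
#' @param alteration model label
#' @param seed integer master seed
#' @param nLambda stability-selection lambda grid size
#' @param alphaGrid,lambdaGrid refit grids
#' @param alphas stability-selection mixing weights
#' @param folds CV fold count
#' @return list: split, ranking, candidates, selection (from
#'   \code{\link{selectFinalModel}}), model, testEval
#' @export
trainBinaryPipeline <- function(X, y, sizes = c(100L),
                                alteration = "IDH", seed = 1L,
                                nLambda = 200L,
                                alphas = seq(0.1, 1, by = 0.1),
                                alphaGrid = seq(0.1, 1, by = 0.1),
                                lambdaGrid = seq(0, 5, by = 0.05),
                                folds = 5L) {
  X <- .asMatrixInput(X)
  ids <- colnames(X)
  split <- stratifiedSplit(ids, y, seed = seed)
  setOf <- setNames(split$set, split$sample_id)
  tr <- ids[setOf[ids] == "training"]
  dev <- ids[setOf[ids] == "development"]
  te <- ids[setOf[ids] == "test"]
  ytr <- y[match(tr, ids)]; ydev <- y[match(dev, ids)]
  yte <- y[match(te, ids)]
  ranking <- selectionPercentage(X[, tr, drop = FALSE], ytr, alphas = alphas,
                                 nLambda = nLambda, folds = folds,
                                 seed = .subSeed(seed, 101L))
  probeSets <- topProbeSets(ranking, sizes)
  candidates <- lapply(probeSets, function(ps) {
    g <- gridRefit(X[, tr, drop = FALSE], ytr, ps, alphaGrid, lambdaGrid,
                   folds, seed = .subSeed(seed, 202L))
    list(probes = ps, alpha = g$alpha, lambda = g$lambda)
  })
  sel <- selectFinalModel(candidates, X[, tr, drop = FALSE], ytr,
                          X[, dev, drop = FALSE], ydev,
                          alteration = alteration, seed = seed)
  pred <- predictBinary(sel$model, X[, te, drop = FALSE])
  list(split = split, ranking = ranking, candidates = candidates,
       selection = sel, model = sel$model,
       testEval = evaluateBinary(pred, setNames(yte, te)))
}
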