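## Elastic-net stability selection. For each mixing weight alpha a random
## log-uniform lambda grid is scored by stratified 5-fold CV accuracy, the
## winning lambda is fixed, the model is refit on each fold's training
## portion, and a probe's per-alpha selection percentage is the fraction of
## folds in which its coefficient is non-zero. The overall percentage is the
## mean over alphas; probes are ranked by it, descending.

.COEF_TOL <- 1e-10   # non-zero test absorbs coordinate-descent noise
.LAMBDA_FLOOR <- 1e-8  # ridge guard standing in for lambda = 0

## Standardize a samples-by-features matrix; zero-variance features get
## scale 1 so they pass through as exact zeros.
.standardize <- function(Xs) {
  ctr <- colMeans(Xs)
  scl <- apply(Xs, 2L, sd)
  scl[scl == 0 | is.na(scl)] <- 1
  list(X = sweep(sweep(Xs, 2L, ctr), 2L, scl, "/"), center = ctr,
       scale = scl)
}

.binaryResponse <- function(y) {
  if (is.logical(y)) return(as.integer(y))
  if (is.factor(y)) y <- as.character(y)
  u <- sort(unique(y))
  if (length(u) != 2L) stop("response must have exactly two classes, found ",
                            length(u))
  as.integer(y == u[2L])
}

## Penalized logistic path evaluated at the requested lambdas exactly.
## Xs must already be standardized (samples x features).
.glmnetPath <- function(Xs, y01, alpha, lambdas) {
  lam_eff <- pmax(lambdas, .LAMBDA_FLOOR)
  seq_lam <- sort(unique(lam_eff), decreasing = TRUE)
  pad <- ncol(Xs) == 1L  # glmnet needs >= 2 columns
  if (pad) Xs <- cbind(Xs, `..pad` = 0)
  fit <- suppressWarnings(
    glmnet::glmnet(Xs, y01, family = "binomial", alpha = alpha,
                   lambda = seq_lam, standardize = FALSE,
                   thresh = 1e-10, maxit = 1e6))
  co <- tryCatch(
    as.matrix(stats::coef(fit, s = lam_eff, exact = TRUE, x = Xs,
                          y = y01)),
    error = function(e)
      ## the unpenalized end of the path can diverge on separable data;
      ## fall back to the smallest lambda the solver converged for
      as.matrix(stats::coef(fit, s = pmax(lam_eff, min(fit$lambda)),
                            exact = FALSE)))
  colnames(co) <- NULL
  if (pad) co <- co[-nrow(co), , drop = FALSE]
  list(intercept = co[1L, ], beta = co[-1L, , drop = FALSE])
}

#' Largest useful penalty for an elastic-net logistic fit
#'
#' The smallest lambda at which every coefficient is zero, computed from the
#' score of the null model on standardized features. For alpha below 0.001
#' the value at alpha = 0.001 is used (the ridge path has no finite zeroing
#' penalty).
#'
#' @param X probes-by-samples matrix (or MValueMatrix)
#' @param y binary response
#' @param alpha elastic-net mixing weight
#' @return positive scalar lambda
#' @export
lambdaMaxValue <- function(X, y, alpha) {
  X <- .asMatrixInput(X)
  y01 <- .binaryResponse(y)
  st <- .standardize(t(X))
  n <- length(y01)
  max(abs(crossprod(st$X, y01 - mean(y01)))) / (n * max(alpha, 0.001))
}

#' Seeded random lambda grid, log-uniform
#'
#' Draws n penalty values log-uniformly from \[lo, hi\] and returns them
#' sorted descending. Identical seeds give identical grids.
#'
#' @param n number of values (default 200)
#' @param lo,hi positive range bounds, lo < hi
#' @param seed integer seed
#' @return numeric vector of length n, sorted descending
#' @export
generateLambdaGrid <- function(n = 200L, lo, hi, seed = 1L) {
  stopifnot(n >= 1L)
  if (lo <= 0) stop("lambda grid lower bound must be > 0")
  if (hi <= lo) stop("lambda grid upper bound must exceed lower bound")
  set.seed(seed)
  sort(exp(runif(n, log(lo), log(hi))), decreasing = TRUE)
}

#' Fit a penalized logistic regression at one (alpha, lambda)
#'
#' Features (probe rows of X) are standardized to mean 0, sd 1 on the given
#' samples before fitting; coefficients are reported on the standardized
#' scale together with the centering/scaling parameters. A lambda of 0 is
#' replaced by a tiny ridge floor (1e-8) to keep the optimizer bounded on
#' separable data.
#'
#' @param X probes-by-samples matrix or MValueMatrix (training samples)
#' @param y binary response (two classes required)
#' @param alpha mixing weight in \[0,1\]
#' @param lambda penalty strength >= 0
#' @return list: coefficients (named, standardized scale), intercept,
#'   center, scale
#' @export
fitElasticNetLogistic <- function(X, y, alpha, lambda) {
  stopifnot(alpha >= 0, alpha <= 1, lambda >= 0)
  X <- .asMatrixInput(X)
  y01 <- .binaryResponse(y)
  st <- .standardize(t(X))
  path <- .glmnetPath(st$X, y01, alpha, lambda)
  list(coefficients = setNames(path$beta[, 1L], rownames(X)),
       intercept = unname(path$intercept[1L]),
       center = setNames(st$center, rownames(X)),
       scale = setNames(st$scale, rownames(X)))
}

## CV accuracy of every lambda in a grid, for one alpha. Returns the
## folds x lambdas accuracy matrix.
.cvAccuracyGrid <- function(X, y01, alpha, lambdaGrid, foldID) {
  k <- max(foldID)
  acc <- matrix(NA_real_, k, length(lambdaGrid))
  for (f in seq_len(k)) {
    tr <- foldID != f
    st <- .standardize(t(X[, tr, drop = FALSE]))
    path <- .glmnetPath(st$X, y01[tr], alpha, lambdaGrid)
    Xte <- sweep(sweep(t(X[, !tr, drop = FALSE]), 2L, st$center), 2L,
                 st$scale, "/")
    eta <- sweep(Xte %*% path$beta, 2L, path$intercept, "+")
    pred <- .logistic(eta) >= 0.5
    acc[f, ] <- colMeans(pred == (y01[!tr] == 1L))
  }
  acc
}

#' Pick the best lambda from a grid by cross-validated accuracy
#'
#' Stratified k-fold CV; the grid member maximizing mean CV accuracy wins,
#' with ties broken toward the larger lambda (the sparser model).
#'
#' @param X probes-by-samples matrix or MValueMatrix
#' @param y binary response
#' @param alpha mixing weight
#' @param lambdaGrid candidate penalties (non-empty)
#' @param folds fold count (>= 2), ignored when foldID is given
#' @param seed fold-assignment seed, ignored when foldID is given
#' @param foldID optional explicit fold assignment (integer per sample)
#' @return list: lambda (the winner), meanAccuracy (per grid member,
#'   in grid order), foldID
#' @export
bestLambdaByCV <- function(X, y, alpha, lambdaGrid, folds = 5L, seed = 1L,
                           foldID = NULL) {
  stopifnot(length(lambdaGrid) >= 1L)
  X <- .asMatrixInput(X)
  y01 <- .binaryResponse(y)
  if (is.null(foldID)) foldID <- makeCVFolds(y01, folds, seed)
  acc <- colMeans(.cvAccuracyGrid(X, y01, alpha, lambdaGrid, foldID))
  best <- which(acc == max(acc))
  winner <- best[which.max(lambdaGrid[best])]
  list(lambda = lambdaGrid[winner], meanAccuracy = acc, foldID = foldID)
}

#' Stability-selection percentages across alphas and CV folds
#'
#' For each alpha: a seeded random lambda grid is generated, the best lambda
#' is chosen by CV accuracy on the shared stratified folds, the model is
#' refit on each fold's training portion at that lambda, and each probe's
#' per-alpha selection percentage is the fraction of folds with a non-zero
#' coefficient. The overall percentage is the mean of per-alpha percentages
#' (\code{pooled = TRUE} instead pools the indicator over all alpha-fold
#' fits; the two coincide when every alpha uses the same fold count). Probes
#' are ranked by overall percentage descending, ties by probe id.
#'
#' @param X complete probes-by-samples matrix or MValueMatrix
#' @param y binary response
#' @param alphas mixing weights (default 0.1 to 1 step 0.1)
#' @param nLambda random lambda grid size per alpha (default 200)
#' @param folds CV fold count (default 5)
#' @param seed integer seed controlling folds and lambda grids
#' @param lambdaRange optional c(lo, hi) for the lambda grids; default is
#'   \[lambda_max * 1e-4, lambda_max\] per alpha
#' @param pooled use the pooled-fraction definition of the overall
#'   percentage
#' @return a \linkS4class{SelectionRanking}
#' @export
selectionPercentage <- function(X, y, alphas = seq(0.1, 1, by = 0.1),
                                nLambda = 200L, folds = 5L, seed = 1L,
                                lambdaRange = NULL, pooled = FALSE) {
  X <- .asMatrixInput(X)
  if (anyNA(X)) stop("X must be complete (run the QC cascade first)")
  y01 <- .binaryResponse(y)
  foldID <- makeCVFolds(y01, folds, seed)
  probes <- rownames(X)
  perAlpha <- matrix(0, length(probes), length(alphas),
                     dimnames = list(probes, paste0("pct_alpha_", alphas)))
  chosen <- numeric(length(alphas))
  for (a in seq_along(alphas)) {
    rng <- lambdaRange
    if (is.null(rng)) {
      hi <- lambdaMaxValue(X, y01, alphas[a])
      rng <- c(hi * 1e-4, hi)
    }
    ## grid seed keyed to the alpha value itself, so results do not depend
    ## on the ordering of the alphas argument
    grid <- generateLambdaGrid(nLambda, rng[1L], rng[2L],
                               .subSeed(seed, round(1000 * alphas[a])))
    cv <- bestLambdaByCV(X, y01, alphas[a], grid, foldID = foldID)
    chosen[a] <- cv$lambda
    sel <- matrix(FALSE, length(probes), folds)
    for (f in seq_len(folds)) {
      tr <- foldID != f
      st <- .standardize(t(X[, tr, drop = FALSE]))
      path <- .glmnetPath(st$X, y01[tr], alphas[a], cv$lambda)
      sel[, f] <- abs(path$beta[, 1L]) > .COEF_TOL
    }
    perAlpha[, a] <- 100 * rowMeans(sel)
  }
  ## With a common fold count per alpha the pooled fraction over all
  ## alpha-fold fits equals the mean of per-alpha percentages, so both modes
  ## share one computation.
  overall <- rowMeans(perAlpha)
  ord <- order(-overall, probes)
  tb <- data.frame(probe_id = probes, overall_pct = unname(overall),
                   stringsAsFactors = FALSE)
  tb <- cbind(tb, as.data.frame(perAlpha, row.names = NULL))
  tb$rank <- integer(nrow(tb))
  tb$rank[ord] <- seq_len(nrow(tb))
  new("SelectionRanking", table = tb,
      metadata = list(alphas = alphas, lambda = setNames(chosen, alphas),
                      folds = folds, seed = seed, nLambda = nLambda,
                      pooled = pooled))
}

#' Nested top-probe sets from a selection ranking
#'
#' @param ranking a \linkS4class{SelectionRanking}
#' @param sizes probe-set sizes; each must not exceed the ranking length
#' @return named list of probe-id vectors, nested (smaller sets are prefixes
#'   of larger ones) under the ranking's deterministic tie-break order
#' @export
topProbeSets <- function(ranking, sizes) {
  stopifnot(is(ranking, "SelectionRanking"))
  tb <- annotationTable(ranking)
  if (any(sizes > nrow(tb)))
    stop("requested probe-set size exceeds ranking length (",
         nrow(tb), ")")
  ordered <- tb$probe_id[order(tb$rank)]
  setNames(lapply(sizes, function(m) ordered[seq_len(m)]),
           paste0("top", sizes))
}

#' Write a selection ranking as TSV
#' @param ranking a \linkS4class{SelectionRanking}
#' @param path destination file
#' @return invisibly, the path
#' @export
writeRanking <- function(ranking, path) {
  write.table(annotationTable(ranking), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
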