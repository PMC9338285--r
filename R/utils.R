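## Shared numeric helpers: seeded stratified folds, rank-based AUC, logistic
## link. Fold construction is exported because the stability-selection oracle
## tests replay fits on the identical fold assignment.

.logistic <- function(x) 1 / (1 + exp(-x))

#' Seeded stratified cross-validation folds
#'
#' Samples are shuffled within each class and dealt round-robin over folds,
#' so every fold carries each class (up to integer rounding) and the
#' assignment is reproducible under the seed.
#'
#' @param y class labels (any atomic vector)
#' @param k number of folds (>= 2)
#' @param seed integer seed
#' @return integer fold id in 1..k per element of y
#' @export
makeCVFolds <- function(y, k = 5L, seed = 1L) {
  stopifnot(k >= 2L)
  if (min(table(y)) < k)
    stop("a class has fewer members than folds; stratified folding impossible")
  fold <- integer(length(y))
  set.seed(seed)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a random positive scores above a random negative, with
#' 0.5 credit for ties; computed from midranks. Returns NA when either class
#' is absent.
#'
#' @param scores numeric predicted scores or probabilities
#' @param truth logical (TRUE = positive) or 0/1 vector
#' @return AUC in \[0,1\], or NA
#' @export
rocAUC <- function(scores, truth) {
  truth <- as.logical(truth)
  npos <- sum(truth); nneg <- sum(!truth)
  if (npos == 0L || nneg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[truth]) - npos * (npos + 1) / 2) / (npos * nneg)
}

## Deterministic sub-seed derivation: keeps derived seeds inside the 32-bit
## integer range whatever the base seed.
.subSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1103L + i * 12289L) %% 2147483629)
}

.asMatrixInput <- function(x) {
  if (is(x, "BetaMatrix") || is(x, "MValueMatrix")) assayValues(x) else x
}
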