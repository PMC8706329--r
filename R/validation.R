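#' @title Classifier-agnostic evaluation harness
#' @description Matthews correlation coefficient, repeated stratified k-fold
#'   cross-validation, out-of-bag ensemble evaluation and label-permutation
#'   testing, all written against a minimal base-classifier contract so the
#'   same code path evaluates a PLS classifier, a random forest, or any
#'   other learner.
#' @name validation
NULL

#' Matthews correlation coefficient from confusion counts
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined as 0 when
#' any marginal (hence the denominator) is 0; this convention keeps
#' degenerate constant predictors at chance level instead of NaN.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts.
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(tp, tn, fp, fn) {
  if (any(c(tp, tn, fp, fn) < 0)) stop("confusion counts must be >= 0")
  if (tp + tn + fp + fn == 0) stop("no evaluated samples")
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}

#' MCC of predicted vs true binary labels
#'
#' The first level of `levels` (default: sorted unique truth) is treated as
#' the positive class; MCC is symmetric in that choice.
#'
#' @param truth,pred Label vectors of equal length.
#' @param levels Optional explicit class levels.
#' @return MCC in `[-1, 1]`.
#' @export
mcc_labels <- function(truth, pred, levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(as.character(truth)))
  truth <- factor(as.character(truth), levels = levels)
  pred <- factor(as.character(pred), levels = levels)
  pos <- levels[1]
  mcc(sum(truth == pos & pred == pos), sum(truth != pos & pred != pos),
      sum(truth != pos & pred == pos), sum(truth == pos & pred != pos))
}

#' Base-classifier constructors
#'
#' A learner is a list with `fit(X, y)` returning a fitted model and
#' `predict(model, X)` returning labels from the training label set —
#' the contract every harness function works against.
#'
#' `pls_learner` wraps the package's PLS2 classifier at a fixed number of
#' components; `rf_learner` wraps `randomForest::randomForest` with the
#' conventional defaults (500 trees, sqrt(p) candidate features per split).
#'
#' @param A Number of PLS components.
#' @param ntree,mtry Random-forest hyperparameters; `mtry = NULL` keeps the
#'   sqrt(p) default.
#' @param seed Seed applied at each `fit` call for learners with internal
#'   randomness.
#' @return A learner list with elements `fit`, `predict`, `name`.
#' @export
pls_learner <- function(A = 2) {
  list(
    name = sprintf("PLS2C(A=%d)", A),
    fit = function(X, y) fit_pls2(X, y, A = min(A, max_pls_components(X))),
    predict = function(model, X) classify(model, X)
  )
}

#' @rdname pls_learner
#' @export
rf_learner <- function(ntree = 500, mtry = NULL, seed = 1) {
  list(
    name = "RF",
    fit = function(X, y) {
      y <- factor(y)
      args <- list(x = X, y = y, ntree = ntree)
      if (!is.null(mtry)) args$mtry <- mtry
      withr::with_seed(seed, do.call(randomForest::randomForest, args))
    },
    predict = function(model, X)
      as.character(stats::predict(model, X))
  )
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin into folds.
stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    if (length(idx) < folds)
      stop("class '", cl, "' has fewer members than folds")
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Repeated stratified k-fold cross-validated MCC
#'
#' Per repeat: a fresh stratified fold split, out-of-fold predictions pooled
#' over the folds, and one MCC computed from the pooled predictions. The
#' returned MCCcv is the mean over repeats (per-repeat values in the
#' `"per_repeat"` attribute).
#'
#' @param learner A base classifier (see [pls_learner()]).
#' @param X Samples-by-features matrix.
#' @param y Binary labels; every class needs at least `folds` members.
#' @param folds Folds per repeat (default 5).
#' @param repeats Number of repeats (default 50).
#' @param seed Seed controlling all splits.
#' @return MCCcv (numeric scalar) with attribute `per_repeat`.
#' @export
repeated_cv_mcc <- function(learner, X, y, folds = 5, repeats = 50,
                            seed = 1) {
  y <- as.character(y)
  levels <- sort(unique(y))
  per_repeat <- withr::with_seed(seed, {
    vapply(seq_len(repeats), function(r) {
      fold <- stratified_folds(y, folds)
      pred <- character(length(y))
      for (f in seq_len(folds)) {
        tr <- fold != f
        model <- learner$fit(X[tr, , drop = FALSE], y[tr])
        pred[!tr] <- learner$predict(model, X[!tr, , drop = FALSE])
      }
      mcc_labels(y, pred, levels)
    }, numeric(1))
  })
  out <- mean(per_repeat)
  attr(out, "per_repeat") <- per_repeat
  out
}

#' Out-of-bag MCC of a resampled ensemble
#'
#' Fits `n_models` models on stratified random subsamples (fraction
#' `frac`, without replacement) and predicts, for each sample, by majority
#' vote over the models in which it was out-of-bag. Samples never
#' out-of-bag are excluded with a warning. The MCC of the aggregated
#' votes is MCCoob.
#'
#' @param learner A base classifier.
#' @param X,y Data and binary labels.
#' @param n_models Ensemble size.
#' @param frac In-bag fraction per model (default 0.8).
#' @param seed Seed for the subsampling.
#' @return MCCoob with attributes `oob_pred` (majority-vote label per
#'   sample, NA when never out-of-bag) and `n_never_oob`.
#' @export
oob_mcc <- function(learner, X, y, n_models = 200, frac = 0.8, seed = 1) {
  y <- as.character(y)
  levels <- sort(unique(y))
  n <- length(y)
  votes <- matrix(0L, n, length(levels), dimnames = list(NULL, levels))
  withr::with_seed(seed, {
    for (b in seq_len(n_models)) {
      inbag <- stratified_subsample(y, frac)
      oob <- setdiff(seq_len(n), inbag)
      if (!length(oob)) next
      model <- learner$fit(X[inbag, , drop = FALSE], y[inbag])
      pred <- learner$predict(model, X[oob, , drop = FALSE])
      for (l in levels) votes[oob[pred == l], l] <-
          votes[oob[pred == l], l] + 1L
    }
  })
  seen <- rowSums(votes) > 0
  if (!any(seen)) stop("no sample was ever out-of-bag")
  n_never <- sum(!seen)
  if (n_never > 0)
    warning(n_never, " sample(s) never out-of-bag; excluded from MCCoob")
  pred <- levels[max.col(votes, ties.method = "first")]
  out <- mcc_labels(y[seen], pred[seen], levels)
  attr(out, "oob_pred") <- ifelse(seen, pred, NA_character_)
  attr(out, "n_never_oob") <- n_never
  out
}

# Stratified subsample without replacement: round(frac * n_c) per class,
# at least 1 and at most n_c - 1 so both in-bag and out-of-bag sets stay
# populated per class whenever n_c >= 2.
stratified_subsample <- function(y, frac) {
  unlist(lapply(unique(y), function(cl) {
    idx <- which(y == cl)
    k <- min(max(round(frac * length(idx)), 1), max(length(idx) - 1, 1))
    sample(idx, k)
  }), use.names = FALSE)
}

#' Label-permutation test of a performance statistic
#'
#' Recomputes `stat_fn(X, y_permuted)` under `n_perm` random permutations of
#' the labels (the data untouched) and returns the plus-one-corrected
#' exceedance probability `p = (1 + #{perm >= observed}) / (n_perm + 1)`.
#'
#' @param stat_fn Function `(X, y) -> scalar` (e.g. an MCCcv wrapper).
#' @param X,y Data and labels.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed for the permutations.
#' @return p-value, with attributes `observed` and `perm_stats`.
#' @export
permutation_test <- function(stat_fn, X, y, n_perm = 1000, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  observed <- stat_fn(X, y)
  perm <- withr::with_seed(seed, vapply(seq_len(n_perm), function(b)
    stat_fn(X, sample(y)), numeric(1)))
  p <- (1 + sum(perm >= observed)) / (n_perm + 1)
  attr(p, "observed") <- observed
  attr(p, "perm_stats") <- perm
  p
}
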