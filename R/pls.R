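#' @title PLS2 classification with VIP-driven stability selection
#' @description Partial least squares on a dummy-coded class response
#'   (PLS2C) fitted by NIPALS, variable importance in projection (VIP)
#'   scores, component-count selection at the first maximum of
#'   cross-validated MCC, and stability selection: 200 stratified
#'   subsampling sub-models, each running iterative VIP-based variable
#'   elimination and keeping its best feature set, aggregated into
#'   per-feature selection frequencies and an out-of-bag MCC.
#' @name pls2c
NULL

# Largest admissible component count for an n x p matrix.
max_pls_components <- function(X) max(1L, min(nrow(X) - 1L, ncol(X)))

# Dummy-code a label vector into an n x 2 indicator matrix with fixed,
# sorted level order.
dummy_code <- function(y) {
  levels <- sort(unique(as.character(y)))
  if (length(levels) != 2) stop("exactly two classes required")
  Y <- outer(as.character(y), levels, "==") * 1
  colnames(Y) <- levels
  Y
}

#' Fit a PLS2 model by NIPALS
#'
#' X and the response are mean-centered internally (means stored on the
#' model). The response may be a label vector (dummy-coded to two indicator
#' columns) or a numeric matrix. Components are extracted by NIPALS with
#' deflation of both blocks; scores are mutually orthogonal. With a single
#' response column the fit coincides with PLS1, and at full rank the
#' regression coefficients coincide with ordinary least squares.
#'
#' @param X Samples-by-features numeric matrix.
#' @param y Class labels (two classes) or a numeric response matrix.
#' @param A Number of components, `1 <= A <= min(n - 1, p)`.
#' @return A `pls_model`: `W` (weights, normalized columns), `P` (X
#'   loadings), `Tmat` (scores), `Qy` (response loadings), `B` (coefficients
#'   for centered data), `x_means`, `y_means`, `levels` (class labels when
#'   dummy-coded), `A`.
#' @export
fit_pls2 <- function(X, y, A) {
  X <- as.matrix(X)
  if (is.matrix(y) || is.data.frame(y)) {
    Y <- as.matrix(y); levels <- NULL
  } else {
    Y <- dummy_code(y); levels <- colnames(Y)
  }
  if (nrow(Y) != nrow(X)) stop("X and response sizes differ")
  if (A < 1 || A > max_pls_components(X))
    stop("A must lie in [1, min(n - 1, p)]")
  x_means <- colMeans(X); y_means <- colMeans(Y)
  E <- sweep(X, 2, x_means); Fm <- sweep(Y, 2, y_means)
  if (all(abs(E) < 1e-14)) stop("X has zero variance")
  n <- nrow(E); p <- ncol(E); m <- ncol(Fm)
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  Tmat <- matrix(0, n, A); Qy <- matrix(0, m, A)
  for (a in seq_len(A)) {
    u <- Fm[, which.max(colSums(Fm^2))]
    if (all(abs(u) < 1e-14)) { A <- a - 1L; break }
    t_old <- rep(Inf, n)
    for (it in seq_len(500)) {
      w <- crossprod(E, u)[, 1]
      w <- w / sqrt(sum(w^2))
      t_ <- E %*% w
      q <- crossprod(Fm, t_)[, 1] / sum(t_^2)
      u <- (Fm %*% q) / sum(q^2)
      if (sum((t_ - t_old)^2) < 1e-24 * sum(t_^2)) break
      t_old <- t_
    }
    p_ <- crossprod(E, t_)[, 1] / sum(t_^2)
    E <- E - t_ %*% t(p_)
    Fm <- Fm - t_ %*% t(q)
    W[, a] <- w; P[, a] <- p_; Tmat[, a] <- t_; Qy[, a] <- q
  }
  if (A < 1) stop("response has zero variance")
  W <- W[, seq_len(A), drop = FALSE]; P <- P[, seq_len(A), drop = FALSE]
  Tmat <- Tmat[, seq_len(A), drop = FALSE]
  Qy <- Qy[, seq_len(A), drop = FALSE]
  R <- W %*% solve(crossprod(P, W))          # X-space rotation
  B <- R %*% t(Qy)
  structure(list(W = W, P = P, Tmat = Tmat, Qy = Qy, R = R, B = B,
                 x_means = x_means, y_means = y_means,
                 levels = levels, A = A,
                 feature_names = colnames(X)),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat("PLS2 model:", x$A, "components,", length(x$x_means), "features\n")
  invisible(x)
}

#' Predict the (numeric) response of a PLS2 model
#'
#' @param object A `pls_model`.
#' @param newdata Matrix on the training feature set.
#' @param ... Unused.
#' @return Predicted response matrix (dummy scale when label-fitted).
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_means))
    stop("feature mismatch: model has ", length(object$x_means),
         " features, newdata has ", ncol(newdata))
  sweep(newdata, 2, object$x_means) %*% object$B +
    matrix(object$y_means, nrow(newdata), length(object$y_means),
           byrow = TRUE)
}

#' Classify samples with a label-fitted PLS2 model
#'
#' Two-class rule: predict the class whose dummy-column prediction is
#' larger; on an exact tie, the class with the lower label index.
#'
#' @param model A `pls_model` fitted on labels.
#' @param X Matrix on the training feature set.
#' @return Character vector of predicted labels.
#' @export
classify <- function(model, X) {
  if (is.null(model$levels)) stop("model was not fitted on class labels")
  Yhat <- predict(model, X)
  model$levels[max.col(Yhat, ties.method = "first")]
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt(p * sum_a SS_a w_ja^2 / sum_a SS_a)` with normalized weight
#' columns and `SS_a` the response variance explained by component a
#' (`|t_a|^2 |q_a|^2`). The mean squared VIP is 1, so `sum VIP^2 = p`.
#'
#' @param model A `pls_model`.
#' @return Numeric VIP score per feature.
#' @export
vip <- function(model) {
  ss <- colSums(model$Tmat^2) * colSums(model$Qy^2)
  if (sum(ss) == 0) return(rep(1, nrow(model$W)))
  v <- sqrt(nrow(model$W) * (model$W^2 %*% ss)[, 1] / sum(ss))
  stats::setNames(v, model$feature_names)
}

# MCCcv profile over component counts 1..A_max, sharing fold fits: each
# fold is fitted once at A_max and predictions for smaller A reuse the
# leading components.
mcc_cv_profile <- function(X, y, A_max, folds, repeats, seed) {
  y <- as.character(y)
  levels <- sort(unique(y))
  prof <- matrix(NA_real_, repeats, A_max)
  withr::with_seed(seed, {
    for (r in seq_len(repeats)) {
      fold <- stratified_folds(y, folds)
      pred <- matrix(NA_character_, length(y), A_max)
      for (f in seq_len(folds)) {
        tr <- fold != f
        A_f <- min(A_max, max_pls_components(X[tr, , drop = FALSE]))
        model <- fit_pls2(X[tr, , drop = FALSE], y[tr], A_f)
        Xc <- sweep(X[!tr, , drop = FALSE], 2, model$x_means)
        for (a in seq_len(A_max)) {
          aa <- min(a, model$A)
          Ba <- model$R[, seq_len(aa), drop = FALSE] %*%
            t(model$Qy[, seq_len(aa), drop = FALSE])
          Yhat <- Xc %*% Ba + matrix(model$y_means, sum(!tr),
                                     length(model$y_means), byrow = TRUE)
          pred[!tr, a] <- model$levels[max.col(Yhat,
                                               ties.method = "first")]
        }
      }
      prof[r, ] <- vapply(seq_len(A_max), function(a)
        mcc_labels(y, pred[, a], levels), numeric(1))
    }
  })
  colMeans(prof)
}

#' Choose the PLS component count at the first maximum of MCCcv
#'
#' Computes MCCcv for `A = 1..A_max` by repeated stratified k-fold
#' cross-validation and returns the first local maximum: the smallest A
#' whose MCCcv is not exceeded by that of A + 1 (ties resolve toward the
#' smaller A); `A_max` if MCCcv keeps increasing throughout.
#'
#' @param X,y Data and binary labels.
#' @param A_max Largest component count to consider.
#' @param folds,repeats Cross-validation scheme (defaults 5 and 50).
#' @param seed Seed for the splits.
#' @return Selected A (integer) with attribute `mcc_profile`.
#' @export
select_components <- function(X, y, A_max = 5, folds = 5, repeats = 50,
                              seed = 1) {
  if (A_max < 1) stop("A_max must be >= 1")
  A_max <- min(A_max, max_pls_components(X) - 1L,
               ncol(as.matrix(X)))
  A_max <- max(A_max, 1L)
  prof <- mcc_cv_profile(as.matrix(X), y, A_max, folds, repeats, seed)
  A <- A_max
  for (a in seq_len(A_max - 1)) {
    if (prof[a] >= prof[a + 1]) { A <- a; break }
  }
  out <- as.integer(A)
  attr(out, "mcc_profile") <- prof
  out
}

#' Stability selection for PLS2 classification
#'
#' Generates `n_sub` sub-models, each on a stratified random subsample
#' (fraction `frac` without replacement). Within a sub-model, features are
#' iteratively eliminated: fit PLS2C, score by VIP, drop features with
#' VIP below `vip_threshold`, refit; each iteration's feature set is scored
#' by a (light) cross-validated MCC on the subsample and the best-scoring
#' set is the sub-model's selection. Out-of-bag samples are predicted by the
#' best iteration's model; across sub-models each sample's out-of-bag
#' majority vote yields MCCoob, and each feature's selection frequency is
#' the fraction of sub-models whose best set contained it.
#'
#' @param X,y Data and binary labels.
#' @param A Component count for the sub-model fits; `NULL` selects it once
#'   on the full data via [select_components()].
#' @param n_sub Number of sub-models (default 200).
#' @param frac Subsample fraction (default 0.8).
#' @param vip_threshold VIP elimination cut (default 1, the conventional
#'   value).
#' @param max_iter Elimination iteration cap (default 10).
#' @param cv_folds,cv_repeats Cross-validation scheme used to score
#'   iterations within a sub-model; deliberately light (5-fold, 1 repeat)
#'   since only a ranking of nested feature sets is needed.
#' @param seed Seed; fixed seed gives an identical result.
#' @return A `stability_result`: `frequency` (per-feature selection
#'   frequency), `oob_pred` (majority-vote out-of-bag label per sample),
#'   `mcc_oob`, `submodel_mcc` (best MCCcv per sub-model), `selected`
#'   (features with frequency >= 0.5), `A`, `n_sub`.
#' @export
stability_selection <- function(X, y, A = NULL, n_sub = 200, frac = 0.8,
                                vip_threshold = 1, max_iter = 10,
                                cv_folds = 5, cv_repeats = 1, seed = 1) {
  X <- as.matrix(X)
  y <- as.character(y)
  levels <- sort(unique(y))
  if (length(levels) != 2 || any(table(y) < 2))
    stop("need two classes with >= 2 members each")
  if (is.null(A))
    A <- select_components(X, y, folds = cv_folds,
                           repeats = max(cv_repeats, 5), seed = seed)
  p <- ncol(X); n <- nrow(X)
  counts <- stats::setNames(numeric(p), colnames(X))
  votes <- matrix(0L, n, 2, dimnames = list(NULL, levels))
  submodel_mcc <- numeric(n_sub)
  seeds <- child_seeds(seed, n_sub)
  for (b in seq_len(n_sub)) {
    inbag <- withr::with_seed(seeds[b], stratified_subsample(y, frac))
    oob <- setdiff(seq_len(n), inbag)
    Xb <- X[inbag, , drop = FALSE]; yb <- y[inbag]
    cvf <- min(cv_folds, min(table(yb)))  # folds bounded by class size
    feats <- seq_len(p)
    best <- list(mcc = -Inf, feats = feats, model = NULL)
    for (it in seq_len(max_iter)) {
      A_it <- min(A, max_pls_components(Xb[, feats, drop = FALSE]))
      model <- fit_pls2(Xb[, feats, drop = FALSE], yb, A_it)
      m_it <- if (cvf >= 2)
        repeated_cv_mcc(pls_learner(A_it), Xb[, feats, drop = FALSE],
                        yb, folds = cvf, repeats = cv_repeats,
                        seed = seeds[b])
      else mcc_labels(yb, classify(model, Xb[, feats, drop = FALSE]))
      if (m_it > best$mcc)
        best <- list(mcc = as.numeric(m_it), feats = feats, model = model)
      keep <- feats[vip(model) >= vip_threshold]
      if (length(keep) == length(feats) || length(keep) < A + 1) break
      feats <- keep
    }
    counts[best$feats] <- counts[best$feats] + 1
    submodel_mcc[b] <- best$mcc
    if (length(oob)) {
      pred <- classify(best$model, X[oob, best$feats, drop = FALSE])
      for (l in levels)
        votes[oob[pred == l], l] <- votes[oob[pred == l], l] + 1L
    }
  }
  seen <- rowSums(votes) > 0
  oob_pred <- ifelse(seen, levels[max.col(votes, ties.method = "first")],
                     NA_character_)
  freq <- counts / n_sub
  structure(list(
    frequency = freq,
    oob_pred = oob_pred,
    mcc_oob = if (any(seen)) mcc_labels(y[seen], oob_pred[seen], levels)
              else NA_real_,
    submodel_mcc = submodel_mcc,
    selected = names(freq)[freq >= 0.5],
    A = as.integer(A), n_sub = n_sub), class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("Stability selection:", x$n_sub, "sub-models, A =", x$A, "\n")
  cat("  MCCoob =", round(x$mcc_oob, 3), "\n")
  cat("  features with frequency >= 0.5:", length(x$selected), "\n")
  invisible(x)
}
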