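#' Fit a principal component analysis model
#'
#' SVD-based PCA on (optionally internally centered) data. Sign convention:
#' each loading column is flipped so that its largest-magnitude element is
#' positive, making the decomposition deterministic.
#'
#' @param X Numeric matrix, samples by features.
#' @param A Number of components, `1 <= A <= rank(X)`.
#' @param center Subtract column means before fitting (default TRUE; pass
#'   FALSE for already-centered input).
#' @return A `pca_model`: `mean`, `loadings` (features x A, orthonormal),
#'   `scores` (samples x A), `eigenvalues` (score variances, n-1 denominator),
#'   `explained_variance` (fractions of total variance, non-increasing),
#'   `all_eigenvalues` (full spectrum, used for Q-statistic limits), `A`.
#' @export
fit_pca <- function(X, A, center = TRUE) {
  X <- as.matrix(X)
  mu <- if (center) colMeans(X) else rep(0, ncol(X))
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  pos <- sum(sv$d > max(sv$d) * 1e-12)
  if (A < 1 || A > pos) stop("A must lie in [1, rank(X)]")
  # fix sign: largest-magnitude loading element positive
  flip <- vapply(seq_len(pos), function(a) {
    v <- sv$v[, a]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  V <- sweep(sv$v[, seq_len(pos), drop = FALSE], 2, flip, "*")
  d2 <- sv$d[seq_len(pos)]^2
  ev <- d2 / (nrow(X) - 1)
  structure(list(
    mean = mu,
    loadings = V[, seq_len(A), drop = FALSE],
    scores = Xc %*% V[, seq_len(A), drop = FALSE],
    eigenvalues = ev[seq_len(A)],
    explained_variance = (d2 / sum(d2))[seq_len(A)],
    all_eigenvalues = ev,
    A = A, n = nrow(X)), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("PCA model:", x$A, "components,",
      sprintf("%.1f%% variance explained\n",
              100 * sum(x$explained_variance)))
  invisible(x)
}

#' Smallest number of components reaching a cumulative variance target
#'
#' @param X Data matrix.
#' @param target Cumulative explained-variance fraction in (0, 1];
#'   default 0.60.
#' @param center Passed to [fit_pca()].
#' @return Integer component count.
#' @export
choose_components_by_variance <- function(X, target = 0.60, center = TRUE) {
  if (target <= 0 || target > 1) stop("target must lie in (0, 1]")
  if (!length(X)) stop("empty matrix")
  m <- fit_pca(X, A = 1, center = center)
  frac <- m$all_eigenvalues / sum(m$all_eigenvalues)
  as.integer(which(cumsum(frac) >= target - 1e-12)[1])
}

#' Project new data onto a PCA model
#'
#' @param model A `pca_model`.
#' @param X Data on the training feature set.
#' @return List: `scores`, `residuals` (X minus its reconstruction).
#' @export
project_pca <- function(model, X) {
  Xc <- sweep(as.matrix(X), 2, model$mean)
  T_ <- Xc %*% model$loadings
  list(scores = T_, residuals = Xc - T_ %*% t(model$loadings))
}

#' Hotelling T2 / Q outlier test at level alpha
#'
#' For each sample, the within-model distance `T2 = sum_a t_a^2 / lambda_a`
#' is compared against the F-based limit `A (n-1) / (n-A) * F(1-alpha; A,
#' n-A)`, and the residual distance `Q` (squared reconstruction error)
#' against the Jackson-Mudholkar limit computed from the residual
#' eigenvalues. Samples exceeding a limit are flagged.
#'
#' @param model A `pca_model`.
#' @param X Data to test (the training data or new data on the same
#'   features).
#' @param alpha Test level (default 0.05).
#' @return An `outlier_report` data.frame: `T2`, `Q`, `T2_out`, `Q_out`,
#'   with attributes `T2_limit`, `Q_limit`, `alpha`.
#' @export
outlier_test <- function(model, X, alpha = 0.05) {
  pr <- project_pca(model, X)
  T_ <- pr$scores
  Q <- rowSums(pr$residuals^2)
  n <- model$n; A <- model$A
  if (n < A + 1) stop("need more samples than components")
  T2 <- rowSums(sweep(T_^2, 2, model$eigenvalues, "/"))
  T2_lim <- A * (n - 1) / (n - A) * stats::qf(1 - alpha, A, n - A)

  resid_ev <- model$all_eigenvalues[-seq_len(A)]
  resid_ev <- resid_ev[resid_ev > 0]
  if (length(resid_ev)) {
    th1 <- sum(resid_ev); th2 <- sum(resid_ev^2); th3 <- sum(resid_ev^3)
    h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
    if (!is.finite(h0) || h0 <= 0) h0 <- 1e-3
    ca <- stats::qnorm(1 - alpha)
    Q_lim <- th1 * (ca * sqrt(2 * th2 * h0^2) / th1 +
                      1 + th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
  } else {
    Q_lim <- 0
  }
  rep_ <- data.frame(T2 = T2, Q = Q,
                     T2_out = T2 > T2_lim, Q_out = Q > Q_lim)
  rownames(rep_) <- rownames(T_)
  attr(rep_, "T2_limit") <- T2_lim
  attr(rep_, "Q_limit") <- Q_lim
  attr(rep_, "alpha") <- alpha
  class(rep_) <- c("outlier_report", "data.frame")
  rep_
}
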