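#' @title Per-feature two-group screening
#' @description Fold change (ratio of group medians on the normalized,
#'   un-logged scale), two-sided Mann-Whitney tests, and Storey q-values for
#'   FDR control, assembled into a volcano-ready table.
#' @name univariate
NULL

#' Fold change between two groups
#'
#' `FC = median(A) / median(B)` on positive intensities, with
#' `log2FC = log2(FC)`; medians pair naturally with the rank-based
#' Mann-Whitney test used alongside.
#'
#' @param a,b Positive intensity vectors for the two groups.
#' @return List: `fc`, `log2fc`, `median_a`, `median_b`.
#' @export
fold_change <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  ma <- stats::median(a); mb <- stats::median(b)
  if (mb == 0) stop("zero median in the denominator group")
  list(fc = ma / mb, log2fc = log2(ma / mb), median_a = ma, median_b = mb)
}

#' Two-sided Mann-Whitney test
#'
#' Exact enumeration when the pooled sample size is at most 20 and there are
#' no ties; tie-corrected normal approximation with continuity correction
#' otherwise. U counts pairs with `x > y` (so perfectly separated
#' `x < y` data gives U = 0).
#'
#' @param x,y Numeric samples.
#' @return List: `U`, `p` (two-sided), `exact` (logical).
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty input")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 20) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value, exact = exact)
}

# pi0 estimate: natural cubic smoother of pi0(lambda) over the lambda grid,
# evaluated at the largest grid point, clipped to (0, 1].
estimate_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  m <- length(p)
  pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0l, df = 3)
  pi0 <- stats::predict(fit, max(lambda))$y
  min(max(pi0, 1 / m), 1)
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 by the lambda-smoother (natural cubic
#' smoothing spline of `pi0(lambda) = #{p > lambda} / (m (1 - lambda))` over
#' the grid 0.05..0.95, evaluated at 0.95, clipped to (0, 1]), then computes
#' `q_i = pi0 * min_{p_j >= p_i} (m p_j / rank_j)`. With `pi0 = 1` this is
#' exactly the Benjamini-Hochberg adjusted p-value.
#'
#' @param p P-values in (0, 1].
#' @param pi0 Null-proportion override; `NULL` (default) estimates it.
#' @return Q-values in (0, 1], same order as `p`.
#' @export
storey_qvalues <- function(p, pi0 = NULL) {
  if (!length(p)) stop("no p-values")
  if (any(p <= 0 | p > 1 | is.na(p))) stop("p-values must lie in (0, 1]")
  m <- length(p)
  if (is.null(pi0)) pi0 <- if (m >= 20) estimate_pi0(p) else 1
  ord <- order(p, decreasing = TRUE)
  q <- numeric(m)
  q[ord] <- pmin(1, cummin(pi0 * m * p[ord] / (m:1)))
  q
}

#' Volcano table for a two-group comparison
#'
#' One row per feature: group medians, fold change on the normalized
#' un-logged intensities, two-sided Mann-Whitney p, Storey q, and flags for
#' the conventional volcano thresholds `|log2FC| >= 1` and `pMW <= 0.05`.
#'
#' @param X Samples-by-features matrix of normalized (positive, un-logged)
#'   intensities.
#' @param groups Binary label per row of `X`; the first sorted level is the
#'   fold-change numerator.
#' @param fc_flag,p_flag Flag thresholds (defaults 1 and 0.05).
#' @param pi0 Optional pi0 override passed to [storey_qvalues()].
#' @return A `data.frame` (one row per feature) ordered as the input
#'   columns: `feature`, `median_a`, `median_b`, `fc`, `log2fc`, `p_mw`,
#'   `qvalue`, `fc_flagged`, `p_flagged`.
#' @export
volcano_table <- function(X, groups, fc_flag = 1, p_flag = 0.05,
                          pi0 = NULL) {
  X <- as.matrix(X)
  groups <- as.character(groups)
  levels <- sort(unique(groups))
  if (length(levels) != 2) stop("exactly two groups required")
  ia <- groups == levels[1]; ib <- groups == levels[2]
  if (sum(ia) < 2 || sum(ib) < 2)
    stop("each group needs at least 2 samples")
  res <- lapply(seq_len(ncol(X)), function(j) {
    fc <- fold_change(X[ia, j], X[ib, j])
    mw <- mann_whitney(X[ia, j], X[ib, j])
    c(fc$median_a, fc$median_b, fc$fc, fc$log2fc, mw$p)
  })
  res <- do.call(rbind, res)
  q <- storey_qvalues(res[, 5], pi0 = pi0)
  data.frame(
    feature = colnames(X),
    median_a = res[, 1], median_b = res[, 2],
    fc = res[, 3], log2fc = res[, 4],
    p_mw = res[, 5], qvalue = q,
    fc_flagged = abs(res[, 4]) >= fc_flag,
    p_flagged = res[, 5] <= p_flag,
    stringsAsFactors = FALSE, row.names = NULL
  )
}
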