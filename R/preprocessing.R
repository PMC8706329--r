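#' @title Feature-filtering cascade, imputation, normalization and scaling
#' @description Implements the standard untargeted-LC-MS preprocessing chain
#'   driven by QC and blank injections: (1) drop features with any missing QC
#'   value, (2) drop features whose blank signal is substantial relative to
#'   the QCs (95th blank percentile over 5th QC percentile above a
#'   threshold), (3) drop features with QC coefficient of variation above a
#'   threshold, (4) impute remaining missing values uniformly between zero
#'   and the feature minimum, (5) probabilistic quotient normalization
#'   against the QC median spectrum, (6) re-apply the QC CV filter, (7)
#'   natural-log transform and mean-center. Filters only ever drop columns;
#'   retained intensities are never altered by a filter.
#' @name preprocessing
NULL

new_filter_report <- function(rule, removed, surviving) {
  data.frame(rule = rule, removed = as.integer(removed),
             surviving = as.integer(surviving), stringsAsFactors = FALSE)
}

#' Drop features with missing values in the QC injections
#'
#' A feature that cannot be measured consistently in the pooled QC sample is
#' considered unreliable; a single missing QC observation removes it.
#' Study/Blank missingness is not considered.
#'
#' @param table A [feature_table()] with at least one QC row.
#' @return List: `table` (filtered), `report` (one-row filter report).
#' @export
filter_missing_in_qc <- function(table) {
  qc <- ft_qc(table)
  if (!length(qc)) stop("no QC rows present")
  keep <- colSums(is.na(table$intensities[qc, , drop = FALSE])) == 0
  list(table = ft_subset(table, cols = which(keep)),
       report = new_filter_report("missing_in_qc", sum(!keep), sum(keep)))
}

# Percentile by linear interpolation of order statistics (type 7), the
# documented convention for the blank-ratio rule. Missing values ignored.
pctl <- function(x, p) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  unname(stats::quantile(x, p, type = 7))
}

#' Drop features with substantial blank signal
#'
#' Removes features whose 95th percentile across blank injections exceeds
#' `threshold` times the 5th percentile across QC injections — i.e. features
#' plausibly dominated by mobile-phase or carry-over contamination. Features
#' absent from the blanks (95th percentile 0) are always retained; features
#' whose QC 5th percentile is 0 are removed.
#'
#' @param table A [feature_table()] with QC and Blank rows.
#' @param threshold Maximum tolerated blank/QC percentile ratio.
#' @return List: `table`, `report`.
#' @export
filter_blank_ratio <- function(table, threshold = 0.20) {
  qc <- ft_qc(table); bl <- ft_blank(table)
  if (!length(bl)) stop("no Blank rows present")
  if (!length(qc)) stop("no QC rows present")
  p95b <- apply(table$intensities[bl, , drop = FALSE], 2, pctl, p = 0.95)
  p05q <- apply(table$intensities[qc, , drop = FALSE], 2, pctl, p = 0.05)
  p95b[is.na(p95b)] <- 0  # feature entirely missing in blanks: no evidence
  keep <- ifelse(p05q > 0, p95b / p05q <= threshold, p95b == 0)
  keep[is.na(keep)] <- FALSE
  list(table = ft_subset(table, cols = which(keep)),
       report = new_filter_report("blank_ratio", sum(!keep), sum(keep)))
}

#' Drop features with high QC coefficient of variation
#'
#' The QC pool is chemically constant, so a feature's CV across QC
#' injections measures pure analytical variability. Features with CV (sample
#' SD over mean) above `max_cv` are removed. The rule is re-applied after
#' normalization, which can change CVs.
#'
#' @param table A [feature_table()] with >= 2 QC rows.
#' @param max_cv Maximum tolerated QC CV.
#' @return List: `table`, `report`.
#' @export
filter_qc_cv <- function(table, max_cv = 0.20) {
  qc <- ft_qc(table)
  if (length(qc) < 2) stop("need >= 2 QC rows to estimate a CV")
  Q <- table$intensities[qc, , drop = FALSE]
  cv <- apply(Q, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2 || mean(v) == 0) return(Inf)
    stats::sd(v) / mean(v)
  })
  keep <- cv <= max_cv
  list(table = ft_subset(table, cols = which(keep)),
       report = new_filter_report("qc_cv", sum(!keep), sum(keep)))
}

#' Impute missing intensities below the feature minimum
#'
#' Each missing entry is replaced by a uniform draw strictly between zero
#' and the minimum observed value of that feature, reflecting the
#' left-censored nature of low-abundance missingness in LC-MS data.
#' Observed entries are never touched.
#'
#' @param table A [feature_table()]; every feature with missing values must
#'   have at least one observed value.
#' @param seed RNG seed for reproducible draws.
#' @return The imputed `feature_table` (complete).
#' @export
impute_missing <- function(table, seed = 1) {
  X <- table$intensities
  miss <- which(is.na(X), arr.ind = TRUE)
  if (!nrow(miss)) return(table)
  mins <- apply(X, 2, function(v) suppressWarnings(min(v, na.rm = TRUE)))
  if (any(!is.finite(mins[unique(miss[, 2])])))
    stop("a feature is entirely missing; cannot impute")
  X[miss] <- withr::with_seed(seed,
    stats::runif(nrow(miss), 0, mins[miss[, 2]]))
  feature_table(X, table$roles, table$classes)
}

#' Probabilistic quotient normalization
#'
#' Removes per-sample dilution by dividing each sample by the median, over
#' features, of its quotients to a reference spectrum. The reference is the
#' feature-wise median of the QC injections (the pooled, dilution-stable
#' sample) by default, falling back to the Study median when no QCs exist or
#' when `reference = "study"`.
#'
#' @param table A complete (post-imputation) [feature_table()].
#' @param reference `"qc"` (default) or `"study"`.
#' @return List: `table` (normalized), `quotients` (per-sample dilution
#'   estimates, named) for audit.
#' @export
pqn_normalize <- function(table, reference = c("qc", "study")) {
  reference <- match.arg(reference)
  X <- table$intensities
  if (anyNA(X)) stop("PQN requires a complete table; impute first")
  rows <- if (reference == "qc" && length(ft_qc(table))) ft_qc(table)
          else ft_study(table)
  ref <- apply(X[rows, , drop = FALSE], 2, stats::median)
  ok <- ref > 0
  if (!any(ok)) stop("reference spectrum is zero for all features")
  q <- apply(sweep(X[, ok, drop = FALSE], 2, ref[ok], "/"), 1,
             stats::median)
  list(table = feature_table(X / q, table$roles, table$classes),
       quotients = q)
}

#' Natural-log transform and mean-center
#'
#' Prepares a complete, normalized table for multivariate modelling: natural
#' log followed by column mean subtraction (means computed over the rows
#' supplied, Study rows by default).
#'
#' @param table A [feature_table()] with strictly positive intensities, or a
#'   plain numeric matrix.
#' @param rows Row indices to transform and center over; defaults to Study
#'   rows of a feature table, all rows of a matrix.
#' @return List: `X` (centered log matrix, `rows` by features), `means`
#'   (column means on the log scale), `classes` (class labels for `rows`,
#'   when available).
#' @export
log_center <- function(table, rows = NULL) {
  if (inherits(table, "feature_table")) {
    if (is.null(rows)) rows <- ft_study(table)
    M <- table$intensities[rows, , drop = FALSE]
    cl <- table$classes[rows]
  } else {
    M <- as.matrix(table)
    if (!is.null(rows)) M <- M[rows, , drop = FALSE]
    cl <- NULL
  }
  if (anyNA(M) || any(M <= 0))
    stop("log transform requires complete, strictly positive intensities")
  L <- log(M)
  mu <- colMeans(L)
  list(X = sweep(L, 2, mu), means = mu, classes = cl)
}

#' Run the full preprocessing cascade
#'
#' Applies, in fixed order: missing-in-QC filter, blank-ratio filter, QC CV
#' filter, below-minimum imputation, PQN, QC CV filter again, then log
#' transform and mean-centering of the Study rows. Filter-report rows
#' telescope: each rule's surviving count is the next rule's input count.
#'
#' @param table A [feature_table()].
#' @param blank_ratio_threshold Blank/QC percentile ratio limit.
#' @param max_qc_cv QC CV limit (applied before and after normalization).
#' @param seed Seed for the imputation draws.
#' @param pqn_reference Passed to [pqn_normalize()].
#' @return List: `table` (filtered, imputed, normalized feature table), `X`
#'   (model-ready centered log matrix of Study rows), `classes`, `quotients`,
#'   `report` (filter report data.frame).
#' @export
preprocess <- function(table, blank_ratio_threshold = 0.20,
                       max_qc_cv = 0.20, seed = 1,
                       pqn_reference = "qc") {
  s1 <- filter_missing_in_qc(table)
  s2 <- filter_blank_ratio(s1$table, blank_ratio_threshold)
  s3 <- filter_qc_cv(s2$table, max_qc_cv)
  imp <- impute_missing(s3$table, seed = seed)
  pqn <- pqn_normalize(imp, reference = pqn_reference)
  s4 <- filter_qc_cv(pqn$table, max_qc_cv)
  lc <- log_center(s4$table)
  report <- rbind(s1$report, s2$report, s3$report,
                  new_filter_report("qc_cv_post_pqn",
                                    s4$report$removed, s4$report$surviving))
  list(table = s4$table, X = lc$X, classes = lc$classes,
       quotients = pqn$quotients, report = report)
}
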