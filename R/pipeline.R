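#' Configuration for an end-to-end comparison
#'
#' Bundles every tunable of a two-group comparison run so the whole analysis
#' is a pure function of (input table, config, seed).
#'
#' @param comparison Character vector of the two class labels to compare
#'   (`NULL`: the two labels present in the table, sorted).
#' @param blank_ratio_threshold,max_qc_cv Preprocessing thresholds.
#' @param pca_variance_target Cumulative explained-variance target for the
#'   PCA component count (default 0.60).
#' @param alpha Outlier-test and significance level (default 0.05).
#' @param design_k Majority-class subset size; `NULL` uses
#'   `ceiling(1.2 * minority size)` capped at the majority size.
#' @param design_layers Onion layers (default 3).
#' @param n_sub Stability-selection sub-models (default 200).
#' @param n_perm Label permutations for the significance of the classifiers
#'   (default 1000).
#' @param cv_folds,cv_repeats Cross-validation scheme for component
#'   selection and the permutation statistic.
#' @param rf_ntree Random-forest ensemble size (default 500).
#' @param seed Global seed.
#' @return A `study_config` list.
#' @export
study_config <- function(comparison = NULL, blank_ratio_threshold = 0.20,
                         max_qc_cv = 0.20, pca_variance_target = 0.60,
                         alpha = 0.05, design_k = NULL, design_layers = 3,
                         n_sub = 200, n_perm = 1000, cv_folds = 5,
                         cv_repeats = 10, rf_ntree = 500, seed = 1) {
  stopifnot(blank_ratio_threshold > 0, blank_ratio_threshold < 1,
            max_qc_cv > 0, max_qc_cv < 1,
            pca_variance_target > 0, pca_variance_target <= 1,
            alpha > 0, alpha < 1, n_sub >= 1, n_perm >= 1,
            cv_folds >= 2, cv_repeats >= 1, rf_ntree >= 1)
  structure(as.list(environment()), class = "study_config")
}

#' Run a full two-group comparison
#'
#' Fixed stage order: preprocessing cascade; PCA with the component count
#' reaching the explained-variance target and a T2/Q outlier gate at
#' `alpha` (flagged samples are removed); when classes are unbalanced,
#' majority-class balancing by onion D-optimal design on the standardized
#' PCA scores plus Q; PLS2C stability selection and a random-forest
#' out-of-bag evaluation through the shared harness, each with a
#' label-permutation p; univariate fold-change / Mann-Whitney / Storey-q
#' screening of the balanced groups.
#'
#' @param table A [feature_table()] with class labels on its Study rows.
#' @param config A [study_config()].
#' @return A `comparison_report` list: `filter_report`, `outliers`,
#'   `pca_A`, `design` (selection or NULL), `samples_used`, `pls`
#'   (stability result), `pls_A`, `pls_perm_p`, `rf_mcc_oob`, `rf_perm_p`,
#'   `univariate` (volcano table), `relevant_features`, `config`.
#' @export
run_comparison <- function(table, config = study_config()) {
  stopifnot(inherits(table, "feature_table"),
            inherits(config, "study_config"))
  seeds <- child_seeds(config$seed, 8)

  pre <- preprocess(table,
                    blank_ratio_threshold = config$blank_ratio_threshold,
                    max_qc_cv = config$max_qc_cv, seed = seeds[1])
  cls <- pre$classes
  comparison <- config$comparison
  if (is.null(comparison)) comparison <- sort(unique(stats::na.omit(cls)))
  if (length(comparison) != 2) stop("comparison must name two classes")
  keep <- which(cls %in% comparison)
  if (length(keep) < 4) stop("too few labelled study samples")
  X <- pre$X[keep, , drop = FALSE]
  y <- cls[keep]

  # PCA outlier gate on the modelled study samples
  A_pca <- choose_components_by_variance(X, config$pca_variance_target,
                                         center = FALSE)
  A_pca <- min(A_pca, nrow(X) - 2L)
  pca <- fit_pca(X, A_pca, center = TRUE)
  outl <- outlier_test(pca, X, alpha = config$alpha)
  inliers <- !(outl$T2_out | outl$Q_out)
  X <- X[inliers, , drop = FALSE]
  y <- y[inliers]
  if (min(table(y)) < 2) stop("a class vanished after outlier removal")

  # onion balancing of the majority class
  design <- NULL
  tab_y <- table(y)
  if (tab_y[1] != tab_y[2]) {
    maj <- names(tab_y)[which.max(tab_y)]
    min_n <- min(tab_y)
    k <- if (is.null(config$design_k))
      min(ceiling(1.2 * min_n), max(tab_y)) else config$design_k
    maj_idx <- which(y == maj)
    A_bal <- min(A_pca, length(maj_idx) - 2L)
    pca_maj <- fit_pca(X[maj_idx, , drop = FALSE], max(A_bal, 1))
    cand <- onion_candidate_set(pca_maj, X[maj_idx, , drop = FALSE])
    design <- onion_select(cand, k,
                           n_layers = min(config$design_layers, k),
                           seed = seeds[2])
    use <- c(which(y != maj), maj_idx[design$selected])
    X <- X[use, , drop = FALSE]
    y <- y[use]
  }

  # multivariate models + permutation significance
  A_pls <- select_components(X, y, folds = config$cv_folds,
                             repeats = config$cv_repeats, seed = seeds[3])
  pls <- stability_selection(X, y, A = A_pls, n_sub = config$n_sub,
                             cv_folds = config$cv_folds, seed = seeds[4])
  pls_stat <- function(Xs, ys)
    as.numeric(repeated_cv_mcc(pls_learner(A_pls), Xs, ys,
                               folds = config$cv_folds,
                               repeats = config$cv_repeats,
                               seed = seeds[5]))
  pls_perm <- permutation_test(pls_stat, X, y, n_perm = config$n_perm,
                               seed = seeds[5])
  rf <- rf_oob_direct(X, y, ntree = config$rf_ntree, seed = seeds[6])
  rf_stat <- function(Xs, ys) rf_oob_direct(Xs, ys,
                                            ntree = config$rf_ntree,
                                            seed = seeds[7])
  rf_perm <- permutation_test(rf_stat, X, y, n_perm = config$n_perm,
                              seed = seeds[7])

  # univariate screen on normalized (un-logged) intensities
  norm_study <- pre$table$intensities[ft_study(pre$table), , drop = FALSE]
  rows_used <- rownames(X)
  volcano <- volcano_table(norm_study[rows_used, , drop = FALSE], y)

  structure(list(
    filter_report = pre$report,
    outliers = outl,
    pca_A = A_pca,
    design = design,
    samples_used = rows_used,
    pls = pls, pls_A = as.integer(A_pls),
    pls_perm_p = as.numeric(pls_perm),
    rf_mcc_oob = as.numeric(rf),
    rf_perm_p = as.numeric(rf_perm),
    univariate = volcano,
    relevant_features = pls$selected,
    config = config), class = "comparison_report")
}

# MCCoob of a single random forest from its internal out-of-bag votes
# (each tree's bootstrap leaves ~36% of samples out-of-bag).
rf_oob_direct <- function(X, y, ntree = 500, seed = 1) {
  y <- factor(as.character(y))
  fit <- withr::with_seed(seed,
    randomForest::randomForest(x = X, y = y, ntree = ntree))
  mcc_labels(as.character(y), as.character(fit$predicted))
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Comparison report\n")
  cat("  features surviving preprocessing:",
      utils::tail(x$filter_report$surviving, 1), "\n")
  cat("  outliers removed:", sum(x$outliers$T2_out | x$outliers$Q_out),
      "\n")
  if (!is.null(x$design))
    cat("  majority-class subset:", length(x$design$selected), "samples\n")
  cat(sprintf("  PLS2C: MCCoob = %.3f (perm p = %.4g), A = %d\n",
              x$pls$mcc_oob, x$pls_perm_p, x$pls_A))
  cat(sprintf("  RF:    MCCoob = %.3f (perm p = %.4g)\n",
              x$rf_mcc_oob, x$rf_perm_p))
  cat("  relevant features (frequency >= 0.5):",
      length(x$relevant_features), "\n")
  cat("  min q-value:", format(min(x$univariate$qvalue), digits = 3), "\n")
  invisible(x)
}

#' Write a comparison report to disk
#'
#' Plain-text outputs: `report.json` (scalar summaries and the relevant
#' feature list), `volcano.tsv`, `selection_frequency.tsv`,
#' `filter_report.tsv`.
#'
#' @param report A `comparison_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_comparison_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(
    surviving_features = utils::tail(report$filter_report$surviving, 1),
    outliers_removed = sum(report$outliers$T2_out | report$outliers$Q_out),
    pca_components = report$pca_A,
    pls_components = report$pls_A,
    pls_mcc_oob = as.numeric(report$pls$mcc_oob),
    pls_perm_p = report$pls_perm_p,
    rf_mcc_oob = report$rf_mcc_oob,
    rf_perm_p = report$rf_perm_p,
    n_relevant_features = length(report$relevant_features),
    relevant_features = report$relevant_features,
    min_qvalue = min(report$univariate$qvalue),
    samples_used = report$samples_used
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(report$univariate, file.path(dir, "volcano.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(feature = names(report$pls$frequency),
               frequency = as.numeric(report$pls$frequency)),
    file.path(dir, "selection_frequency.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$filter_report,
                     file.path(dir, "filter_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
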