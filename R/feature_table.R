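#' Construct a feature table
#'
#' The central container of the package: a samples-by-features intensity
#' matrix from an untargeted LC-MS run together with the role of every
#' injection (study sample, pooled quality control, or blank) and, for study
#' samples, an optional class label. Missing intensities are stored as `NA`.
#'
#' @param intensities Numeric matrix, samples in rows, features in columns.
#'   Non-negative where observed; `NA` marks missing values. Row names are
#'   sample IDs (generated if absent); column names are feature IDs in
#'   `Rt_mass` style (e.g. `"1.23_180.0634"`).
#' @param roles Character vector, one of `"Study"`, `"QC"`, `"Blank"` per row.
#' @param classes Optional character/factor vector of class labels for Study
#'   rows (`NA` for QC/Blank rows).
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(intensities, roles, classes = NULL) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  n <- nrow(intensities)
  roles <- as.character(roles)
  if (length(roles) != n)
    stop("'roles' must have one entry per row of 'intensities'")
  bad <- setdiff(unique(roles), c("Study", "QC", "Blank"))
  if (length(bad))
    stop("unknown sample role(s): ", paste(bad, collapse = ", "))
  if (any(intensities < 0, na.rm = TRUE))
    stop("intensities must be non-negative where observed")
  if (is.null(rownames(intensities)))
    rownames(intensities) <- sprintf("S%03d", seq_len(n))
  if (is.null(colnames(intensities)))
    colnames(intensities) <- sprintf("F%04d", seq_len(ncol(intensities)))
  if (anyDuplicated(colnames(intensities)))
    stop("feature IDs must be unique")
  if (is.null(classes)) classes <- rep(NA_character_, n)
  classes <- as.character(classes)
  if (length(classes) != n)
    stop("'classes' must have one entry per row")
  structure(
    list(intensities = intensities, roles = roles, classes = classes),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$intensities), "samples x",
      ncol(x$intensities), "features\n")
  cat("  roles:", paste(sprintf("%s=%d", names(table(x$roles)),
                                table(x$roles)), collapse = ", "), "\n")
  cl <- table(x$classes[x$roles == "Study"], useNA = "no")
  if (length(cl))
    cat("  classes:", paste(sprintf("%s=%d", names(cl), cl),
                            collapse = ", "), "\n")
  nm <- sum(is.na(x$intensities))
  cat("  missing values:", nm,
      sprintf("(%.1f%%)\n", 100 * nm / length(x$intensities)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

# Internal row/column subsetting that keeps the object consistent.
ft_subset <- function(table, rows = NULL, cols = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(table$intensities))
  if (is.null(cols)) cols <- seq_len(ncol(table$intensities))
  feature_table(table$intensities[rows, cols, drop = FALSE],
                table$roles[rows], table$classes[rows])
}

ft_study <- function(table) which(table$roles == "Study")
ft_qc <- function(table) which(table$roles == "QC")
ft_blank <- function(table) which(table$roles == "Blank")

#' Write a feature table as TSV
#'
#' Plain-text dialect used throughout the package: first column `sample_id`,
#' second `role` (Study/QC/Blank), third `class` (label or NA), remaining
#' columns the features. Missing intensities are written as `NA`.
#'
#' @param table A `feature_table`.
#' @param path Output file path.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(sample_id = rownames(table$intensities),
                   role = table$roles,
                   class = table$classes,
                   table$intensities,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table from TSV
#'
#' @param path File written by [write_feature_table()] (or any TSV in the
#'   same dialect).
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "role", "class")
  if (!all(need %in% names(df)[1:3]))
    stop("expected columns sample_id, role, class at the start of ", path)
  X <- as.matrix(df[, -(1:3), drop = FALSE])
  rownames(X) <- df$sample_id
  feature_table(X, df$role, as.character(df$class))
}
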