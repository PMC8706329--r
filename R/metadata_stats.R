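#' @title Cohort-metadata screening
#' @description Per-factor association tests between cohort metadata and a
#'   binary outcome: Fisher's exact test for categorical factors and a
#'   Shapiro-Wilk-gated choice between the t-test and the Mann-Whitney test
#'   for continuous ones.
#' @name metadata_stats
NULL

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Point-probability rule: the p-value sums the hypergeometric probabilities
#' of all tables with the observed margins whose probability does not exceed
#' that of the observed table (the rule behind `stats::fisher.test`, which
#' performs the computation).
#'
#' @param a,b,c,d Cell counts (rows = groups, columns = factor
#'   present/absent), or a 2x2 matrix as `a`.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL) {
  tab <- if (is.matrix(a)) a else matrix(c(a, c, b, d), 2)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("cell counts must be non-negative integers")
  if (sum(tab) == 0) stop("all-zero table")
  stats::fisher.test(tab)$p.value
}

#' Normality-gated two-group test for a continuous variable
#'
#' Shapiro-Wilk on each group; when both p-values exceed `normal_p` the
#' groups are treated as normal and a t-test is run (Welch by default),
#' otherwise a two-sided Mann-Whitney test. The dispatch is a pure function
#' of the two Shapiro-Wilk p-values.
#'
#' @param x,y The two groups (n >= 3 each for the normality gate).
#' @param normal_p Normality threshold on the Shapiro-Wilk p (default 0.10).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return List: `test` ("t-test" or "mann-whitney"), `p`, `shapiro_p`
#'   (length 2).
#' @export
continuous_test <- function(x, y, normal_p = 0.10, var_equal = FALSE) {
  if (length(x) < 3 || length(y) < 3)
    stop("need >= 3 observations per group for the normality gate")
  sw <- c(stats::shapiro.test(x)$p.value, stats::shapiro.test(y)$p.value)
  if (all(sw > normal_p)) {
    list(test = "t-test",
         p = stats::t.test(x, y, var.equal = var_equal)$p.value,
         shapiro_p = sw)
  } else {
    list(test = "mann-whitney", p = mann_whitney(x, y)$p, shapiro_p = sw)
  }
}

#' Screen cohort metadata against a binary outcome
#'
#' One test per factor: binary/categorical factors get Fisher's exact test
#' on the 2x2 outcome-by-factor table (with per-group counts and
#' percentages reported), continuous factors the gated test of
#' [continuous_test()]. Factors with p below `alpha` are flagged.
#'
#' @param metadata Data.frame of factors.
#' @param outcome Binary vector (0/1 or two-level), one entry per row.
#' @param types Named character vector typing each factor as
#'   `"categorical"` or `"continuous"`; inferred (two unique values =
#'   categorical) for factors not named.
#' @param alpha Flagging level (default 0.05).
#' @return Data.frame: `factor`, `type`, `test`, `group1_summary`,
#'   `group0_summary`, `p`, `significant`.
#' @export
screen_metadata <- function(metadata, outcome, types = NULL, alpha = 0.05) {
  out_lv <- sort(unique(as.character(outcome)), decreasing = TRUE)
  if (length(out_lv) != 2) stop("outcome must be binary")
  g1 <- as.character(outcome) == out_lv[1]
  rows <- lapply(names(metadata), function(f) {
    v <- metadata[[f]]
    ty <- if (!is.null(types) && f %in% names(types)) types[[f]]
      else if (is.numeric(v) && length(unique(v[!is.na(v)])) > 2)
        "continuous" else "categorical"
    if (!ty %in% c("categorical", "continuous"))
      stop("untyped factor: ", f)
    if (ty == "categorical") {
      vv <- as.character(v)
      lv <- sort(unique(vv[!is.na(vv)]), decreasing = TRUE)
      if (length(lv) != 2)
        stop("categorical factor '", f, "' must be binary")
      a <- sum(g1 & vv == lv[1], na.rm = TRUE)
      b <- sum(g1 & vv == lv[2], na.rm = TRUE)
      c_ <- sum(!g1 & vv == lv[1], na.rm = TRUE)
      d <- sum(!g1 & vv == lv[2], na.rm = TRUE)
      p <- fisher_exact(a, b, c_, d)
      data.frame(factor = f, type = ty, test = "fisher",
                 group1_summary = sprintf("%d (%.0f%%)", a,
                                          100 * a / max(a + b, 1)),
                 group0_summary = sprintf("%d (%.0f%%)", c_,
                                          100 * c_ / max(c_ + d, 1)),
                 p = p, stringsAsFactors = FALSE)
    } else {
      ct <- continuous_test(v[g1], v[!g1])
      data.frame(factor = f, type = ty, test = ct$test,
                 group1_summary = sprintf("%.3g (%.3g)", mean(v[g1]),
                                          stats::sd(v[g1])),
                 group0_summary = sprintf("%.3g (%.3g)", mean(v[!g1]),
                                          stats::sd(v[!g1])),
                 p = ct$p, stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, rows)
  res$significant <- res$p < alpha
  res
}
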