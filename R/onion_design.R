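#' @title Onion D-optimal subset selection
#' @description Class balancing for unbalanced case-control comparisons:
#'   instead of random down-sampling of the majority class, a representative
#'   subset is chosen by layered (onion) D-optimal design on the samples'
#'   PCA scores augmented with the Q distance-to-model coordinate.
#'   Candidates are split into concentric shells by distance from the
#'   centroid, the requested subset size is apportioned across shells
#'   proportionally to shell size, and a D-optimal selection (greedy Fedorov
#'   exchange with random restarts) is run within each shell, so the chosen
#'   samples span the whole cloud rather than just its dense core or its rim.
#' @name onion_design
NULL

#' Assign candidates to concentric layers
#'
#' Layers are shells bounded by quantiles of the Euclidean distance from the
#' candidate centroid; layer sizes differ by at most one candidate from the
#' equal-quantile targets.
#'
#' @param candidates Numeric matrix, candidates by coordinates.
#' @param n_layers Number of shells (>= 1).
#' @return Integer vector of layer indices (1 = innermost).
#' @export
assign_layers <- function(candidates, n_layers) {
  candidates <- as.matrix(candidates)
  n <- nrow(candidates)
  if (n_layers < 1) stop("n_layers must be >= 1")
  if (n < n_layers) stop("need at least one candidate per layer")
  if (n_layers == 1) return(rep(1L, n))
  d <- sqrt(rowSums(sweep(candidates, 2, colMeans(candidates))^2))
  if (max(d) == 0)
    stop("all candidates identical; layers are undefined")
  # rank-based split: ties broken by original order, sizes differ by <= 1
  ord <- rank(d, ties.method = "first")
  as.integer(ceiling(ord * n_layers / n))
}

design_logdet <- function(M, idx) {
  Xs <- M[idx, , drop = FALSE]
  determinant(crossprod(Xs), logarithm = TRUE)$modulus[1]
}

#' D-optimal row selection by Fedorov exchange
#'
#' Maximizes `det(X'X)` of the selected rows of the design matrix
#' `[1 | coordinates]` by greedy point exchange from random non-singular
#' starts; the best of `n_starts` restarts is returned. The result is a
#' local optimum; on small instances it is routinely the global one.
#'
#' @param candidates Numeric matrix, candidates by coordinates.
#' @param k Subset size; must be at least `ncol(candidates) + 1` (otherwise
#'   the information matrix is singular for every subset).
#' @param n_starts Number of random restarts (default 20).
#' @param seed RNG seed.
#' @return Integer vector of `k` selected row indices (sorted), with
#'   attribute `logdet` (achieved log-determinant).
#' @export
d_optimal_select <- function(candidates, k, n_starts = 20, seed = 1) {
  candidates <- as.matrix(candidates)
  n <- nrow(candidates)
  M <- cbind(1, candidates)
  p <- ncol(M)
  if (k > n) stop("k exceeds the number of candidates")
  if (k < p)
    stop("k must be >= ", p, " (columns of the design matrix), got ", k)
  if (k == n) {
    sel <- seq_len(n)
    attr(sel, "logdet") <- design_logdet(M, sel)
    return(sel)
  }
  seeds <- child_seeds(seed, n_starts)
  best <- NULL; best_ld <- -Inf
  for (s in seq_len(n_starts)) {
    sel <- withr::with_seed(seeds[s], sample.int(n, k))
    ld <- design_logdet(M, sel)
    tries <- 0
    while (!is.finite(ld) && tries < 50) {  # resample a singular start
      tries <- tries + 1
      sel <- withr::with_seed(seeds[s] %% 2147483562L + tries,
                              sample.int(n, k))
      ld <- design_logdet(M, sel)
    }
    if (!is.finite(ld)) next
    repeat {
      improved <- FALSE
      for (i in seq_len(k)) {
        outside <- setdiff(seq_len(n), sel)
        cand_ld <- vapply(outside, function(j) {
          trial <- sel; trial[i] <- j
          design_logdet(M, trial)
        }, numeric(1))
        jbest <- which.max(cand_ld)
        if (length(jbest) && cand_ld[jbest] > ld + 1e-10) {
          sel[i] <- outside[jbest]
          ld <- cand_ld[jbest]
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    if (ld > best_ld) { best_ld <- ld; best <- sel }
  }
  if (is.null(best))
    stop("could not find a non-singular starting design")
  out <- sort(best)
  attr(out, "logdet") <- best_ld
  out
}

#' Onion D-optimal selection of a representative subset
#'
#' Splits the candidates into `n_layers` concentric shells, apportions `k`
#' across shells proportionally to shell sizes (largest-remainder rounding,
#' every shell guaranteed at least one point when `k >= n_layers`), and runs
#' a D-optimal selection within each shell.
#'
#' @param candidates Numeric matrix, candidates by coordinates (typically
#'   standardized PCA scores plus the Q coordinate, see
#'   [onion_candidate_set()]).
#' @param k Total subset size (`k >= n_layers`).
#' @param n_layers Number of shells (default 3).
#' @param n_starts,seed Passed to [d_optimal_select()].
#' @return A `design_selection` list: `selected` (sorted candidate indices),
#'   `layers` (layer index per candidate), `layer_logdet` (achieved log-det
#'   per layer), `k`, `n_layers`.
#' @export
onion_select <- function(candidates, k, n_layers = 3, n_starts = 20,
                         seed = 1) {
  candidates <- as.matrix(candidates)
  n <- nrow(candidates)
  if (k < n_layers) stop("k must be >= n_layers")
  if (k > n) stop("k exceeds the number of candidates")
  layers <- assign_layers(candidates, n_layers)
  sizes <- tabulate(layers, n_layers)
  # largest-remainder apportionment, at least 1 per non-empty layer,
  # capped at layer size
  quota <- k * sizes / n
  alloc <- pmax(floor(quota), ifelse(sizes > 0, 1L, 0L))
  alloc <- pmin(alloc, sizes)
  rem <- quota - floor(quota)
  while (sum(alloc) < k) {
    open <- which(alloc < sizes)
    if (!length(open)) stop("infeasible apportionment")
    i <- open[which.max(rem[open])]
    alloc[i] <- alloc[i] + 1L
    rem[i] <- -1
  }
  while (sum(alloc) > k) {
    shrink <- which(alloc > 1L)
    if (!length(shrink)) stop("infeasible apportionment")
    i <- shrink[which.min(rem[shrink])]
    alloc[i] <- alloc[i] - 1L
  }
  seeds <- child_seeds(seed, n_layers)
  selected <- integer(0)
  layer_logdet <- rep(NA_real_, n_layers)
  p <- ncol(candidates) + 1
  for (l in seq_len(n_layers)) {
    if (alloc[l] == 0) next
    idx <- which(layers == l)
    if (alloc[l] == length(idx)) {
      pick <- seq_along(idx)
      layer_logdet[l] <- if (alloc[l] >= p)
        design_logdet(cbind(1, candidates[idx, , drop = FALSE]), pick)
      else NA_real_
    } else if (alloc[l] >= p) {
      pick <- d_optimal_select(candidates[idx, , drop = FALSE], alloc[l],
                               n_starts = n_starts, seed = seeds[l])
      layer_logdet[l] <- attr(pick, "logdet")
    } else {
      # too few points for a non-singular information matrix: fall back to
      # a max-spread choice (greedy farthest-point from the layer centroid)
      pick <- max_spread_select(candidates[idx, , drop = FALSE], alloc[l])
    }
    selected <- c(selected, idx[pick])
  }
  structure(list(selected = sort(selected), layers = layers,
                 layer_logdet = layer_logdet, k = k, n_layers = n_layers),
            class = "design_selection")
}

# Greedy farthest-point selection used when a layer's allocation is smaller
# than the design-matrix column count.
max_spread_select <- function(X, k) {
  X <- as.matrix(X)
  d0 <- sqrt(rowSums(sweep(X, 2, colMeans(X))^2))
  pick <- which.max(d0)
  while (length(pick) < k) {
    dmin <- apply(X, 1, function(r)
      min(sqrt(colSums((t(X[pick, , drop = FALSE]) - r)^2))))
    dmin[pick] <- -Inf
    pick <- c(pick, which.max(dmin))
  }
  sort(pick)
}

#' Build the onion candidate set from a PCA model
#'
#' Describes each candidate sample by its standardized PCA scores plus its
#' standardized Q (distance-to-model) coordinate, the joint geometry on
#' which layers and D-optimality are computed. Standardization to unit
#' variance keeps any one coordinate (Q in particular) from dominating the
#' distances.
#'
#' @param model A `pca_model` fitted on the data the candidates live in.
#' @param X The candidate rows (on the model's feature set).
#' @return Numeric matrix, candidates by (A + 1) coordinates.
#' @export
onion_candidate_set <- function(model, X) {
  pr <- project_pca(model, X)
  coords <- cbind(pr$scores, Q = rowSums(pr$residuals^2))
  colnames(coords) <- c(paste0("PC", seq_len(model$A)), "Q")
  sds <- apply(coords, 2, stats::sd)
  sds[sds == 0] <- 1
  sweep(coords, 2, sds, "/")
}
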