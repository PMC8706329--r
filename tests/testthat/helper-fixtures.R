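# Small programmatic fixtures shared across test files.

# A tiny hand-built feature table: n_study study rows (two classes),
# n_qc QCs, n_blank blanks, p features of constant intensity `base`.
toy_table <- function(n_study = 6, n_qc = 4, n_blank = 3, p = 5,
                      base = 100) {
  n <- n_study + n_qc + n_blank
  X <- matrix(base, n, p,
              dimnames = list(NULL, sprintf("1.0%d_100.00%d", 1:p, 1:p)))
  roles <- rep(c("Study", "QC", "Blank"), c(n_study, n_qc, n_blank))
  classes <- c(rep(c("A", "B"), length.out = n_study),
               rep(NA, n_qc + n_blank))
  feature_table(X, roles, classes)
}

# Two well-separated Gaussian clusters in p dimensions.
separable_data <- function(n_per = 10, p = 4, gap = 10, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per * p), n_per),
               matrix(rnorm(n_per * p, mean = gap), n_per))
    list(X = X, y = rep(c("A", "B"), each = n_per))
  })
}

# Exhaustive two-sided Fisher p by hypergeometric enumeration: sums the
# probabilities of all tables with the observed margins whose point
# probability is at most that of the observed table.
fisher_oracle <- function(a, b, c, d, slack = 1e-7) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + slack)])
}

# Two-column indicator coding of a binary label vector.
dummy_code_test <- function(y) {
  lv <- sort(unique(y))
  Y <- cbind(as.numeric(y == lv[1]), as.numeric(y == lv[2]))
  colnames(Y) <- lv
  Y
}

# A deterministic 1-nearest-neighbour learner used to probe the harness.
nn_learner <- function() {
  list(
    name = "1NN",
    fit = function(X, y) list(X = X, y = y),
    predict = function(model, X) {
      apply(X, 1, function(r) {
        d <- rowSums(sweep(model$X, 2, r)^2)
        model$y[which.min(d)]
      })
    }
  )
}

# A learner that ignores the data and predicts the majority training class.
majority_learner <- function() {
  list(
    name = "majority",
    fit = function(X, y) names(which.max(table(y))),
    predict = function(model, X) rep(model, nrow(X))
  )
}
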