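test_that("PLS2 reproduces exact and least-squares limits", {
  # with mutually orthogonal centered columns the first weight vector is
  # the informative column itself, so A = 1 gives an exact training fit
  Xo <- qr.Q(qr(cbind(1, withr::with_seed(1,
                                          matrix(rnorm(60), 20, 3)))))[, 2:4]
  Y <- Xo[, 2, drop = FALSE] * 2 + 5
  m1 <- fit_pls2(Xo, Y, A = 1)
  expect_lt(max(abs(predict(m1, Xo) - Y)), 1e-8)
  # full-rank PLS equals OLS
  X <- withr::with_seed(1, matrix(rnorm(60), 20, 3))
  Y2 <- withr::with_seed(2, matrix(rnorm(40), 20, 2))
  m2 <- fit_pls2(X, Y2, A = 3)
  ols <- lm.fit(cbind(1, X), Y2)
  expect_lt(max(abs(predict(m2, X) - cbind(1, X) %*% ols$coefficients)),
            1e-6)
  # score orthogonality
  G <- crossprod(m2$Tmat)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  expect_error(fit_pls2(matrix(0, 5, 3), matrix(rnorm(5)), 1), "variance")
})

test_that("NIPALS agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  X <- withr::with_seed(3, matrix(rnorm(30 * 8), 30))
  y <- rep(c("A", "B"), 15)
  m <- fit_pls2(X, y, A = 2)
  ref <- mixOmics::pls(X, dummy_code_test(y), ncomp = 2, scale = FALSE,
                       mode = "regression")
  # scores agree up to per-component sign
  for (a in 1:2) {
    r <- abs(cor(m$Tmat[, a], ref$variates$X[, a]))
    expect_gt(r, 1 - 1e-6)
  }
})

test_that("classification follows the larger-dummy-prediction rule", {
  sep <- separable_data(n_per = 8, gap = 8, seed = 4)
  m <- fit_pls2(sep$X, sep$y, A = 2)
  expect_equal(classify(m, sep$X), sep$y)
  expect_equal(mcc_labels(sep$y, classify(m, sep$X)), 1.0)
  # tie resolves to the lower label index
  mt <- m
  mt$B[] <- 0
  mt$y_means[] <- 0.5
  expect_equal(unique(classify(mt, sep$X)), "A")
  expect_error(predict(m, sep$X[, 1:2]), "mismatch")
})

test_that("VIP satisfies its normalization and symmetry identities", {
  X <- withr::with_seed(5, matrix(rnorm(40 * 12), 40))
  y <- rep(c("A", "B"), 20)
  for (A in 1:3) {
    v <- vip(fit_pls2(X, y, A))
    expect_equal(sum(v^2), 12, tolerance = 1e-8)
  }
  # two identical informative features get identical VIPs
  z <- rep(c(-1, 1), 20)
  X2 <- cbind(z + 0.3 * rnorm(40), 0, matrix(rnorm(40 * 4), 40))
  X2[, 2] <- X2[, 1]
  v2 <- vip(fit_pls2(X2, ifelse(z > 0, "A", "B"), 1))
  expect_equal(v2[1], v2[2], tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("VIP ranks a planted informative feature first", {
  hits <- vapply(1:30, function(s) {
    withr::with_seed(s, {
      z <- rep(c(-1, 1), each = 15)
      X <- cbind(z + rnorm(30, sd = 0.5), matrix(rnorm(30 * 50), 30))
      which.max(vip(fit_pls2(X, ifelse(z > 0, "A", "B"), 1))) == 1
    })
  }, logical(1))
  expect_gte(sum(hits), 28)
})

test_that("component selection stops at the first MCCcv maximum", {
  # strongly separable along 1 latent direction: profile flat-or-decreasing
  # after its first max, so the rule returns a small A
  sep <- separable_data(n_per = 15, p = 6, gap = 6, seed = 6)
  A <- select_components(sep$X, sep$y, A_max = 4, repeats = 5, seed = 1)
  prof <- attr(A, "mcc_profile")
  if (A < 4) expect_gte(prof[A], prof[A + 1])
  if (A > 1) expect_true(all(diff(prof[seq_len(A)]) > 0))
  expect_equal(as.integer(select_components(sep$X, sep$y, A_max = 1,
                                            repeats = 2, seed = 1)), 1L)
})

test_that("a planted two-latent-variable signal selects two components", {
  picks <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      n <- 40
      t1 <- rnorm(n); t2 <- rnorm(n)
      y <- ifelse(t1 + t2^2 - 1 > 0, "A", "B")
      L <- matrix(rnorm(2 * 20), 2)
      X <- cbind(t1, t2) %*% L + matrix(rnorm(n * 20, sd = 0.3), n)
      as.integer(select_components(X, y, A_max = 4, repeats = 5, seed = s))
    })
  }, integer(1))
  expect_equal(as.integer(names(which.max(table(picks)))), 2L)
})

test_that("stability selection recovers planted features on a seeded cohort", {
  sim <- generate_cohort(sim_config(seed = 1))
  pre <- preprocess(sim$table, seed = 1)
  ss <- stability_selection(pre$X, pre$classes, A = 2, n_sub = 50, seed = 1)
  disc <- colnames(sim$table$intensities)[sim$truth$discriminant_indices]
  planted <- ss$frequency[intersect(disc, colnames(pre$X))]
  noise <- ss$frequency[setdiff(colnames(pre$X), disc)]
  expect_gt(median(planted), 0.6)
  expect_gt(median(planted), max(noise))
  expect_gt(ss$mcc_oob, 0.5)
  # determinism
  ss2 <- stability_selection(pre$X, pre$classes, A = 2, n_sub = 50,
                             seed = 1)
  expect_identical(ss$frequency, ss2$frequency)
  expect_identical(ss$oob_pred, ss2$oob_pred)
})

test_that("planted cohorts dominate their null twins in MCCoob", {
  wins <- vapply(1:5, function(s) {
    sim <- generate_cohort(sim_config(n_per_group = c(20, 20),
                                      n_features = 200, seed = s))
    pre <- preprocess(sim$table, seed = s)
    ss <- stability_selection(pre$X, pre$classes, A = 2, n_sub = 30,
                              seed = s)
    simn <- generate_cohort(sim_config(n_per_group = c(20, 20),
                                       n_features = 200, effect_size = 0,
                                       n_discriminant = 0, seed = s))
    pren <- preprocess(simn$table, seed = s)
    ssn <- stability_selection(pren$X, pren$classes, A = 2, n_sub = 30,
                               seed = s)
    ss$mcc_oob > ssn$mcc_oob
  }, logical(1))
  expect_true(all(wins))
})

test_that("the permutation test honors the plus-one convention", {
  # indicator statistic: only a permutation reproducing the observed
  # labelling ties the observed value; with 20 balanced samples the
  # chance of that in 1000 draws is ~0.5%, and none occurs at this seed
  y0 <- rep(c("A", "B"), each = 10)
  stat <- function(X, y) as.numeric(all(y == y0))
  p <- permutation_test(stat, matrix(0, 20, 1), y0, n_perm = 1000,
                        seed = 1)
  expect_equal(as.numeric(p), 1 / 1001, tolerance = 1e-12)
  # the reported p always equals (1 + #{perm >= observed}) / (n_perm + 1)
  expect_equal(as.numeric(p),
               (1 + sum(attr(p, "perm_stats") >= attr(p, "observed"))) /
                 1001)
  # a constant statistic ties everywhere -> p = 1
  pc <- permutation_test(function(X, y) 0, matrix(0, 20, 1), y0,
                         n_perm = 99, seed = 1)
  expect_equal(as.numeric(pc), 1)
  expect_error(permutation_test(stat, matrix(0, 20, 1), y0, n_perm = 0),
               "n_perm")
})
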