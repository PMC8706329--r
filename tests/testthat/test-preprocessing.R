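test_that("the QC-missingness filter drops exactly the incomplete-QC features", {
  tab <- toy_table(n_study = 4, n_qc = 5, p = 10)
  # features 1-3 get a single missing QC value; feature 4 is heavily
  # missing in Study rows but complete in QCs
  qc_rows <- which(tab$roles == "QC")
  for (j in 1:3) tab$intensities[qc_rows[j], j] <- NA
  tab$intensities[1:2, 4] <- NA
  out <- filter_missing_in_qc(tab)
  expect_equal(ncol(out$table$intensities), 7)
  expect_equal(out$report$removed, 3)
  expect_true("1.04_100.004" %in% colnames(out$table$intensities))
  # study missingness untouched on survivors
  expect_true(anyNA(out$table$intensities[1:2, "1.04_100.004"]))
  no_qc <- toy_table(n_qc = 0)
  no_qc$roles[no_qc$roles == "QC"] <- "Study"
  expect_error(filter_missing_in_qc(
    feature_table(tab$intensities, rep("Study", nrow(tab$intensities)))),
    "QC")
})

test_that("the blank-ratio filter applies the 95th/5th percentile rule", {
  tab <- toy_table(n_study = 4, n_qc = 5, n_blank = 4, p = 3)
  qc <- which(tab$roles == "QC"); bl <- which(tab$roles == "Blank")
  tab$intensities[qc, ] <- 100             # P5(QC) = 100
  tab$intensities[bl, 1] <- 25             # ratio 0.25 -> removed
  tab$intensities[bl, 2] <- 0              # absent in blanks -> retained
  tab$intensities[bl, 3] <- c(10, 10, 10, 30)
  out <- filter_blank_ratio(tab, threshold = 0.20)
  kept <- colnames(out$table$intensities)
  expect_false("1.01_100.001" %in% kept)
  expect_true("1.02_100.002" %in% kept)
  # oracle: interpolated 95th percentile of [10,10,10,30]
  p95 <- unname(quantile(c(10, 10, 10, 30), 0.95, type = 7))
  expect_identical("1.03_100.003" %in% kept, p95 / 100 <= 0.20)
  expect_error(filter_blank_ratio(toy_table(n_blank = 0)), "Blank")
})

test_that("the QC CV filter uses the sample SD and is idempotent", {
  tab <- toy_table(n_study = 4, n_qc = 2, p = 2)
  qc <- which(tab$roles == "QC")
  tab$intensities[qc, 1] <- c(100, 150)    # CV = sd/mean ~ 0.283
  tab$intensities[qc, 2] <- c(100, 100)    # CV = 0
  expect_equal(sd(c(100, 150)) / 125, 0.2828427, tolerance = 1e-6)
  out <- filter_qc_cv(tab, max_cv = 0.20)
  expect_equal(colnames(out$table$intensities), "1.02_100.002")
  again <- filter_qc_cv(out$table, max_cv = 0.20)
  expect_equal(again$table$intensities, out$table$intensities)
  expect_equal(again$report$removed, 0)
})

test_that("imputation draws strictly inside (0, feature minimum)", {
  tab <- toy_table(n_study = 6, p = 4)
  tab$intensities[, 2] <- 50 + 10 * seq_len(nrow(tab$intensities))
  tab$intensities[1:3, 2] <- NA
  imp <- impute_missing(tab, seed = 11)
  filled <- imp$intensities[1:3, 2]
  expect_true(all(filled > 0 & filled < 90))  # min observed = 90
  expect_identical(imp$intensities[-(1:3), ], tab$intensities[-(1:3), ])
  expect_identical(impute_missing(tab, seed = 11)$intensities,
                   imp$intensities)
  expect_false(identical(impute_missing(tab, seed = 12)$intensities,
                         imp$intensities))
  # no missing values: identity
  full <- toy_table()
  expect_identical(impute_missing(full, seed = 1), full)
  # entirely-missing feature: error
  tab$intensities[, 3] <- NA
  expect_error(impute_missing(tab, seed = 1), "entirely missing")
})

test_that("PQN removes exact dilution and recovers simulated factors", {
  tab <- toy_table(n_study = 4, n_qc = 4, n_blank = 3, p = 6)
  st <- which(tab$roles == "Study")
  base <- matrix(rep(c(100, 200, 300, 400, 500, 600), each = 4), 4)
  tab$intensities[st, ] <- base * c(1, 3, 0.5, 2)
  qc <- which(tab$roles == "QC")
  tab$intensities[qc, ] <- matrix(rep(c(100, 200, 300, 400, 500, 600),
                                      each = 4), 4)
  out <- pqn_normalize(tab)
  expect_equal(unname(out$quotients[st]), c(1, 3, 0.5, 2))
  expect_equal(out$table$intensities[st, ],
               matrix(rep(c(100, 200, 300, 400, 500, 600), each = 4), 4),
               ignore_attr = TRUE)

  sim <- generate_cohort(sim_config(n_per_group = c(20, 20),
                                    n_features = 300, seed = 21))
  imp <- impute_missing(sim$table, seed = 21)
  pq <- pqn_normalize(imp)
  st <- imp$roles == "Study"
  expect_gt(cor(pq$quotients[st], sim$truth$dilution_factors), 0.99)
})

test_that("PQN restores a dilution-only perturbation within 1 percent", {
  sim <- generate_cohort(sim_config(n_per_group = c(15, 15),
                                    n_features = 200, missing_rate = 0,
                                    dilution_range = c(1, 1), seed = 31))
  tab <- sim$table
  st <- which(tab$roles == "Study")
  dil <- withr::with_seed(99, runif(length(st), 0.5, 2))
  pert <- tab
  pert$intensities[st, ] <- pert$intensities[st, ] * dil
  n0 <- pqn_normalize(tab)$table$intensities
  n1 <- pqn_normalize(pert)$table$intensities
  rel <- abs(n1[st, ] - n0[st, ]) / n0[st, ]
  expect_lt(max(rel), 0.01)
})

test_that("log_center yields zero column means and guards its domain", {
  tab <- toy_table(p = 3)
  tab$intensities[] <- exp(1)
  lc <- log_center(tab)
  expect_equal(unname(lc$X), matrix(0, 6, 3))
  sim <- generate_cohort(sim_config(n_per_group = c(8, 8),
                                    n_features = 40, seed = 2))
  imp <- impute_missing(sim$table, seed = 2)
  lc2 <- log_center(imp)
  expect_lt(max(abs(colMeans(lc2$X))), 1e-10)
  expect_equal(dim(lc2$X), c(16, 40))
  bad <- toy_table()
  bad$intensities[1, 1] <- 0
  expect_error(log_center(bad), "positive")
})

test_that("the cascade keeps its fixed order and telescoping counts", {
  sim <- generate_cohort(sim_config(n_per_group = c(15, 15),
                                    n_features = 250, blank_level = 0.5,
                                    blank_contaminated_frac = 0.15,
                                    seed = 13))
  pre <- preprocess(sim$table, seed = 13)
  rep_ <- pre$report
  expect_equal(rep_$rule, c("missing_in_qc", "blank_ratio", "qc_cv",
                            "qc_cv_post_pqn"))
  p0 <- ncol(sim$table$intensities)
  expect_equal(rep_$surviving[1], p0 - rep_$removed[1])
  for (i in 2:4)
    expect_equal(rep_$surviving[i], rep_$surviving[i - 1] - rep_$removed[i])
  expect_equal(ncol(pre$table$intensities), tail(rep_$surviving, 1))
  expect_gt(rep_$removed[2], 0)  # heavy contamination must trip the filter
  # filters only drop columns: surviving raw intensities are unchanged
  s1 <- filter_missing_in_qc(sim$table)$table
  kept <- colnames(s1$intensities)
  expect_identical(s1$intensities, sim$table$intensities[, kept])
})
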