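test_that("cohort generation is bit-identical under a fixed seed", {
  cfg <- sim_config(n_per_group = c(10, 10), n_features = 60, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c_ <- generate_cohort(sim_config(n_per_group = c(10, 10),
                                   n_features = 60, seed = 43))
  expect_false(identical(a$table$intensities, c_$table$intensities))
})

test_that("realized QC CV tracks the configured target", {
  sim <- generate_cohort(sim_config(n_features = 500, qc_count = 10,
                                    qc_cv_target = 0.10, seed = 1))
  qc <- sim$table$intensities[sim$table$roles == "QC", ]
  cv <- apply(qc, 2, function(v) sd(v, na.rm = TRUE) / mean(v, na.rm = TRUE))
  expect_gt(median(cv, na.rm = TRUE), 0.07)
  expect_lt(median(cv, na.rm = TRUE), 0.13)
})

test_that("planted features realize the configured standardized shift", {
  # dilution fixed at 1 so the log-scale SD is the biological SD alone
  cfg <- sim_config(n_per_group = c(60, 60), n_features = 200,
                    n_discriminant = 20, effect_size = 2,
                    dilution_range = c(1, 1), missing_rate = 0, seed = 7)
  sim <- generate_cohort(cfg)
  st <- sim$table$roles == "Study"
  L <- log(sim$table$intensities[st, ])
  cl <- sim$table$classes[st]
  d <- vapply(sim$truth$discriminant_indices, function(j) {
    sp <- sqrt((var(L[cl == "A", j]) + var(L[cl == "B", j])) / 2)
    (mean(L[cl == "B", j]) - mean(L[cl == "A", j])) / sp
  }, numeric(1))
  expect_lt(abs(mean(d) - 2), 0.4)  # within 20% of the planted effect
  sim2 <- generate_cohort(sim_config(n_per_group = c(10, 10), seed = 2))
  expect_true(all(sim2$truth$dilution_factors >= 0.5 &
                    sim2$truth$dilution_factors <= 2))
})

test_that("missingness concentrates below the lowest intensity decile", {
  sim <- generate_cohort(sim_config(n_per_group = c(30, 30),
                                    n_features = 300, missing_rate = 0.5,
                                    seed = 3))
  X <- sim$table$intensities
  expect_gt(sum(is.na(X)), 0)
  # every surviving (observed) study value that is missing-eligible sits in
  # the low tail: observed minimum of a feature with missing entries must
  # not exceed the censoring threshold by much -> check the simpler global
  # property that no missing cell coexists with all-high observed values
  # by regenerating without censoring and comparing.
  full <- generate_cohort(sim_config(n_per_group = c(30, 30),
                                     n_features = 300, missing_rate = 0,
                                     seed = 3))
  thr <- quantile(full$table$intensities[full$table$roles == "Study", ],
                  0.10, na.rm = TRUE)
  hidden <- full$table$intensities[is.na(X)]
  expect_true(all(hidden < thr + 1e-9))
})

test_that("a zero effect size plants no class difference", {
  sim <- generate_cohort(sim_config(n_per_group = c(50, 50),
                                    n_features = 100, effect_size = 0,
                                    n_discriminant = 10, missing_rate = 0,
                                    seed = 5))
  st <- sim$table$roles == "Study"
  L <- log(sim$table$intensities[st, ])
  cl <- sim$table$classes[st]
  d <- colMeans(L[cl == "B", ]) - colMeans(L[cl == "A", ])
  expect_lt(abs(mean(d)), 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_per_group = c(0, 10)), "positive")
  expect_error(sim_config(effect_size = -1), ">= 0")
  expect_error(sim_config(dilution_range = c(2, 1)), "lo")
  expect_error(sim_config(missing_rate = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(n_discriminant = 600, n_features = 500))
})

test_that("metadata generator hits prevalences and is deterministic", {
  md <- generate_metadata(10000, c(smoke = 0.5, atopy = 0.3), seed = 1)
  expect_gt(mean(md$smoke), 0.48)
  expect_lt(mean(md$smoke), 0.52)
  expect_identical(md, generate_metadata(10000,
                                         c(smoke = 0.5, atopy = 0.3),
                                         seed = 1))
  expect_error(generate_metadata(10, c(a = 1.2), seed = 1), "\\[0, 1\\]")
})

test_that("metadata association achieves the requested odds ratio", {
  md <- generate_metadata(40000, c(risk = 0.4), outcome_prevalence = 0.5,
                          associated_factor = "risk", odds_ratio = 3,
                          seed = 2)
  tab <- table(md$outcome, md$risk)
  or <- (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])
  expect_gt(or, 2.6)
  expect_lt(or, 3.4)
  expect_lt(abs(mean(md$risk) - 0.4), 0.02)
})

test_that("feature tables round-trip through the TSV dialect", {
  sim <- generate_cohort(sim_config(n_per_group = c(5, 5), n_features = 20,
                                    seed = 9))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(sim$table, path)
  back <- read_feature_table(path)
  expect_equal(back$roles, sim$table$roles)
  expect_equal(back$classes, sim$table$classes)
  expect_equal(back$intensities, sim$table$intensities, tolerance = 1e-12)
})
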