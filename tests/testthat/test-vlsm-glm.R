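test_that("testable mask applies the minimum lesion/non-lesion counts", {
  grid <- voxel_grid(c(3, 3, 2))
  n <- 20
  lesions <- matrix(0L, 18, n)
  lesions[1, ] <- 1L                      # lesioned in all -> not testable
  lesions[2, 1:5] <- 1L                   # exactly 5 -> testable
  lesions[3, 1:4] <- 1L                   # 4 -> not testable
  lesions[4, 1:16] <- 1L                  # 4 spared -> not testable
  lesions[5, 1:10] <- 1L
  coh <- lesion_cohort(grid, lesions, sprintf("s%02d", 1:n))
  mask <- testable_voxel_mask(coh, design_spec(min_lesion_count = 5,
                                               min_nonlesion_count = 5))
  expect_equal(which(mask), c(2L, 5L))
})

test_that("lesion-only model reproduces the pooled two-sample t statistic", {
  coh <- random_cohort(n = 24, seed = 31)
  tab <- make_table(coh$subject_ids, seed = 32)
  fit <- fit_voxelwise_glm(coh, tab, design_spec(covariates = character(0)))
  for (k in seq_along(fit$voxels)) {
    l <- coh$lesions[fit$voxels[k], ]
    expect_equal(fit$t[k], pooled_t(tab$outcome, l), tolerance = 1e-10)
  }
  expect_gt(length(fit$voxels), 10)
})

test_that("a pure covariate signal is absorbed by its coefficient, not the lesion term", {
  coh <- random_cohort(n = 40, seed = 41)
  tab <- make_table(coh$subject_ids, seed = 42)
  tab$outcome <- 2 * tab$age              # exact, zero noise
  fit <- fit_voxelwise_glm(coh, tab)
  expect_equal(unname(fit$coefficients[, "age"]),
               rep(2, length(fit$voxels)), tolerance = 1e-8)
  expect_lt(max(abs(fit$coefficients[, "lesion"])), 1e-8)
  # against the independent normal-equations solver
  Z <- cbind(1, tab$age, tab$lesion_volume, tab$followup_time)
  for (k in head(seq_along(fit$voxels), 20)) {
    o <- oracle_ols(tab$outcome, coh$lesions[fit$voxels[k], ], Z)
    expect_equal(unname(fit$coefficients[k, "lesion"]),
                 unname(o$lesion_beta), tolerance = 1e-8)
  }
})

test_that("an 8-subject toy design matches the normal-equations oracle to 1e-10", {
  grid <- voxel_grid(c(2, 2, 2))
  lesions <- matrix(0L, 8, 8)
  lesions[1, c(1, 2, 5, 7)] <- 1L         # the voxel under test
  lesions[2, c(3, 4)] <- 1L               # keeps all masks valid
  lesions[2, c(6, 8)] <- 1L
  coh <- lesion_cohort(grid, lesions, sprintf("s%d", 1:8))
  tab <- covariate_table(tibble::tibble(
    subject_id = sprintf("s%d", 1:8),
    age = c(55, 60, 62, 70, 71, 75, 80, 85),
    lesion_volume = c(5, 40, 12, 7, 60, 22, 9, 30),
    followup_time = c(24, 48, 36, 96, 120, 72, 30, 160),
    outcome = c(3, 14, 6, 2, 21, 9, 8, 12)
  ), check_nihss_range = FALSE)
  spec <- design_spec(min_lesion_count = 2, min_nonlesion_count = 2)
  fit <- fit_voxelwise_glm(coh, tab, spec)
  Z <- cbind(1, tab$age, tab$lesion_volume, tab$followup_time)
  for (k in seq_along(fit$voxels)) {
    o <- oracle_ols(tab$outcome, coh$lesions[fit$voxels[k], ], Z)
    expect_equal(unname(fit$coefficients[k, "lesion"]),
                 unname(o$lesion_beta), tolerance = 1e-10)
    expect_equal(unname(fit$coefficients[k, c("(Intercept)", "age",
                                              "lesion_volume",
                                              "followup_time")]),
                 unname(o$beta[1:4]), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(fit$mse[k], o$mse, tolerance = 1e-10)
    expect_equal(fit$t[k], unname(o$t), tolerance = 1e-10)
    expect_equal(fit$df, o$df)
  }
})

test_that("the shared-design engine equals brute-force OLS on a 100-voxel instance", {
  coh <- random_cohort(n = 35, shape = c(5, 5, 4), seed = 51)
  tab <- make_table(coh$subject_ids, seed = 52)
  for (interactions in c(FALSE, TRUE)) {
    spec <- design_spec(include_interactions = interactions,
                        min_lesion_count = 3, min_nonlesion_count = 3)
    fit <- fit_voxelwise_glm(coh, tab, spec)
    expect_gte(length(fit$voxels), 90)
    tabdf <- as.data.frame(tab)
    for (k in seq_along(fit$voxels)) {
      l <- coh$lesions[fit$voxels[k], ]
      Z <- cbind(1, tabdf$age, tabdf$lesion_volume, tabdf$followup_time)
      if (interactions) {
        Z <- cbind(Z, tabdf$age * tabdf$lesion_volume,
                   tabdf$lesion_volume * tabdf$followup_time)
      }
      o <- oracle_ols(tab$outcome, l, Z)
      expect_equal(unname(fit$coefficients[k, "lesion"]),
                   unname(o$lesion_beta), tolerance = 1e-8)
      expect_equal(fit$t[k], unname(o$t), tolerance = 1e-8)
      expect_equal(fit$mse[k], o$mse, tolerance = 1e-8)
    }
  }
})

test_that("lesions that worsen outcome yield positive lesion t at lesioned voxels", {
  spec <- recovery_spec(seed = 61)
  sim <- simulate_cohort(spec)
  fit <- fit_voxelwise_glm(sim$cohort, sim$covariates)
  eloquent <- unlist(lapply(spec$regions, `[[`, "voxels"))
  in_region <- fit$voxels %in% eloquent
  expect_gt(mean(fit$t[in_region]), 2)
  expect_gt(mean(fit$t[in_region]), mean(fit$t[!in_region]) + 1)
})

test_that("a pure-noise covariate barely changes the lesion t at high SNR", {
  spec <- recovery_spec(seed = 71, n_subjects = 120)
  spec$noise_sd <- 1
  sim <- simulate_cohort(spec)
  fit1 <- fit_voxelwise_glm(sim$cohort, sim$covariates)
  tab2 <- tibble::as_tibble(sim$covariates)
  set.seed(72)
  tab2$junk <- rnorm(nrow(tab2))
  tab2 <- covariate_table(tab2, check_nihss_range = FALSE)
  fit2 <- fit_voxelwise_glm(sim$cohort, tab2, design_spec(
    covariates = c("age", "lesion_volume", "followup_time", "junk")))
  common <- intersect(fit1$voxels, fit2$voxels)
  strong <- fit1$t[match(common, fit1$voxels)] > 3
  t1 <- fit1$t[match(common, fit1$voxels)][strong]
  t2 <- fit2$t[match(common, fit2$voxels)][strong]
  expect_lt(max(abs(t1 - t2) / abs(t1)), 0.1)
})

test_that("voxels whose lesion pattern is collinear with the design are dropped", {
  n <- 16
  grid <- voxel_grid(c(3, 3, 2))
  lesions <- matrix(0L, 18, n)
  lesions[1, 1:8] <- 1L
  lesions[2, seq(1, n, 2)] <- 1L
  lesions[3, ] <- 1L                     # keeps every mask nonempty
  coh <- lesion_cohort(grid, lesions, sprintf("s%02d", 1:n))
  tab <- make_table(coh$subject_ids, seed = 81)
  # make a covariate equal to voxel 1's lesion pattern: that voxel's design
  # is rank deficient and must be dropped, others keep fitting
  tab$age <- as.numeric(lesions[1, ]) + 60
  spec <- design_spec(min_lesion_count = 4, min_nonlesion_count = 4)
  expect_message(fit <- fit_voxelwise_glm(coh, tab, spec),
                 "rank-deficient")
  expect_false(1L %in% fit$voxels)
  expect_true(2L %in% fit$voxels)
})

test_that("eloquence map extraction preserves t values and testability", {
  coh <- random_cohort(n = 25, seed = 91)
  tab <- make_table(coh$subject_ids, seed = 92)
  fit <- fit_voxelwise_glm(coh, tab)
  em <- lesion_t_map(fit)
  expect_equal(em$t[fit$voxels], fit$t)
  expect_true(all(is.na(em$t[!fit$testable])))
  expect_true(is.na(em$threshold))

  td <- tidy(fit)
  expect_equal(nrow(td), length(fit$voxels))
  expect_true(all(c("t_lesion", "mse", "lesion", "age") %in% names(td)))
})

test_that("null cohorts produce voxel t-scores centred on zero", {
  sim <- null_cohort(fwer_spec(seed = 101))
  fit <- fit_voxelwise_glm(sim$cohort, sim$covariates)
  expect_gt(length(fit$voxels), 300)
  expect_lt(abs(mean(fit$t)), 3 * sd(fit$t) / sqrt(length(fit$t)))
})
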