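test_that("identical hemispheres give t = 0, p = 1", {
  withr::local_seed(1)
  n <- 40
  v <- runif(n, 0.2, 0.4)
  res <- hemisphere_repeated_test(v, v, noise_covariates(n))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_raw, 1)
  expect_equal(res$df, n - 6)
})

test_that("paired-difference model equals the long-form repeated-measures fit", {
  withr::local_seed(2)
  for (r in 1:20) {
    n <- 30
    cv <- noise_covariates(n)
    left <- rnorm(n, 0.3, 0.05)
    right <- left + 0.01 + rnorm(n, 0, 0.02)
    ours <- hemisphere_repeated_test(left, right, cv)
    # independent route: subject fixed effects + hemisphere (+/- 1/2 coded)
    # main effect + hemisphere-by-covariate interactions on the long data
    long <- data.frame(y = c(left, right),
                       subj = factor(rep(seq_len(n), 2)),
                       hemi = rep(c(-0.5, 0.5), each = n))
    Xc <- scale(as.matrix(cv), center = TRUE, scale = FALSE)
    long <- cbind(long, Xc[rep(seq_len(n), 2), ] * long$hemi)
    full <- lm(y ~ subj + hemi + age + sex + icv_diff + tr + te, long)
    tt <- summary(full)$coefficients["hemi", ]
    expect_equal(ours$statistic, unname(tt["t value"]), tolerance = 1e-8)
    expect_equal(ours$p_raw, unname(tt["Pr(>|t|)"]), tolerance = 1e-8)
    # t^2 equals the F of dropping the hemisphere main effect
    red <- lm(y ~ subj + age + sex + icv_diff + tr + te, long)
    expect_equal(ours$statistic^2, anova(red, full)$F[2], tolerance = 1e-8)
  }
})

test_that("constant and collinear covariates are reported by name", {
  withr::local_seed(3)
  n <- 30
  cv <- noise_covariates(n)
  cv$te <- 68
  expect_error(hemisphere_repeated_test(rnorm(n), rnorm(n), cv),
               "'te' is constant")
  cv <- noise_covariates(n)
  cv$dup <- cv$age * 2
  expect_error(hemisphere_repeated_test(rnorm(n), rnorm(n), cv),
               "collinear.*dup")
})

test_that("interaction screen flags sex-specific group effects", {
  withr::local_seed(4)
  n <- 240
  group <- rep(c("NC", "MCI", "AD"), each = n / 3)
  sex <- rep(c("M", "F"), n / 2)
  cv <- group_noise_covariates(n)[, c("age", "whole_icv", "icv_diff", "tr", "te")]
  # group effect present in females only
  ai <- rnorm(n, 0, 0.01) + ifelse(group == "AD" & sex == "F", 0.03, 0)
  scr <- interaction_screen(ai, group, sex, cv)
  expect_true(scr$stratify_by_sex)
  expect_lt(scr$p_raw, 0.05)
  # single-sex input errors
  expect_error(interaction_screen(ai, group, rep("F", n), cv), "both sexes")
  # empty cell errors
  sex2 <- ifelse(group == "AD", "M", sex)
  expect_error(interaction_screen(ai, group, sex2, cv), "empty sex x group")
})

test_that("group main effect is near zero for identical group AI vectors", {
  withr::local_seed(5)
  base <- rnorm(30, 0, 0.01)
  ai <- rep(base, 3)
  group <- rep(c("NC", "MCI", "AD"), each = 30)
  cv <- group_noise_covariates(90)
  res <- group_main_effect(ai, group, cv)
  expect_lt(res$statistic, 1)
  expect_gt(res$p_raw, 0.3)
  expect_error(group_main_effect(ai, rep("NC", 90), cv), "two groups")
})

test_that("stratified group effects drop sex and subset correctly", {
  withr::local_seed(6)
  n <- 120
  group <- rep(c("NC", "MCI", "AD"), each = n / 3)
  sex <- rep(c("M", "F"), n / 2)
  ai <- rnorm(n, 0, 0.01) + ifelse(group == "AD" & sex == "F", 0.05, 0)
  cv <- group_noise_covariates(n)
  resF <- group_main_effect(ai, group, cv, stratum = "F", sex = sex)
  resM <- group_main_effect(ai, group, cv, stratum = "M", sex = sex)
  expect_lt(resF$p_raw, 0.001)
  # the effect was planted in females only: far stronger evidence there
  expect_gt(resF$statistic, 5 * resM$statistic)
  expect_error(group_main_effect(ai, group, cv, stratum = "F"), "sex is required")
})

test_that("post hoc contrasts apply the threefold Bonferroni correction", {
  withr::local_seed(7)
  n <- 90
  group <- rep(c("NC", "MCI", "AD"), each = n / 3)
  ai <- rnorm(n, 0, 0.01) + ifelse(group == "AD", 0.02, 0)
  cv <- group_noise_covariates(n)
  ph <- posthoc_pairwise(ai, group, cv)
  expect_equal(vapply(ph, function(p) p$effect, ""),
               c("AD - NC", "AD - MCI", "MCI - NC"))
  for (p in ph) {
    expect_equal(p$p_adjusted, min(1, 3 * p$p_raw))
    expect_gte(p$p_adjusted, p$p_raw)
    expect_equal(p$adjustment, "bonferroni")
  }
  expect_gt(ph[[1]]$statistic, 0)   # AD planted rightward
  # capping at 1
  ai0 <- rnorm(n, 0, 0.01)
  ph0 <- posthoc_pairwise(ai0, group, cv)
  expect_true(all(vapply(ph0, function(p) p$p_adjusted, 1) <= 1))
})

test_that("BH procedure matches the hand step-up on canonical cases", {
  r <- fdr_bh(c(0.01, 0.02, 0.03, 0.04, 0.05), q = 0.05)
  expect_true(all(r$reject))            # hand step-up: all five rejected
  expect_equal(r$critical_index, 5)
  r2 <- fdr_bh(rep(1, 10), q = 0.05)
  expect_false(any(r2$reject))
  expect_equal(r2$critical_index, 0)
  expect_error(fdr_bh(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("BH mask equals the independent step-up oracle on random vectors", {
  withr::local_seed(8)
  for (r in 1:1000) {
    m <- sample(c(5, 20, 100), 1)
    p <- runif(m)^sample(1:3, 1)   # mix of null-ish and signal-ish shapes
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_identical(fdr_bh(p, q)$reject, oracle_bh_mask(p, q))
  }
})

test_that("association regression recovers direction and errors on degeneracy", {
  withr::local_seed(9)
  n <- 150
  cv <- group_noise_covariates(n)
  ai <- rnorm(n, 0, 0.02)
  score <- 30 - 200 * ai + rnorm(n, 0, 2)
  res <- association_regression(ai, score, cv)
  expect_lt(res$statistic, 0)
  expect_lt(res$p_raw, 0.001)
  expect_error(association_regression(ai, rep(5, n), cv), "zero variance")
  expect_error(association_regression(rep(0.1, n), score, cv), "constant")
})

test_that("full battery flags a planted AD rightward effect and reruns identically", {
  spec <- cohort_spec(n_per_group = c(NC = 25L, MCI = 25L, AD = 25L),
                      n_nodes = 16L, density = 0.4,
                      global_asym_delta = c(NC = 0, MCI = 0.005, AD = 0.02),
                      subject_asym_sd = 0.01, seed = 31L)
  sim <- suppressWarnings(simulate_cohort(spec))
  met <- cohort_metrics(sim$networks)
  bat <- run_full_battery(met, sim$cohort)
  wg <- bat$within_global
  expect_true(wg$significant[wg$group == "AD" & wg$measure == "e_glob"])
  expect_gt(wg$statistic[wg$group == "AD" & wg$measure == "e_glob"], 0)
  ge <- bat$group_effects
  expect_true(any(ge$measure == "e_glob" & ge$significant))
  # determinism: identical inputs give identical bundles
  bat2 <- run_full_battery(met, sim$cohort)
  expect_identical(bat, bat2)
  # id mismatches are rejected
  bad <- sim$cohort; bad$id[1] <- "NOPE"
  expect_error(run_full_battery(met, bad), "id mismatch")
})

test_that("battery completes on a fully symmetric null cohort", {
  spec <- cohort_spec(n_per_group = c(NC = 15L, MCI = 15L, AD = 15L),
                      n_nodes = 12L, density = 0.5, seed = 32L)
  sim <- simulate_cohort(spec)
  met <- cohort_metrics(sim$networks)
  # all AIs exactly zero -> constant AI columns; battery must complete and
  # log the degenerate measures rather than fail
  bat <- suppressWarnings(run_full_battery(met, sim$cohort))
  expect_s3_class(bat, "asym_battery")
  expect_equal(length(bat$screened_nodes), 0)
})
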