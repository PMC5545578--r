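test_that("null cohort has bit-identical hemispheres and zero AI", {
  spec <- cohort_spec(n_per_group = c(NC = 4L, MCI = 4L, AD = 4L),
                      n_nodes = 20L, density = 0.4, seed = 1L)
  sim <- simulate_cohort(spec)
  for (nw in sim$networks) {
    expect_identical(nw$left$weights, nw$right$weights)
  }
  expect_true(all(sim$cohort$true_ai == 0))
})

test_that("planted shifts appear on shared edges exactly as specified", {
  delta <- c(NC = 0, MCI = 0.01, AD = 0.04)
  nodal_nodes <- c(2L, 5L)
  nodal_delta <- c(NC = 0, MCI = 0, AD = 0.05)
  spec <- cohort_spec(n_per_group = c(NC = 2L, MCI = 2L, AD = 2L),
                      n_nodes = 12L, density = 0.6,
                      global_asym_delta = delta,
                      nodal_asym_nodes = nodal_nodes,
                      nodal_asym_delta = nodal_delta, seed = 2L)
  sim <- simulate_cohort(spec)
  for (s in seq_len(nrow(sim$cohort))) {
    g <- sim$cohort$group[s]
    Wl <- sim$networks[[s]]$left$weights
    Wr <- sim$networks[[s]]$right$weights
    shared <- Wl > 0
    diff <- Wr - Wl
    incident <- outer(seq_len(12) %in% nodal_nodes,
                      seq_len(12) %in% nodal_nodes, "|")
    plain <- shared & !incident
    # unclipped edges carry exactly the group shift
    unclipped <- plain & Wr < 1 & Wr > .Machine$double.eps
    expect_true(all(abs(diff[unclipped] - delta[[g]]) < 1e-12))
    nod <- shared & incident & Wr < 1 & Wr > .Machine$double.eps
    if (any(nod))
      expect_true(all(abs(diff[nod] - delta[[g]] - nodal_delta[[g]]) < 1e-12))
    # absent edges stay absent on both sides
    expect_true(all(Wr[!shared] == 0))
  }
})

test_that("weights are clipped into (0, 1] and symmetric with zero diagonal", {
  spec <- cohort_spec(n_per_group = c(NC = 3L, MCI = 0L, AD = 3L),
                      n_nodes = 15L, density = 0.5,
                      base_weight_mean = 0.9, base_weight_sd = 0.2,
                      global_asym_delta = c(NC = 0, MCI = 0, AD = 0.3),
                      seed = 3L)
  sim <- simulate_cohort(spec)
  for (nw in sim$networks) {
    for (h in c("left", "right")) {
      W <- nw[[h]]$weights
      expect_true(all(W >= 0 & W <= 1))
      expect_identical(W, t(W))
      expect_true(all(diag(W) == 0))
    }
  }
  expect_gt(sim$truth$clip_rate, 0)   # mean 0.9 + shift must clip
})

test_that("edge weights match the specified distribution", {
  spec <- cohort_spec(n_per_group = c(NC = 10L, MCI = 0L, AD = 0L),
                      n_nodes = 40L, density = 0.3,
                      base_weight_mean = 0.5, base_weight_sd = 0.1,
                      seed = 4L)
  sim <- simulate_cohort(spec, compute_true_ai = FALSE)
  w <- unlist(lapply(sim$networks, function(nw) {
    W <- nw$left$weights
    W[upper.tri(W) & W > 0]
  }))
  se <- 0.1 / sqrt(length(w))
  expect_lt(abs(mean(w) - 0.5), 3 * se)
  # density: each pair connected with the requested probability
  ne <- length(w) / 10
  npairs <- 40 * 39 / 2
  expect_lt(abs(ne / npairs - 0.3), 3 * sqrt(0.3 * 0.7 / (npairs * 10)) + 0.01)
})

test_that("cohort generation is element-wise reproducible", {
  spec <- cohort_spec(n_per_group = c(NC = 3L, MCI = 3L, AD = 3L),
                      n_nodes = 10L, density = 0.5,
                      subject_asym_sd = 0.01, seed = 5L)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$networks, b$networks)
  spec2 <- spec; spec2$seed <- 6L
  c <- simulate_cohort(spec2)
  expect_false(identical(a$cohort, c$cohort))
})

test_that("demographics follow the group-specific covariate model", {
  spec <- cohort_spec(n_per_group = c(NC = 150L, MCI = 150L, AD = 150L),
                      n_nodes = 4L, density = 1, seed = 7L)
  sim <- simulate_cohort(spec, compute_true_ai = FALSE)
  co <- sim$cohort
  # AD group is male-dominated (p = 19/25), NC is not (p = 21/48)
  pm <- tapply(co$sex == "M", co$group, mean)
  expect_gt(pm[["AD"]], 0.6)
  expect_lt(pm[["NC"]], 0.6)
  # age means track the group model within sampling error
  am <- tapply(co$age, co$group, mean)
  expect_lt(abs(am[["AD"]] - 77.4), 3 * 8.4 / sqrt(150))
  expect_lt(abs(am[["NC"]] - 75.0), 3 * 6.0 / sqrt(150))
  # hemispheric ICVs are positive and sum to the whole ICV
  expect_true(all(co$left_icv > 0 & co$right_icv > 0))
  expect_equal(co$left_icv + co$right_icv, co$whole_icv, tolerance = 1e-12)
})

test_that("low density triggers the connectivity warning, networks returned", {
  spec <- cohort_spec(n_per_group = c(NC = 2L, MCI = 0L, AD = 0L),
                      n_nodes = 30L, density = 0.02, seed = 8L)
  expect_warning(sim <- simulate_cohort(spec), "not connected")
  expect_equal(length(sim$networks), 2)
  expect_gt(length(sim$truth$log), 0)
})

test_that("scores are linearly coupled to the true AI", {
  sm <- default_score_model()
  sm$TOTAL$noise_sd <- 0   # deterministic score
  spec <- cohort_spec(n_per_group = c(NC = 10L, MCI = 10L, AD = 10L),
                      n_nodes = 16L, density = 0.4,
                      global_asym_delta = c(NC = 0, MCI = 0.01, AD = 0.03),
                      subject_asym_sd = 0.02, score_model = sm, seed = 9L)
  sim <- suppressWarnings(simulate_cohort(spec))
  co <- sim$cohort
  pred <- sm$TOTAL$beta0 + sm$TOTAL$beta_ai * co$true_ai +
    sm$TOTAL$beta_age * (co$age - 75) + sm$TOTAL$beta_sex * (co$sex == "M")
  expect_equal(co$ravlt_total, pred, tolerance = 1e-12)
})

test_that("cohort disk round-trip preserves tables and matrices", {
  spec <- cohort_spec(n_per_group = c(NC = 2L, MCI = 2L, AD = 2L),
                      n_nodes = 8L, density = 0.6, seed = 10L)
  sim <- simulate_cohort(spec)
  d <- withr::local_tempdir()
  write_cohort(sim, d)
  back <- read_cohort(d)
  expect_equal(back$cohort$id, sim$cohort$id)
  expect_equal(back$cohort$age, sim$cohort$age, tolerance = 1e-9)
  for (id in sim$cohort$id)
    expect_identical(back$networks[[id]]$right$weights,
                     sim$networks[[id]]$right$weights)
})
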