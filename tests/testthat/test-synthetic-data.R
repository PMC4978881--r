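test_that("sporulation count generator is a pure function of params and seed", {
  prm <- spor_sim_params(baseline_logit = 0.3, effect_A = -1, rho = 0.03)
  dsn <- data.frame(strain = c("T", "S"), A = c(0, 1), B = 0)
  a <- simulate_sporulation_counts(prm, dsn, seed = 7)
  b <- simulate_sporulation_counts(prm, dsn, seed = 7)
  expect_identical(a, b)
  expect_true(all(a$y >= 0 & a$y <= a$n))

  tc1 <- simulate_nuclei_timecourse(kinetic_params(8, .25, .5, .65), seed = 3)
  tc2 <- simulate_nuclei_timecourse(kinetic_params(8, .25, .5, .65), seed = 3)
  expect_identical(tc1, tc2)

  sp <- expr_sim_spec(n_genes = 50, n_tfs = 2)
  e1 <- simulate_expression_pair(sp, seed = 11)
  e2 <- simulate_expression_pair(sp, seed = 11)
  expect_identical(e1, e2)
})

test_that("symmetric binomial null gives efficiency near one half", {
  prm <- spor_sim_params(baseline_logit = 0, rho = 0, n_reps = 200)
  cts <- simulate_sporulation_counts(prm,
                                     data.frame(strain = "x", A = 0, B = 0),
                                     seed = 42)
  se <- sqrt(0.25 / sum(cts$n))
  expect_lt(abs(mean(cts$y / cts$n) - 0.5), 3 * se + 1e-12)
})

test_that("allele effect propagates to the pooled proportion (inverse logit)", {
  prm <- spor_sim_params(baseline_logit = 0, effect_A = -1.465, rho = 0,
                         n_reps = 1e4)
  cts <- simulate_sporulation_counts(prm,
                                     data.frame(strain = "a1", A = 1, B = 0),
                                     seed = 13)
  p_target <- plogis(-1.465)
  se <- sqrt(p_target * (1 - p_target) / sum(cts$n))
  expect_lt(abs(sum(cts$y) / sum(cts$n) - p_target), 3 * se)
})

test_that("invalid generator parameters are rejected", {
  expect_error(spor_sim_params(rho = 1), "rho")
  expect_error(spor_sim_params(rho = -0.1), "rho")
  expect_error(spor_sim_params(n_cells = 0), "n_cells")
  expect_error(simulate_nuclei_timecourse(kinetic_params(1, 1, 1, 1),
                                          times = c(-1, 2, 3)), ">= 0")
})

test_that("nuclei counts match the kinetic state probabilities", {
  kin <- kinetic_params(8, 0.25, 0.5, 0.65)
  # before the delay every cell is in the one-nucleus state
  tc <- simulate_nuclei_timecourse(kin, times = c(0, 2, 4, 6), 500, seed = 1)
  expect_true(all(tc$c1 == 500 & tc$c2 == 0 & tc$c4 == 0))
  # zero cells per time is a valid degenerate draw
  tc0 <- simulate_nuclei_timecourse(kin, times = c(0, 10), 0, seed = 1)
  expect_true(all(tc0[, c("c1", "c2", "c4")] == 0))
  # large-sample fractions agree with the closed form at t = 20
  tc <- simulate_nuclei_timecourse(kin, times = c(0, 20), 1e5, seed = 99)
  p <- state_probabilities(kin, 20)
  obs <- unlist(tc[2, c("c1", "c2", "c4")]) / 1e5
  se <- sqrt(p * (1 - p) / 1e5)
  expect_true(all(abs(obs - p) < 3 * se + 1e-12))
})

test_that("expression pair plants the promised structure", {
  # noise-free increasing archetype is non-decreasing after base transform
  sp <- expr_sim_spec(n_genes = 4, noise_sd = 0, diff_fraction = 1,
                      archetype_assignment = rep("increasing", 4), n_tfs = 0)
  sim <- simulate_expression_pair(sp, seed = 2)
  bt <- base_transform(sim$strain1)
  expect_true(all(apply(bt$values, 1, function(v) all(diff(v) >= 0))))

  # a null pair (no differential genes) is bitwise identical across strains
  sp0 <- expr_sim_spec(n_genes = 30, diff_fraction = 0, noise_sd = 0,
                       n_tfs = 0)
  sim0 <- simulate_expression_pair(sp0, seed = 3)
  expect_identical(sim0$strain1$values, sim0$strain2$values)

  # planted regulon: realized odds ratio close to the requested value
  sp5 <- expr_sim_spec(n_genes = 2000, diff_fraction = 0.5, noise_sd = 0,
                       n_tfs = 0,
                       regulon_enrichment = list(tfX = list(or = 5,
                                                            cluster = "early")))
  sim5 <- simulate_expression_pair(sp5, seed = 4)
  in_cl <- sim5$truth$differential & sim5$truth$archetype_strain1 == "early"
  tgt <- sim5$truth$target_tfX
  a <- sum(in_cl & tgt); b <- sum(in_cl & !tgt)
  cc <- sum(!in_cl & tgt); d <- sum(!in_cl & !tgt)
  log_or <- log(a * d / (b * cc))
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  expect_lt(abs(log_or - log(5)), 3 * se)
})

test_that("fully null simulation yields no downstream signal", {
  sp <- expr_sim_spec(n_genes = 200, diff_fraction = 0, noise_sd = 0,
                      n_tfs = 3)
  sim <- simulate_expression_pair(sp, seed = 8)
  de <- diff_temporal_test(base_transform(sim$strain1),
                           base_transform(sim$strain2),
                           n_null = 20, seed = 9)
  expect_identical(sum(de$significant), 0L)
  expect_true(all(de$statistic == 0))
  cl <- cluster_genes(base_transform(sim$strain1))
  expect_true(all(cl$labels$label == "unclassified"))

  prm <- spor_sim_params(rho = 0, n_reps = 6)
  cts <- simulate_sporulation_counts(prm,
                                     data.frame(strain = c("T", "S"),
                                                A = c(0, 1), B = 0),
                                     seed = 10)
  expect_gt(pair_test(cts)$p_value, 0.05)
})
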