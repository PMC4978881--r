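test_that("intercept-only fit matches the pooled-logit closed form", {
  cts <- make_counts("a", y = c(50, 60), n = c(200, 200))
  fit <- fit_quasibinomial(cts, design = cbind(intercept = c(1, 1)))
  expect_equal(unname(fit$coefficients),
               oracle_pooled_logit(c(50, 60), c(200, 200)),
               tolerance = 1e-8)
  expect_equal(unname(fit$coefficients), -0.9694006, tolerance = 1e-6)
  expect_gte(fit$dispersion, 0)
})

test_that("per-strain-intercept fits equal pooled logits (IRLS vs oracle)", {
  set.seed(21)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    cts <- do.call(rbind, lapply(seq_len(k), function(s) {
      n <- sample(150:400, 3, replace = TRUE)
      make_counts(paste0("s", s), y = rbinom(3, n, runif(1, .1, .9)), n = n)
    }))
    X <- sapply(unique(cts$strain), function(s) as.numeric(cts$strain == s))
    fit <- fit_quasibinomial(cts, X)
    for (s in unique(cts$strain)) {
      idx <- cts$strain == s
      expect_equal(unname(fit$coefficients[s]),
                   oracle_pooled_logit(cts$y[idx], cts$n[idx]),
                   tolerance = 1e-8)
    }
    expect_true(isSymmetric(fit$covariance, tol = 1e-10))
    expect_true(all(eigen(fit$covariance, only.values = TRUE)$values > -1e-10))
  }
})

test_that("equal proportions across strains give equal coefficients", {
  cts <- rbind(make_counts("a", c(30, 40), c(100, 100)),
               make_counts("b", c(35, 35), c(100, 100)),
               make_counts("c", c(28, 42), c(100, 100)))
  X <- sapply(unique(cts$strain), function(s) as.numeric(cts$strain == s))
  fit <- fit_quasibinomial(cts, X)
  expect_equal(unname(diff(range(fit$coefficients))), 0, tolerance = 1e-8)
})

test_that("pair test has the documented estimate, df, symmetry and null", {
  cts_i <- make_counts("i", c(150, 160), c(300, 300))
  cts_j <- make_counts("j", c(50, 55), c(300, 300))
  tst <- pair_test(rbind(cts_i, cts_j))
  expect_equal(tst$estimate,
               oracle_pooled_logit(c(150, 160), c(300, 300)) -
                 oracle_pooled_logit(c(50, 55), c(300, 300)),
               tolerance = 1e-8)
  expect_identical(tst$df, 2L)
  expect_lt(tst$p_value, 0.05)

  rev <- pair_test(rbind(cts_i, cts_j), "j", "i")
  expect_equal(rev$estimate, -tst$estimate, tolerance = 1e-10)
  expect_equal(rev$p_value, tst$p_value, tolerance = 1e-12)

  # exact null: identical counts in both strains
  same <- rbind(make_counts("x", c(80, 90), 300),
                make_counts("y", c(80, 90), 300))
  tst0 <- pair_test(same)
  expect_equal(tst0$estimate, 0, tolerance = 1e-10)
  expect_equal(tst0$p_value, 1, tolerance = 1e-8)
})

test_that("interaction estimate is the pooled-logit double difference", {
  cts <- rbind(make_counts("T", c(120, 130), 300),
               make_counts("S", c(40, 45), 300),
               make_counts("Td", c(80, 85), 300),
               make_counts("Sd", c(38, 42), 300))
  coding <- data.frame(strain = c("T", "S", "Td", "Sd"),
                       A = c(0, 1, 0, 1), B = c(0, 0, 1, 1))
  tst <- interaction_test(cts, coding)
  l <- function(y) oracle_pooled_logit(y, c(300, 300))
  expected <- l(c(38, 42)) - l(c(40, 45)) - l(c(80, 85)) + l(c(120, 130))
  expect_equal(tst$estimate, expected, tolerance = 1e-8)

  # swapping the A and B factor labels leaves the interaction unchanged
  coding_swap <- data.frame(strain = coding$strain, A = coding$B,
                            B = coding$A)
  tst_swap <- interaction_test(cts, coding_swap)
  expect_equal(tst_swap$estimate, tst$estimate, tolerance = 1e-10)
  expect_equal(tst_swap$p_value, tst$p_value, tolerance = 1e-10)
})

test_that("an exactly multiplicative design has zero interaction", {
  # pooled cell odds 1, 1/2, 1/2, 1/4: l11 = l10 + l01 - l00 exactly,
  # with replicate variation so the dispersion estimate is positive
  n <- 600
  cts <- rbind(make_counts("a", c(290, 310), n),   # pooled 1/2
               make_counts("b", c(190, 210), n),   # pooled 1/3
               make_counts("c", c(195, 205), n),   # pooled 1/3
               make_counts("d", c(115, 125), n))   # pooled 1/5
  coding <- data.frame(strain = c("a", "b", "c", "d"),
                       A = c(0, 1, 0, 1), B = c(0, 0, 1, 1))
  tst <- interaction_test(cts, coding)
  expect_equal(tst$estimate, 0, tolerance = 1e-8)
  expect_equal(tst$p_value, 1, tolerance = 1e-6)
  expect_gt(tst$se, 0)
})

test_that("missing design cells and exhausted degrees of freedom error", {
  cts <- rbind(make_counts("a", c(10, 12), 100),
               make_counts("b", c(20, 22), 100),
               make_counts("c", c(30, 33), 100))
  coding <- data.frame(strain = c("a", "b", "c"),
                       A = c(0, 1, 0), B = c(0, 0, 1))
  expect_error(interaction_test(cts, coding), "missing design cell")

  one_each <- make_counts("z", 10, 100)
  expect_error(fit_quasibinomial(one_each, cbind(1)), "residual degrees")
  all_zero <- make_counts("z", c(0, 0, 0), 100)
  expect_error(fit_quasibinomial(all_zero, cbind(rep(1, 3))), "separation")
})

test_that("dispersion is near 1 under a pure binomial null", {
  set.seed(77)
  phi <- replicate(800, {
    cts <- make_counts("s", rbinom(6, 300, 0.4), 300)
    fit_quasibinomial(cts, cbind(rep(1, 6)))$dispersion
  })
  # each estimate is chi2_5/5; the mean over 800 draws concentrates at 1
  expect_lt(abs(mean(phi) - 1), 0.1)
  expect_true(all(phi >= 0))
})

test_that("interaction-test power is monotone in the interaction size", {
  set.seed(88)
  dsn <- data.frame(strain = c("TT", "S", "Td", "Sd"),
                    A = c(0, 1, 0, 1), B = c(0, 0, 1, 1))
  n_sim <- 250
  power <- sapply(c(0, 0.6, 1.2, 1.8), function(eff) {
    prm <- spor_sim_params(baseline_logit = 0.4, effect_A = -1,
                           effect_B = -0.5, effect_AB = eff, rho = 0.02,
                           n_reps = 6)
    mean(replicate(n_sim, {
      interaction_test(simulate_sporulation_counts(prm, dsn), dsn)$p_value <= 0.05
    }))
  })
  mc_se <- sqrt(pmax(power * (1 - power), 0.25 / n_sim) / n_sim)
  expect_true(all(diff(power) > -(mc_se[-1] + mc_se[-length(mc_se)])))
  expect_gt(power[4], power[1])
})

test_that("fold difference is a symmetric ratio of mean efficiencies", {
  a <- make_counts("A", c(180, 180), 300)   # 0.6
  b <- make_counts("B", c(60, 60), 300)     # 0.2
  expect_equal(fold_difference(a, b), 3.0)
  expect_equal(fold_difference(b, a), 3.0)
  expect_equal(fold_difference(a, a), 1.0)
  zero <- make_counts("Z", c(0, 0), 300)
  expect_error(fold_difference(a, zero), "undefined")
})
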