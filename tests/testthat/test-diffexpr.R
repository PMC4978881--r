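test_that("local linear smoothing reproduces affine and constant series", {
  tt <- sporulation_times()
  M <- rbind(affine = 1.5 + 0.3 * tt, const = rep(2, length(tt)))
  es <- expression_series(M, tt)
  sm <- smooth_expression(es, h = 1.2)
  expect_equal(sm$values, es$values, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_identical(sm$stage, "smoothed")
})

test_that("smoothed values equal a brute-force tricube weighted regression", {
  tt <- seq(0, 8, by = 1)
  set.seed(4)
  y <- rnorm(length(tt))
  es <- expression_series(matrix(y, 1), tt)
  sm <- smooth_expression(es, h = 2.5, expand = FALSE)
  for (i in c(1, 4, 9)) {
    w <- pmax(0, 1 - (abs(tt - tt[i]) / 2.5)^3)^3
    fit <- lm(y ~ tt, weights = w)
    expect_equal(unname(sm$values[1, i]),
                 unname(predict(fit, data.frame(tt = tt[i]))),
                 tolerance = 1e-10)
  }
})

test_that("too-small strict bandwidths report the offending time", {
  es <- expression_series(matrix(rnorm(9), 1), sporulation_times())
  expect_error(smooth_expression(es, h = 0.3, expand = FALSE),
               "t = ")
})

test_that("base transform anchors, is idempotent and offset-invariant", {
  tt <- sporulation_times()
  set.seed(5)
  M <- matrix(rnorm(3 * length(tt)), 3, dimnames = list(c("g1", "g2", "g3")))
  es <- expression_series(M, tt)
  bt <- base_transform(es)
  expect_true(all(bt$values[, 1] == 0))
  expect_identical(bt$stage, "base_transformed")
  expect_equal(base_transform(bt)$values, bt$values)

  # genes differing by a constant offset transform identically
  es2 <- expression_series(rbind(M[1, ], M[1, ] + 3), tt)
  bt2 <- base_transform(es2)
  expect_equal(bt2$values[1, ], bt2$values[2, ], ignore_attr = TRUE)

  no_zero <- expression_series(M, tt + 1)
  expect_error(base_transform(no_zero), "t = 0")
})

test_that("storey q-values follow the step-up arithmetic and its bounds", {
  expect_equal(storey_qvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(storey_qvalues(rep(1, 5)), rep(1, 5))
  expect_error(storey_qvalues(numeric(0)), "empty")
  expect_error(storey_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(6)
  p <- runif(5000)
  q <- storey_qvalues(p)
  expect_true(all(q >= p - 1e-12))        # pi0 = 1 dominates
  expect_true(all(q <= 1))
  expect_lt(mean(q <= 0.10), 0.01)        # uniform null yields ~no calls
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))  # monotone in p
  q_s <- storey_qvalues(p, pi0_method = "smoother")
  expect_true(all(q_s <= q + 1e-12))      # estimated pi0 <= 1
})

test_that("identical strains give all-zero statistics and q of 1", {
  tt <- sporulation_times()
  set.seed(7)
  M <- matrix(rnorm(40 * length(tt)), 40)
  a <- base_transform(expression_series(M, tt))
  de <- diff_temporal_test(a, a, n_null = 10, seed = 1)
  expect_true(all(de$statistic == 0))
  expect_true(all(de$q_value == 1))
  expect_false(any(de$significant))
})

test_that("the statistic ignores curves shared by both strains", {
  tt <- sporulation_times()
  set.seed(8)
  G <- 30
  M1 <- matrix(rnorm(G * length(tt), sd = 0.2), G)
  M2 <- matrix(rnorm(G * length(tt), sd = 0.2), G)
  a1 <- base_transform(expression_series(M1, tt))
  a2 <- base_transform(expression_series(M2, tt))
  de <- diff_temporal_test(a1, a2, n_null = 15, seed = 3)

  # add a curve representable in the test's internal basis (anchored at 0)
  shared <- c(0, 2 * splines::ns(tt[tt > 0], df = 2)[, 1])
  b1 <- base_transform(expression_series(sweep(M1, 2, shared, `+`), tt))
  b2 <- base_transform(expression_series(sweep(M2, 2, shared, `+`), tt))
  de_shift <- diff_temporal_test(b1, b2, n_null = 15, seed = 3)
  expect_equal(de_shift$statistic, de$statistic, tolerance = 1e-8)
})

test_that("basis dimension must leave residual degrees of freedom", {
  tt <- sporulation_times()
  a <- base_transform(expression_series(matrix(rnorm(2 * 9), 2), tt))
  expect_error(diff_temporal_test(a, a, basis_df = 9), "smaller")
  expect_error(diff_temporal_test(a, a, basis_df = 7), "too large")
  raw <- expression_series(matrix(rnorm(18), 2), tt)
  expect_error(diff_temporal_test(raw, raw), "base_transformed")
})

test_that("planted differential genes are detected with FDR control", {
  sim <- simulate_expression_pair(
    expr_sim_spec(n_genes = 600, diff_fraction = 0.1, noise_sd = 0.2,
                  n_tfs = 0), seed = 31)
  de <- diff_temporal_test(base_transform(sim$strain1),
                           base_transform(sim$strain2),
                           n_null = 30, seed = 32)
  truth <- sim$truth$differential
  expect_gt(mean(de$significant[truth]), 0.6)
  fdr <- sum(de$significant & !truth) / max(1, sum(de$significant))
  expect_lt(fdr, 0.15)
})
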