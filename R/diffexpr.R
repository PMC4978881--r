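# residual-maker matrix of a design; I - X (X'X)^-1 X'
residual_projector <- function(X) {
  q <- qr.Q(qr(X))
  diag(nrow(X)) - tcrossprod(q)
}

#' Temporal differential-expression test between two strains
#'
#' Per gene, a nested-model F-like statistic contrasts a null in which one
#' shared natural-spline curve (plus strain-specific intercepts) describes
#' both strains' base-transformed time courses against an alternative with
#' strain-specific curves:
#' \deqn{F = (\mathrm{RSS}_0 - \mathrm{RSS}_1)/\mathrm{RSS}_1 .}
#' The null distribution is built by permuting strain labels within time
#' points (`n_null` permuted datasets, one flip pattern each) and pooling
#' the permuted statistics across genes; p-values are empirical tail
#' probabilities against this pool and q-values come from
#' [storey_qvalues()].  Flip patterns are constrained to swap at least
#' three time points and leave at least three unswapped (when the grid
#' allows): near-identity relabellings would carry each truly differential
#' gene's own signal into the pooled null and inflate it, a well-known
#' contamination of pooled permutation nulls.
#'
#' The `t = 0` column is identically zero after the base transformation
#' and is excluded from the regression.  Each strain's curve is then
#' centred over the remaining times: after baseline subtraction every
#' value of a strain carries the same `-value(t0)` term, and centring
#' cancels it exactly, so noise in the baseline measurement is neither
#' mistaken for temporal signal nor allowed to decalibrate the permutation
#' null.  This is how the test controls for expression at t = 0; constant
#' level offsets between strains are deliberately not counted as temporal
#' differential expression.  The permutation null assumes residuals are
#' exchangeable across strains within time points, which holds for
#' unsmoothed series; pre-smoothed input correlates residuals across
#' times and makes the permutation p-values anticonservative, so test
#' unsmoothed curves (the test has its own spline smoother built in).
#'
#' @param strain1,strain2 base-transformed [expression_series()] on a
#'   common grid with identical gene sets.
#' @param basis_df natural-spline degrees of freedom (default 2); must be
#'   smaller than the number of time points.  With a single replicate per
#'   time the alternative model spends `2 * (basis_df + 1)` parameters, so
#'   small bases buy large power gains for the smooth monotone and
#'   saturating trends of interest (see the methods vignette).
#' @param n_null number of permuted datasets for the pooled null.
#' @param seed integer seed for the permutations.
#' @param fdr q-value cutoff for the `significant` flag (default 0.10).
#' @param pi0_method passed to [storey_qvalues()].
#' @return data.frame with columns `gene`, `statistic`, `p_value`,
#'   `q_value`, `significant`.
#' @export
diff_temporal_test <- function(strain1, strain2, basis_df = 2, n_null = 50,
                               seed = NULL, fdr = 0.10,
                               pi0_method = "fixed_1") {
  stopifnot(inherits(strain1, "expression_series"),
            inherits(strain2, "expression_series"))
  if (strain1$stage != "base_transformed" ||
      strain2$stage != "base_transformed")
    stop_sporeffect("both series must be base_transformed (see base_transform())")
  if (!isTRUE(all.equal(strain1$times, strain2$times)))
    stop_sporeffect("the two strains must share one time grid")
  if (!identical(rownames(strain1$values), rownames(strain2$values)))
    stop_sporeffect("the two strains must share one gene set")
  times <- strain1$times
  if (basis_df >= length(times))
    stop_sporeffect("'basis_df' must be smaller than the number of time points")
  keep <- times > 0
  tt <- times[keep]
  if (basis_df > length(tt) - 2L)
    stop_sporeffect("'basis_df' too large for the residual degrees of freedom")
  set_seed_if(seed)

  N <- splines::ns(tt, df = basis_df)
  m <- length(tt)
  s2 <- rep(c(0, 1), each = m)
  Nstack <- rbind(N, N)
  X0 <- cbind(1, s2, Nstack)
  X1 <- cbind(X0, Nstack * s2)
  M0 <- residual_projector(X0)
  M1 <- residual_projector(X1)

  Y1 <- strain1$values[, keep, drop = FALSE]
  Y2 <- strain2$values[, keep, drop = FALSE]
  # centring each strain over t > 0 cancels the shared -value(t0) term
  Y <- cbind(Y1 - rowMeans(Y1), Y2 - rowMeans(Y2))
  f_stat <- function(Y) {
    rss0 <- rowSums((Y %*% M0) * Y)
    rss1 <- rowSums((Y %*% M1) * Y)
    num <- pmax(rss0 - rss1, 0)
    tol <- 1e-12 * pmax(rss0, 1)
    ifelse(num <= tol, 0, num / pmax(rss1, tol))
  }
  Fobs <- f_stat(Y)

  # pooled permutation null: one within-time strain-flip pattern per
  # dataset, constrained away from (near-)identity relabellings
  min_flip <- if (m >= 6L) 3L else 1L
  Fnull <- matrix(0, nrow(Y), n_null)
  for (b in seq_len(n_null)) {
    repeat {
      flip <- which(runif(m) < 0.5)
      if (length(flip) >= min_flip && m - length(flip) >= min_flip) break
    }
    Yb <- Y
    Yb[, flip] <- Y[, flip + m]
    Yb[, flip + m] <- Y[, flip]
    Fnull[, b] <- f_stat(Yb)
  }
  pool <- sort(as.numeric(Fnull))
  n_pool <- length(pool)
  # p = (1 + #{null >= F}) / (1 + n_pool)
  p <- (1 + n_pool - findInterval(Fobs, pool, left.open = TRUE)) / (1 + n_pool)
  q <- storey_qvalues(p, pi0_method = pi0_method)
  data.frame(gene = rownames(strain1$values), statistic = Fobs,
             p_value = p, q_value = q, significant = q <= fdr,
             row.names = NULL)
}

#' Storey q-values for FDR control
#'
#' \eqn{q_i = \pi_0 \min_{j : p_j \ge p_i} m p_j / \mathrm{rank}(p_j)},
#' capped at 1.  The proportion of true nulls \eqn{\pi_0} is fixed at 1
#' (conservative, Benjamini-Hochberg-like) by default, or estimated by
#' Storey's smoother over a lambda grid.
#'
#' @param pvals vector of p-values in `[0, 1]`.
#' @param pi0_method `"fixed_1"` (default) or `"smoother"`.
#' @return q-values in the input order.
#' @export
storey_qvalues <- function(pvals, pi0_method = c("fixed_1", "smoother")) {
  pi0_method <- match.arg(pi0_method)
  if (length(pvals) == 0L) stop_sporeffect("empty p-value vector")
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop_sporeffect("p-values must lie in [0, 1]")
  m <- length(pvals)
  pi0 <- if (pi0_method == "fixed_1") 1 else {
    lambda <- seq(0.05, 0.95, by = 0.05)
    pi0_l <- vapply(lambda, function(l) mean(pvals > l) / (1 - l), numeric(1))
    fit <- smooth.spline(lambda, pi0_l, df = 3)
    min(1, max(predict(fit, x = max(lambda))$y, 1e-8))
  }
  o <- order(pvals, decreasing = TRUE)
  q_sorted <- pmin(1, cummin(pi0 * m * pvals[o] / (m:1)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}
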