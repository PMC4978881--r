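#' Validate a sporulation count table
#'
#' A sporulation count table records, for every replicate of every strain,
#' the number of four-nuclei (sporulated) cells `y` among `n` cells counted.
#'
#' @param counts data.frame with columns `strain`, `replicate`, `y`, `n`.
#' @return The validated data.frame, invisibly classed as
#'   `"sporulation_counts"`.
#' @export
as_sporulation_counts <- function(counts) {
  required <- c("strain", "replicate", "y", "n")
  missing_cols <- setdiff(required, names(counts))
  if (length(missing_cols))
    stop_sporeffect("count table is missing column(s): ",
                    paste(missing_cols, collapse = ", "))
  if (nrow(counts) == 0L)
    stop_sporeffect("count table has no rows")
  bad <- which(!is.finite(counts$y) | !is.finite(counts$n) |
                 counts$y < 0 | counts$n < 1 | counts$y > counts$n |
                 counts$y != round(counts$y) | counts$n != round(counts$n))
  if (length(bad))
    stop_sporeffect("invalid count row(s) (need 0 <= y <= n, n >= 1, integer): row ",
                    paste(bad, collapse = ", "))
  counts$strain <- as.character(counts$strain)
  class(counts) <- unique(c("sporulation_counts", class(counts)))
  counts
}

# quasi-binomial IRLS via the stats engine; X is the model matrix
qb_glm <- function(y, n, X) {
  stopifnot(nrow(X) == length(y))
  p <- ncol(X)
  residual_df <- length(y) - p
  if (residual_df < 1L)
    stop_sporeffect("design leaves no residual degrees of freedom ",
                    "(need more records than coefficients)")
  if (qr(X)$rank < p)
    stop_sporeffect("design matrix is rank deficient")
  # complete-separation diagnostic: a design cell whose pooled count is all
  # successes or all failures has an infinite fitted log-odds
  cell <- apply(X, 1L, paste, collapse = "\r")
  for (cl in unique(cell)) {
    idx <- cell == cl
    tot_y <- sum(y[idx]); tot_n <- sum(n[idx])
    if (tot_y == 0 || tot_y == tot_n)
      stop_sporeffect("complete separation: all counts are 0 or n within a ",
                      "design cell; log-odds are not estimable")
  }
  fit <- suppressWarnings(
    stats::glm.fit(x = X, y = y / n, weights = n,
                   family = stats::quasibinomial(link = "logit"),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  mu <- fit$fitted.values
  pearson <- (y / n - mu) * sqrt(n / (mu * (1 - mu)))
  dispersion <- sum(pearson^2) / residual_df
  qr_r <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  qr_r[lower.tri(qr_r)] <- 0
  cov_unscaled <- chol2inv(qr_r)
  covariance <- dispersion * cov_unscaled
  dimnames(covariance) <- list(colnames(X), colnames(X))
  structure(list(coefficients = fit$coefficients,
                 covariance = covariance,
                 dispersion = dispersion,
                 residual_df = residual_df,
                 fitted = mu,
                 converged = isTRUE(fit$converged)),
            class = "spore_glm_fit")
}

#' Fit a quasi-binomial logit GLM to sporulation counts
#'
#' Models the four-nuclei count \eqn{y_{i,k}} among \eqn{n_{i,k}} counted
#' cells with a binomial mean-variance relation scaled by a constant
#' dispersion \eqn{\phi} (quasi-likelihood), on the logit scale:
#' \deqn{\log \frac{\mu_{i,k}}{n_{i,k} - \mu_{i,k}} = x_{i,k}^\top \beta .}
#' Coefficients are obtained by iteratively reweighted least squares;
#' \eqn{\phi} is the Pearson chi-square divided by the residual degrees of
#' freedom, and the coefficient covariance is \eqn{\phi} times the inverse
#' Fisher information.
#'
#' @param counts a sporulation count table (see [as_sporulation_counts()]).
#' @param design numeric model matrix with one row per count record.
#' @return An object of class `"spore_glm_fit"` with elements
#'   `coefficients`, `covariance`, `dispersion`, `residual_df`, `converged`.
#' @examples
#' counts <- data.frame(strain = "a", replicate = 1:2, y = c(50, 60),
#'                      n = c(200, 200))
#' fit <- fit_quasibinomial(counts, design = cbind(intercept = c(1, 1)))
#' fit$coefficients  # equals qlogis(110/290)
#' @export
fit_quasibinomial <- function(counts, design) {
  counts <- as_sporulation_counts(counts)
  design <- as.matrix(design)
  if (nrow(design) != nrow(counts))
    stop_sporeffect("'design' must have one row per count record")
  qb_glm(counts$y, counts$n, design)
}

# t-test of a linear contrast c'beta of a quasi-binomial fit
qb_contrast_test <- function(fit, contrast) {
  if (!fit$converged)
    stop_sporeffect("GLM did not converge; test is not reliable")
  estimate <- sum(contrast * fit$coefficients)
  se <- sqrt(drop(t(contrast) %*% fit$covariance %*% contrast))
  t_stat <- estimate / se
  structure(list(estimate = estimate,
                 se = se,
                 t_stat = t_stat,
                 df = fit$residual_df,
                 p_value = 2 * pt(-abs(t_stat), df = fit$residual_df),
                 dispersion = fit$dispersion),
            class = "spore_test")
}

#' @export
print.spore_test <- function(x, ...) {
  cat(sprintf("log-odds contrast: %.4f (SE %.4f), t = %.3f on %d df, p = %.3g, phi = %.3f\n",
              x$estimate, x$se, x$t_stat, x$df, x$p_value, x$dispersion))
  invisible(x)
}

#' Pair test: equality of sporulation log-odds between two strains
#'
#' Fits a per-strain-intercept quasi-binomial GLM
#' \eqn{\mathrm{logit}(\mu_{i,k}/n_{i,k}) = \beta_i} to the replicate counts
#' of two strains and t-tests \eqn{H_0 : \beta_i = \beta_j}.  The reported
#' estimate is \eqn{\hat\beta_{\mathrm{strain1}} - \hat\beta_{\mathrm{strain2}}}
#' with `df = total records - 2`.
#'
#' @param counts count table holding both strains' replicates.
#' @param strain1,strain2 strain identifiers; default the two strains found
#'   in `counts` (in order of appearance).
#' @return A `"spore_test"` with `estimate`, `se`, `t_stat`, `df`,
#'   `p_value`, `dispersion`.
#' @export
pair_test <- function(counts, strain1 = NULL, strain2 = NULL) {
  counts <- as_sporulation_counts(counts)
  strains <- unique(counts$strain)
  if (is.null(strain1) && is.null(strain2)) {
    if (length(strains) != 2L)
      stop_sporeffect("pair_test needs exactly two strains (got ",
                      length(strains), "); name them explicitly")
    strain1 <- strains[1]; strain2 <- strains[2]
  }
  if (!all(c(strain1, strain2) %in% strains))
    stop_sporeffect("strain(s) not present in the count table")
  counts <- counts[counts$strain %in% c(strain1, strain2), , drop = FALSE]
  X <- cbind(as.numeric(counts$strain == strain1),
             as.numeric(counts$strain == strain2))
  colnames(X) <- c(strain1, strain2)
  fit <- qb_glm(counts$y, counts$n, X)
  qb_contrast_test(fit, c(1, -1))
}

#' Interaction test: is the double-mutant odds ratio multiplicative?
#'
#' Fits \eqn{\mathrm{logit}(\mu/n) = \beta_0 + \beta_A A + \beta_B B +
#' \beta_{A,B} A B} over the four strains of a 2x2 allele-by-mutation
#' design (reference background has \eqn{A = B = 0}) and t-tests
#' \eqn{H_0 : \beta_{A,B} = 0}, i.e. that the odds ratio of sporulation in
#' the double mutant equals the product of the single-mutation odds ratios.
#'
#' @param counts count table covering all four design cells.
#' @param coding data.frame with columns `strain`, `A`, `B` (0/1 indicator
#'   of each mutation per strain).
#' @return A `"spore_test"` for the interaction coefficient.
#' @export
interaction_test <- function(counts, coding) {
  counts <- as_sporulation_counts(counts)
  if (!all(c("strain", "A", "B") %in% names(coding)))
    stop_sporeffect("'coding' needs columns strain, A, B")
  coding$strain <- as.character(coding$strain)
  idx <- match(counts$strain, coding$strain)
  if (anyNA(idx))
    stop_sporeffect("strains without (A,B) coding: ",
                    paste(unique(counts$strain[is.na(idx)]), collapse = ", "))
  A <- as.numeric(coding$A[idx])
  B <- as.numeric(coding$B[idx])
  cells <- unique(paste(A, B))
  expected <- c("0 0", "1 0", "0 1", "1 1")
  missing_cell <- setdiff(expected, cells)
  if (length(missing_cell))
    stop_sporeffect("missing design cell(s) (A B): ",
                    paste(missing_cell, collapse = "; "))
  X <- cbind(intercept = 1, A = A, B = B, `A:B` = A * B)
  fit <- qb_glm(counts$y, counts$n, X)
  qb_contrast_test(fit, c(0, 0, 0, 1))
}

#' Fold difference between two strains' mean sporulation efficiencies
#'
#' The ratio of the replicate-mean sporulation efficiencies (mean of `y/n`)
#' of two strains, with the higher-sporulating strain in the numerator, so
#' the result is always \eqn{\ge 1} and symmetric in its arguments.
#'
#' @param counts_A,counts_B count tables for the two strains.
#' @return A single number \eqn{\ge 1}.
#' @export
fold_difference <- function(counts_A, counts_B) {
  counts_A <- as_sporulation_counts(counts_A)
  counts_B <- as_sporulation_counts(counts_B)
  m_A <- mean(counts_A$y / counts_A$n)
  m_B <- mean(counts_B$y / counts_B$n)
  if (min(m_A, m_B) == 0)
    stop_sporeffect("a strain has mean sporulation efficiency 0; ",
                    "fold difference is undefined")
  max(m_A, m_B) / min(m_A, m_B)
}
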