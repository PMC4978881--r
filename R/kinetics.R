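#' Construct and validate kinetic parameters
#'
#' Parameters of the delayed first-order meiotic progression model:
#' a delay `t0` (hours) before any cell initiates meiosis, a transition
#' rate `k1` (per hour) from G1/G0 into Meiosis I, a rate `k2` (per hour)
#' from MI into MII, and a competent fraction `f` of cells able to initiate
#' meiosis at all (terminal sporulation below 100%).
#'
#' @param t0 delay in hours, >= 0.
#' @param k1,k2 transition rates per hour, > 0.
#' @param f competent fraction in (0, 1].
#' @return A named list of class `"kinetic_params"`.
#' @export
kinetic_params <- function(t0, k1, k2, f) {
  check_number(t0, "t0", lower = 0)
  check_number(k1, "k1", lower = 0, allow_boundary = c(FALSE, TRUE))
  check_number(k2, "k2", lower = 0, allow_boundary = c(FALSE, TRUE))
  check_number(f, "f", lower = 0, upper = 1, allow_boundary = c(FALSE, TRUE))
  structure(list(t0 = unname(t0), k1 = unname(k1), k2 = unname(k2),
                 f = unname(f)), class = "kinetic_params")
}

#' Model probabilities of the one-, two- and four-nuclei states
#'
#' For the sequential compartment model G1/G0 -> MI -> MII with a shared
#' delay `t0` and competent fraction `f`, the state probabilities at time
#' `t` (with \eqn{\tau = \max(0, t - t_0)}) are
#' \deqn{p_1 = (1-f) + f e^{-k_1 \tau}}
#' \deqn{p_2 = f \frac{k_1}{k_2 - k_1}\left(e^{-k_1\tau} - e^{-k_2\tau}\right)}
#' (with the limit \eqn{f k_1 \tau e^{-k_1 \tau}} when \eqn{k_1 = k_2}) and
#' \eqn{p_4 = 1 - p_1 - p_2}.
#'
#' @param kin a [kinetic_params()] object (or coercible list).
#' @param t vector of times in hours, all >= 0.
#' @return Matrix with one row per time and columns `p1`, `p2`, `p4`;
#'   rows sum to 1.
#' @export
state_probabilities <- function(kin, t) {
  kin <- do.call(kinetic_params, unclass(kin)[c("t0", "k1", "k2", "f")])
  if (any(!is.finite(t)) || any(t < 0))
    stop_sporeffect("all times must be finite and >= 0")
  tau <- pmax(0, t - kin$t0)
  e1 <- exp(-kin$k1 * tau)
  p1 <- (1 - kin$f) + kin$f * e1
  if (abs(kin$k1 - kin$k2) < 1e-9) {
    p2 <- kin$f * kin$k1 * tau * e1
  } else {
    p2 <- kin$f * kin$k1 / (kin$k2 - kin$k1) * (e1 - exp(-kin$k2 * tau))
  }
  p4 <- 1 - p1 - p2
  p4[p4 < 0 & p4 > -1e-12] <- 0
  cbind(p1 = p1, p2 = p2, p4 = p4)
}

validate_nuclei_timecourse <- function(tc) {
  required <- c("time_h", "c1", "c2", "c4")
  missing_cols <- setdiff(required, names(tc))
  if (length(missing_cols))
    stop_sporeffect("nuclei time course is missing column(s): ",
                    paste(missing_cols, collapse = ", "))
  cnt <- as.matrix(tc[, c("c1", "c2", "c4")])
  if (any(!is.finite(cnt)) || any(cnt < 0))
    stop_sporeffect("nuclei counts must be finite and >= 0")
  if (any(rowSums(cnt) < 1))
    stop_sporeffect("every time point needs a total count >= 1")
  if (any(tc$time_h < 0)) stop_sporeffect("times must be >= 0")
  tc
}

kin_bounds_default <- function(times) {
  list(t0 = c(0, max(times)), k1 = c(1e-3, 10), k2 = c(1e-3, 10),
       f = c(0.01, 1))
}

# weighted least-squares objective on state fractions; inlined model
# evaluation (no validation) because this sits in the optimizer hot loop
kin_objective <- function(par, times, frac, wt) {
  tau <- pmax(0, times - par[1])
  k1 <- par[2]; k2 <- par[3]; f <- par[4]
  e1 <- exp(-k1 * tau)
  p1 <- (1 - f) + f * e1
  p2 <- if (abs(k1 - k2) < 1e-9) f * k1 * tau * e1
        else f * k1 / (k2 - k1) * (e1 - exp(-k2 * tau))
  sum(wt * ((frac[, 1] - p1)^2 + (frac[, 2] - p2)^2 +
              (frac[, 3] - (1 - p1 - p2))^2))
}

kin_to_unit <- function(par, lb, ub) qlogis(pmin(pmax((par - lb) / (ub - lb),
                                                      1e-9), 1 - 1e-9))
kin_from_unit <- function(x, lb, ub) lb + (ub - lb) * plogis(x)

# one Nelder-Mead run on the box-transformed scale; optional restart from
# the optimum polishes the simplex (it collapses near minima at zero)
kin_optim_once <- function(start, times, frac, wt, lb, ub, polish = FALSE) {
  obj <- function(x) kin_objective(kin_from_unit(x, lb, ub), times, frac, wt)
  o <- optim(kin_to_unit(start, lb, ub), obj, method = "Nelder-Mead",
             control = list(maxit = 600, reltol = 1e-10))
  if (polish)
    o <- optim(o$par, obj, method = "Nelder-Mead",
               control = list(maxit = 600, reltol = 1e-12))
  list(par = kin_from_unit(o$par, lb, ub), value = o$value,
       convergence = o$convergence)
}

#' Fit the delayed first-order kinetic model to a nuclei time course
#'
#' Minimizes the count-weighted least-squares discrepancy between observed
#' state fractions and model probabilities,
#' \eqn{\sum_t n_t \sum_{s} (\hat f_{s,t} - p_s(t))^2}, over
#' `(t0, k1, k2, f)` inside a bounds box.  Optimization is a derivative-free
#' simplex started from `n_starts` deterministic Halton points in the box
#' plus a moment-style heuristic start; the fit is therefore deterministic.
#'
#' @param tc data.frame with columns `time_h`, `c1`, `c2`, `c4` (counts of
#'   one-/two-/four-nuclei cells; replicate rows at the same time are
#'   allowed and enter with their own weights).
#' @param bounds named list of length-2 ranges for `t0`, `k1`, `k2`, `f`;
#'   default `t0` in `[0, max(time)]`, rates in `[1e-3, 10]`, `f` in
#'   `[0.01, 1]`.
#' @param n_starts number of multistart locations (default 20).
#' @return List of class `"kinetic_fit"`: `params` ([kinetic_params()]),
#'   `objective` (residual weighted sum of squares), `flagged` (TRUE when
#'   the optimizer failed or a parameter sits on a bound), `flag_reason`.
#' @export
fit_kinetics <- function(tc, bounds = NULL, n_starts = 20) {
  tc <- validate_nuclei_timecourse(tc)
  if (length(unique(tc$time_h)) < 5L)
    stop_sporeffect("need at least 5 distinct time points to fit 4 parameters")
  times <- tc$time_h
  cnt <- as.matrix(tc[, c("c1", "c2", "c4")])
  tot <- rowSums(cnt)
  frac <- cnt / tot
  bounds <- bounds %||% kin_bounds_default(times)
  lb <- vapply(bounds, `[`, numeric(1), 1L)
  ub <- vapply(bounds, `[`, numeric(1), 2L)

  # heuristic start: f from the terminal four-nuclei fraction, t0 from the
  # last time the one-nucleus fraction is still near 1
  f0 <- min(ub[4], max(lb[4], max(frac[, 3]) + 0.05))
  drop_t <- times[frac[, 1] < 0.95]
  t00 <- min(ub[1], max(lb[1], if (length(drop_t)) 0.8 * min(drop_t) else
    stats::median(times)))
  starts <- rbind(c(t00, 0.3, 0.3, f0),
                  sweep(sweep(halton_sequence(n_starts, 4), 2, ub - lb, `*`),
                        2, lb, `+`))

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- kin_optim_once(starts[i, ], times, frac, tot, lb, ub)
    if (is.null(best) || res$value < best$value) best <- res
  }
  best <- kin_optim_once(best$par, times, frac, tot, lb, ub, polish = TRUE)
  par <- best$par
  rel_edge <- pmin(par - lb, ub - par) / (ub - lb)
  on_bound <- rel_edge < 1e-3
  flagged <- best$convergence != 0 || any(on_bound)
  reason <- c(if (best$convergence != 0) "optimizer did not converge",
              if (any(on_bound))
                paste("parameter(s) at bound:",
                      paste(c("t0", "k1", "k2", "f")[on_bound], collapse = ", ")))
  structure(list(params = kinetic_params(par[1], par[2], par[3], par[4]),
                 objective = best$value,
                 flagged = flagged,
                 flag_reason = reason,
                 convergence = best$convergence,
                 bounds = bounds, times = times),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("delayed first-order kinetics: t0 = %.3f h, k1 = %.4f /h, k2 = %.4f /h, f = %.3f\n",
              p$t0, p$k1, p$k2, p$f))
  cat(sprintf("weighted RSS = %.4g%s\n", x$objective,
              if (x$flagged) paste0("  [flagged: ",
                                    paste(x$flag_reason, collapse = "; "), "]")
              else ""))
  invisible(x)
}

#' Bootstrap uncertainty for the kinetic fit
#'
#' Parametric multinomial bootstrap: cells at each time point are resampled
#' from the observed state fractions, the model is refitted to each
#' resample (started from the point estimate), and percentile confidence
#' intervals are formed.
#'
#' @param tc nuclei time course (see [fit_kinetics()]).
#' @param B number of bootstrap draws (>= 100).
#' @param level confidence level for the percentile intervals.
#' @param seed integer seed; fixed seeds give identical draws.
#' @param point optional precomputed [fit_kinetics()] result.
#' @return List of class `"kinetic_bootstrap"`: `draws` (B x 4 matrix),
#'   `ci` (2 x 4 percentile bounds), `point`, `n_failed`.
#' @export
bootstrap_kinetics <- function(tc, B = 200, level = 0.95, seed = NULL,
                               point = NULL) {
  tc <- validate_nuclei_timecourse(tc)
  if (B < 100) stop_sporeffect("'B' must be at least 100")
  check_number(level, "level", lower = 0, upper = 1,
               allow_boundary = c(FALSE, FALSE))
  set_seed_if(seed)
  point <- point %||% fit_kinetics(tc)
  times <- tc$time_h
  cnt <- as.matrix(tc[, c("c1", "c2", "c4")])
  tot <- rowSums(cnt)
  frac <- cnt / tot
  lb <- vapply(point$bounds, `[`, numeric(1), 1L)
  ub <- vapply(point$bounds, `[`, numeric(1), 2L)
  start <- unlist(point$params)

  draws <- matrix(NA_real_, B, 4,
                  dimnames = list(NULL, c("t0", "k1", "k2", "f")))
  failed <- logical(B)
  for (b in seq_len(B)) {
    res_cnt <- t(vapply(seq_along(times),
                        function(i) drop(rmultinom(1, tot[i], frac[i, ])),
                        numeric(3)))
    fb <- res_cnt / rowSums(res_cnt)
    fit_b <- kin_optim_once(start, times, fb, tot, lb, ub)
    failed[b] <- fit_b$convergence != 0
    draws[b, ] <- fit_b$par
  }
  if (mean(failed) > 0.10)
    stop_sporeffect(sprintf("bootstrap unstable: %d of %d refits failed",
                            sum(failed), B))
  ok <- draws[!failed, , drop = FALSE]
  alpha <- (1 - level) / 2
  ci <- apply(ok, 2, quantile, probs = c(alpha, 1 - alpha), names = FALSE)
  rownames(ci) <- c("lower", "upper")
  structure(list(draws = ok, ci = ci, point = point, level = level,
                 n_failed = sum(failed)),
            class = "kinetic_bootstrap")
}

#' Compare kinetic parameters of two strains by bootstrap
#'
#' Fits both time courses, bootstraps each independently, and forms the
#' difference distribution from paired independent draws.  The two-sided
#' bootstrap p-value uses a +1 continuity numerator:
#' \eqn{p = 2\min\{(1 + \#\{d \le 0\})/(B+1), (1 + \#\{d \ge 0\})/(B+1)\}},
#' capped at 1.
#'
#' @param tc_A,tc_B nuclei time courses for the two strains.
#' @param B bootstrap draws per strain.
#' @param level confidence level for percentile intervals of the difference.
#' @param seed integer seed.
#' @return data.frame with one row per parameter: point difference (A - B),
#'   percentile CI and bootstrap p-value.
#' @export
compare_kinetics <- function(tc_A, tc_B, B = 500, level = 0.95, seed = NULL) {
  set_seed_if(seed)
  boot_A <- bootstrap_kinetics(tc_A, B = B, level = level)
  boot_B <- bootstrap_kinetics(tc_B, B = B, level = level)
  m <- min(nrow(boot_A$draws), nrow(boot_B$draws))
  d <- boot_A$draws[seq_len(m), , drop = FALSE] -
    boot_B$draws[seq_len(m), , drop = FALSE]
  point <- unlist(boot_A$point$params) - unlist(boot_B$point$params)
  alpha <- (1 - level) / 2
  res <- data.frame(
    parameter = colnames(d),
    difference = point,
    lower = apply(d, 2, quantile, probs = alpha, names = FALSE),
    upper = apply(d, 2, quantile, probs = 1 - alpha, names = FALSE),
    p_value = vapply(seq_len(ncol(d)), function(j) {
      min(1, 2 * min((1 + sum(d[, j] <= 0)) / (m + 1),
                     (1 + sum(d[, j] >= 0)) / (m + 1)))
    }, numeric(1)),
    row.names = NULL)
  res
}
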