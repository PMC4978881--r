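#' Parameters for simulating replicate sporulation counts
#'
#' The generative mirror of the quasi-binomial tests: each strain's
#' replicate success probability is drawn from a beta distribution whose
#' mean is the inverse-logit of the linear predictor
#' \eqn{\beta_0 + \beta_A A + \beta_B B + \beta_{A,B} A B} and whose
#' intra-class correlation is `rho`; the replicate count is then binomial.
#' `rho = 0` degenerates to a pure binomial.
#'
#' @param baseline_logit log-odds of sporulation in the reference
#'   background.
#' @param effect_A,effect_B,effect_AB additive log-odds effects of the
#'   allele indicator A, the deletion indicator B and their product.
#' @param rho beta-binomial intra-class correlation in `[0, 1)`.
#' @param n_cells cells counted per replicate (default 300, the study's
#'   counting depth).
#' @param n_reps replicates per strain (default 6: two experiments of
#'   three biological replicates).
#' @return Validated list of class `"spor_sim_params"`.
#' @export
spor_sim_params <- function(baseline_logit = 0, effect_A = 0, effect_B = 0,
                            effect_AB = 0, rho = 0.02, n_cells = 300,
                            n_reps = 6) {
  check_number(baseline_logit, "baseline_logit")
  check_number(effect_A, "effect_A")
  check_number(effect_B, "effect_B")
  check_number(effect_AB, "effect_AB")
  check_number(rho, "rho", lower = 0, upper = 1,
               allow_boundary = c(TRUE, FALSE))
  check_number(n_cells, "n_cells", lower = 1)
  check_number(n_reps, "n_reps", lower = 1)
  structure(list(baseline_logit = baseline_logit, effect_A = effect_A,
                 effect_B = effect_B, effect_AB = effect_AB, rho = rho,
                 n_cells = as.integer(n_cells), n_reps = as.integer(n_reps)),
            class = "spor_sim_params")
}

#' Simulate beta-binomial sporulation count tables
#'
#' @param params a [spor_sim_params()] object.
#' @param design data.frame with columns `strain`, `A`, `B` (one row per
#'   strain; 0/1 mutation indicators).
#' @param seed integer seed; identical seeds give identical tables.
#' @return A sporulation count table (columns `strain`, `replicate`, `A`,
#'   `B`, `y`, `n`).
#' @export
simulate_sporulation_counts <- function(params, design, seed = NULL) {
  if (!inherits(params, "spor_sim_params")) params <- do.call(spor_sim_params, params)
  if (nrow(design) == 0L) stop_sporeffect("'design' must be non-empty")
  if (!all(c("strain", "A", "B") %in% names(design)))
    stop_sporeffect("'design' needs columns strain, A, B")
  set_seed_if(seed)
  out <- lapply(seq_len(nrow(design)), function(i) {
    eta <- params$baseline_logit +
      params$effect_A * design$A[i] +
      params$effect_B * design$B[i] +
      params$effect_AB * design$A[i] * design$B[i]
    m <- plogis(eta)
    p <- if (params$rho == 0) rep(m, params$n_reps) else {
      s <- (1 - params$rho) / params$rho
      rbeta(params$n_reps, m * s, (1 - m) * s)
    }
    data.frame(strain = as.character(design$strain[i]),
               replicate = seq_len(params$n_reps),
               A = design$A[i], B = design$B[i],
               y = rbinom(params$n_reps, params$n_cells, p),
               n = params$n_cells)
  })
  as_sporulation_counts(do.call(rbind, out))
}

#' Simulate a multinomial nuclei-state time course
#'
#' Draws, at each requested time, `n_cells_per_time` cells from the
#' multinomial over the one-/two-/four-nuclei states given by
#' [state_probabilities()].
#'
#' @param kin a [kinetic_params()] object.
#' @param times sampling times in hours (default 0 to 24 h every 2 h).
#' @param n_cells_per_time cells scored per time point (default 300).
#' @param seed integer seed.
#' @return data.frame with columns `time_h`, `c1`, `c2`, `c4`.
#' @export
simulate_nuclei_timecourse <- function(kin, times = seq(0, 24, by = 2),
                                       n_cells_per_time = 300, seed = NULL) {
  P <- state_probabilities(kin, times)   # also validates kin and times
  check_number(n_cells_per_time, "n_cells_per_time", lower = 0)
  set_seed_if(seed)
  cnt <- if (n_cells_per_time == 0) {
    matrix(0L, length(times), 3)
  } else {
    t(vapply(seq_along(times),
             function(i) drop(rmultinom(1, n_cells_per_time, P[i, ])),
             numeric(3)))
  }
  data.frame(time_h = times, c1 = cnt[, 1], c2 = cnt[, 2], c4 = cnt[, 3])
}

#' The study's nine-point logarithmic sampling grid (hours)
#'
#' 0 h, 30 min, 45 min, 1 h 10 min, 1 h 40 min, 2 h 30 min, 3 h 50 min,
#' 5 h 40 min and 8 h 30 min after transfer to sporulation medium.
#'
#' @return Numeric vector of nine times in hours.
#' @export
sporulation_times <- function() {
  c(0, 1/2, 3/4, 7/6, 5/3, 5/2, 23/6, 17/3, 17/2)
}

trend_archetypes <- function() c("early", "increasing", "late", "repressing", "flat")

#' Noise-free temporal trend archetype curves
#'
#' The qualitative trend morphologies used by the expression simulator and
#' recovered by [cluster_genes()], anchored at 0 at `t = 0`:
#' * `early` — rise completed within the first third of the time range,
#'   then plateau;
#' * `increasing` — monotone rise over the full range;
#' * `late` — flat for the first half, then rise;
#' * `repressing` — monotone decline;
#' * `flat` — constant 0.
#'
#' @param type archetype name.
#' @param times time grid in hours.
#' @param amplitude total log2-unit change (default 2).
#' @return Numeric vector of curve values at `times`.
#' @export
archetype_curve <- function(type = trend_archetypes(), times, amplitude = 2) {
  type <- match.arg(type)
  t0 <- min(times); Tr <- max(times) - t0
  s <- (times - t0) / Tr
  switch(type,
         early = amplitude * pmin(1, s * 3),
         increasing = amplitude * s,
         late = amplitude * pmax(0, (s - 0.5) * 2),
         repressing = -amplitude * s,
         flat = rep(0, length(times)))
}

#' Specification for a two-strain expression simulation
#'
#' @param n_genes number of genes.
#' @param times sampling grid in hours (default [sporulation_times()]);
#'   must be strictly increasing and start at 0.
#' @param diff_fraction fraction of genes with strain-specific curves.
#' @param noise_sd Gaussian noise SD on log2 values.
#' @param amplitude trend amplitude in log2 units.
#' @param archetype_assignment optional per-gene archetype for strain 1
#'   (`"auto"` cycles differential genes through the four trend
#'   archetypes and leaves the rest flat).
#' @param regulon_enrichment named list of planted regulons, each a list
#'   with elements `or` (target-membership odds ratio inside the designated
#'   cluster) and `cluster` (an archetype name).
#' @param n_tfs number of unplanted background regulons.
#' @param target_rate baseline probability that a gene belongs to a
#'   regulon.
#' @return Validated list of class `"expr_sim_spec"`.
#' @export
expr_sim_spec <- function(n_genes = 2000, times = sporulation_times(),
                          diff_fraction = 0.10, noise_sd = 0.2,
                          amplitude = 2, archetype_assignment = "auto",
                          regulon_enrichment = list(), n_tfs = 10,
                          target_rate = 0.10) {
  check_number(n_genes, "n_genes", lower = 1)
  if (length(times) < 4L || is.unsorted(times, strictly = TRUE) ||
      times[1] != 0)
    stop_sporeffect("'times' must be strictly increasing with times[1] = 0")
  check_number(diff_fraction, "diff_fraction", lower = 0, upper = 1)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(amplitude, "amplitude", lower = 0)
  if (!identical(archetype_assignment, "auto")) {
    if (length(archetype_assignment) != n_genes ||
        !all(archetype_assignment %in% trend_archetypes()))
      stop_sporeffect("'archetype_assignment' must be 'auto' or one valid ",
                      "archetype per gene")
  }
  structure(list(n_genes = as.integer(n_genes), times = times,
                 diff_fraction = diff_fraction, noise_sd = noise_sd,
                 amplitude = amplitude,
                 archetype_assignment = archetype_assignment,
                 regulon_enrichment = regulon_enrichment,
                 n_tfs = as.integer(n_tfs), target_rate = target_rate),
            class = "expr_sim_spec")
}

#' Simulate a two-strain expression pair with planted truth
#'
#' Differential genes carry a trend archetype curve in strain 1; in strain
#' 2 they are flat, except genes with an early trend, which are repressed
#' in strain 2 (mirroring early carbohydrate/mitochondrial genes of the
#' high-sporulating background being repressed in the low one).
#' Non-differential genes share one curve in both strains.  Gene-specific
#' baseline log2 levels are added so that the baseline transformation is
#' exercised; Gaussian noise is independent per strain, gene and time.
#' Planted regulons are Bernoulli memberships whose in-cluster odds are
#' `or` times the out-of-cluster odds.
#'
#' @param spec an [expr_sim_spec()].
#' @param seed integer seed.
#' @return List with `strain1`, `strain2` (raw [expression_series()]
#'   objects), `truth` (per-gene planted labels and regulon memberships)
#'   and `regulons` (named list of target-gene vectors).
#' @export
simulate_expression_pair <- function(spec, seed = NULL) {
  if (!inherits(spec, "expr_sim_spec")) spec <- do.call(expr_sim_spec, spec)
  set_seed_if(seed)
  G <- spec$n_genes
  genes <- sprintf("g%04d", seq_len(G))
  n_diff <- round(spec$diff_fraction * G)
  differential <- rep(FALSE, G)
  if (n_diff > 0) differential[sample.int(G, n_diff)] <- TRUE

  if (identical(spec$archetype_assignment, "auto")) {
    arch1 <- rep("flat", G)
    arch1[differential] <- rep(c("early", "increasing", "late", "repressing"),
                               length.out = n_diff)
  } else arch1 <- spec$archetype_assignment
  arch2 <- arch1
  arch2[differential] <- ifelse(arch1[differential] == "early",
                                "repressing", "flat")

  curves <- vapply(trend_archetypes(),
                   archetype_curve, numeric(length(spec$times)),
                   times = spec$times, amplitude = spec$amplitude)
  baseline <- rnorm(G, mean = 7, sd = 1)
  make_strain <- function(arch) {
    M <- t(curves[, arch, drop = FALSE]) + baseline +
      if (spec$noise_sd > 0)
        matrix(rnorm(G * length(spec$times), sd = spec$noise_sd),
               G, length(spec$times)) else 0
    rownames(M) <- genes
    expression_series(M, spec$times, stage = "raw")
  }
  strain1 <- make_strain(arch1)
  strain2 <- make_strain(arch2)

  # regulons: planted TFs enriched in their designated archetype class,
  # background TFs at the baseline rate everywhere
  o0 <- spec$target_rate / (1 - spec$target_rate)
  regulons <- list()
  truth <- data.frame(gene = genes, differential = differential,
                      archetype_strain1 = arch1, archetype_strain2 = arch2,
                      stringsAsFactors = FALSE)
  for (tf in names(spec$regulon_enrichment)) {
    pl <- spec$regulon_enrichment[[tf]]
    in_cluster <- differential & arch1 == pl$cluster
    odds <- ifelse(in_cluster, pl$or * o0, o0)
    member <- runif(G) < odds / (1 + odds)
    regulons[[tf]] <- genes[member]
    truth[[paste0("target_", tf)]] <- member
  }
  if (spec$n_tfs > 0) {
    for (i in seq_len(spec$n_tfs)) {
      tf <- sprintf("bgTF%02d", i)
      member <- runif(G) < spec$target_rate
      regulons[[tf]] <- genes[member]
      truth[[paste0("target_", tf)]] <- member
    }
  }
  list(strain1 = strain1, strain2 = strain2, truth = truth,
       regulons = regulons)
}
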