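# shared fixtures and independent oracles

make_counts <- function(strain, y, n) {
  data.frame(strain = strain, replicate = seq_along(y), y = y, n = n)
}

# pooled-logit oracle for saturated (per-strain-intercept) binomial GLMs
oracle_pooled_logit <- function(y, n) qlogis(sum(y) / sum(n))

# truth labels for clustering comparisons: flat genes should come out
# unclassified
truth_labels <- function(truth, col = "archetype_strain1") {
  ifelse(truth[[col]] == "flat", "unclassified", truth[[col]])
}

# four-cell mediator panel generator with planted effect classes
simulate_panel <- function(classes, baseline_logit = 0.4, effect_A = -1.5,
                           rho = 0.02, n_reps = 6, n_cells = 300) {
  design <- data.frame(strain = c("wt_high", "wt_low"),
                       background = c("high", "low"), deletion = "none")
  counts <- list(simulate_sporulation_counts(
    spor_sim_params(baseline_logit = baseline_logit, effect_A = effect_A,
                    rho = rho, n_reps = n_reps, n_cells = n_cells),
    data.frame(strain = c("wt_high", "wt_low"), A = c(0, 1), B = 0)))
  for (g in names(classes)) {
    prm <- spor_sim_params(baseline_logit = baseline_logit,
                           effect_A = effect_A,
                           effect_B = classes[[g]][1],
                           effect_AB = classes[[g]][2],
                           rho = rho, n_reps = n_reps, n_cells = n_cells)
    dsn <- data.frame(strain = paste0(c("del_high_", "del_low_"), g),
                      A = c(0, 1), B = 1)
    counts[[g]] <- simulate_sporulation_counts(prm, dsn)
    design <- rbind(design,
                    data.frame(strain = dsn$strain,
                               background = c("high", "low"), deletion = g))
  }
  counts <- do.call(rbind, counts)[, c("strain", "replicate", "y", "n")]
  list(counts = counts, design = design)
}
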