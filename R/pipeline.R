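#' Default pipeline configuration
#'
#' All stage parameters with their defaults; input paths must be filled in
#' before [pipeline_run()].  Configurations round-trip losslessly through
#' YAML.
#'
#' @param ... overrides of the defaults.
#' @return Named list of class `"run_config"`.
#' @export
default_config <- function(...) {
  cfg <- list(
    expression_strain1 = NULL,    # genes x times TSV, strain 1
    expression_strain2 = NULL,    # genes x times TSV, strain 2
    regulons_gmt = NULL,          # TF regulon gene sets
    counts_tsv = NULL,            # optional mediator-screen counts
    mediator_design_tsv = NULL,   # strain -> (background, deletion)
    out_dir = "sporeffect_out",
    h = 1.2,                      # smoothing bandwidth, hours
    basis_df = 2,                 # spline df of the differential test
    fdr = 0.10,                   # q-value cutoff
    n_null = 50,                  # permutation datasets
    epsilon = 0.25,               # trend symbol threshold, log2 units
    p_cut = 0.05, or_cut = 1.5,   # regulon-enrichment thresholds
    alpha = 0.05,                 # mediator-test level
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop_sporeffect("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read / write a pipeline configuration
#'
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_sporeffect("config not found: ", path)
  do.call(default_config, yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config a [default_config()] list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

write_manifest <- function(config, path) {
  lines <- c(sprintf("package: sporeffect %s",
                     as.character(packageVersion("sporeffect"))),
             vapply(names(config), function(k)
               sprintf("%s: %s", k,
                       paste(format(config[[k]]), collapse = " ")),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Run the full expression-to-mediators pipeline
#'
#' Executes the analysis stages in their fixed order — smooth, base
#' transform, differential-temporal test, trend clustering of the
#' significant genes, regulon enrichment per cluster, and (when count data
#' are configured) the mediator screen — writing every stage's table and a
#' run manifest into `out_dir`.  Two runs with identical configuration and
#' seeds produce identical output files.
#'
#' @param config a [default_config()] list or the path of a YAML config.
#' @return Invisibly, a list with the in-memory stage results and the
#'   output paths.
#' @export
pipeline_run <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  needed <- c("expression_strain1", "expression_strain2", "regulons_gmt")
  for (k in needed)
    if (is.null(config[[k]]))
      stop_sporeffect("config field '", k, "' is required")
  paths <- unlist(config[c(needed, "counts_tsv", "mediator_design_tsv")])
  missing_in <- paths[!file.exists(paths)]
  if (length(missing_in))
    stop_sporeffect("input file(s) not found: ",
                    paste(missing_in, collapse = ", "))
  with_mediators <- !is.null(config$counts_tsv)
  if (with_mediators && is.null(config$mediator_design_tsv))
    stop_sporeffect("'mediator_design_tsv' is required with 'counts_tsv'")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_sporeffect("stage '", name, "' failed: ", conditionMessage(e)))
  }
  s1 <- stage("read", read_expression_tsv(config$expression_strain1))
  s2 <- stage("read", read_expression_tsv(config$expression_strain2))
  regulons <- stage("read", read_gmt(config$regulons_gmt))

  sm1 <- stage("smooth", base_transform(smooth_expression(s1, h = config$h)))
  sm2 <- stage("smooth", base_transform(smooth_expression(s2, h = config$h)))
  write_expression_tsv(sm1, file.path(config$out_dir, "expression_strain1_transformed.tsv"))
  write_expression_tsv(sm2, file.path(config$out_dir, "expression_strain2_transformed.tsv"))

  # the differential test runs on unsmoothed base-transformed curves (its
  # spline basis does the smoothing; pre-smoothing decalibrates the
  # permutation null); the smoothed curves feed the trend abstraction
  de <- stage("diff_temporal_test",
              diff_temporal_test(base_transform(s1), base_transform(s2),
                                 basis_df = config$basis_df,
                                 n_null = config$n_null, seed = config$seed,
                                 fdr = config$fdr))
  write_tsv(de, file.path(config$out_dir, "differential_expression.tsv"))

  sig <- de$gene[de$significant]
  keep1 <- expression_series(sm1$values[sig, , drop = FALSE], sm1$times,
                             stage = "base_transformed")
  cl <- stage("cluster", cluster_genes(keep1, epsilon = config$epsilon))
  write_tsv(cl$labels, file.path(config$out_dir, "trend_labels.tsv"))
  write_gene_lists(cl$clusters, file.path(config$out_dir, "clusters"))

  enr <- stage("enrichment",
               candidate_regulators(cl$clusters[c("early", "increasing",
                                                  "late", "repressing")],
                                    regulons,
                                    universe = rownames(s1$values),
                                    p_cut = config$p_cut,
                                    or_cut = config$or_cut))
  write_tsv(enr, file.path(config$out_dir, "regulon_enrichment.tsv"))

  calls <- NULL
  if (with_mediators) {
    counts <- stage("read", read_counts_tsv(config$counts_tsv))
    design <- stage("read", read_tsv_checked(config$mediator_design_tsv,
                                             c("strain", "background",
                                               "deletion")))
    calls <- stage("mediator_screen",
                   screen_candidates(counts, design, alpha = config$alpha))
    write_tsv(calls, file.path(config$out_dir, "mediator_calls.tsv"))
  }
  write_manifest(config, file.path(config$out_dir, "run_manifest.txt"))
  invisible(list(differential = de, clusters = cl, enrichment = enr,
                 mediator_calls = calls, out_dir = config$out_dir))
}

#' Write a complete synthetic input bundle plus configuration
#'
#' Generates every pipeline input with [simulate_expression_pair()] and
#' [simulate_sporulation_counts()], writes them as TSV/GMT under `dir`,
#' and returns the path of a ready-to-run YAML configuration.  Useful for
#' smoke tests and worked examples.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @param n_genes number of simulated genes.
#' @param noise_sd expression noise SD.
#' @param planted_or odds ratio of the planted regulon in the early
#'   cluster.
#' @return Path of the written `config.yaml`.
#' @export
write_synthetic_bundle <- function(dir, seed = 1, n_genes = 400,
                                   noise_sd = 0.2, planted_or = 5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- expr_sim_spec(n_genes = n_genes, noise_sd = noise_sd,
                        regulon_enrichment = list(
                          plantedTF = list(or = planted_or,
                                           cluster = "early")))
  sim <- simulate_expression_pair(spec, seed = seed)
  write_expression_tsv(sim$strain1, file.path(dir, "expression_strain1.tsv"))
  write_expression_tsv(sim$strain2, file.path(dir, "expression_strain2.tsv"))
  write_gmt(sim$regulons, file.path(dir, "regulons.gmt"))
  write_tsv(sim$truth, file.path(dir, "truth.tsv"))

  # allele-by-deletion panel: one mediator, one allele-independent,
  # one no-effect gene
  panel <- list(medA = c(-1.5, 1.5), indB = c(-1.5, 0), nulC = c(0, 0))
  counts <- list(); design <- list()
  wt <- simulate_sporulation_counts(
    spor_sim_params(baseline_logit = 0.4, effect_A = -1.5),
    data.frame(strain = c("wt_high", "wt_low"), A = c(0, 1), B = 0),
    seed = seed + 1)
  counts[["wt"]] <- wt
  design[["wt"]] <- data.frame(strain = c("wt_high", "wt_low"),
                               background = c("high", "low"),
                               deletion = "none")
  for (i in seq_along(panel)) {
    g <- names(panel)[i]
    prm <- spor_sim_params(baseline_logit = 0.4, effect_A = -1.5,
                           effect_B = panel[[g]][1],
                           effect_AB = panel[[g]][2])
    dsn <- data.frame(strain = paste0(c("del_high_", "del_low_"), g),
                      A = c(0, 1), B = 1)
    counts[[g]] <- simulate_sporulation_counts(prm, dsn, seed = seed + 1 + i)
    design[[g]] <- data.frame(strain = dsn$strain,
                              background = c("high", "low"), deletion = g)
  }
  counts <- do.call(rbind, counts)
  counts <- counts[, c("strain", "replicate", "y", "n")]
  write_counts_tsv(counts, file.path(dir, "sporulation_counts.tsv"))
  write_tsv(do.call(rbind, design), file.path(dir, "mediator_design.tsv"))

  tc <- simulate_nuclei_timecourse(kinetic_params(8, 0.25, 0.5, 0.65),
                                   seed = seed + 9)
  write_nuclei_tsv(tc, file.path(dir, "nuclei_timecourse.tsv"))

  cfg <- default_config(
    expression_strain1 = file.path(dir, "expression_strain1.tsv"),
    expression_strain2 = file.path(dir, "expression_strain2.tsv"),
    regulons_gmt = file.path(dir, "regulons.gmt"),
    counts_tsv = file.path(dir, "sporulation_counts.tsv"),
    mediator_design_tsv = file.path(dir, "mediator_design.tsv"),
    out_dir = file.path(dir, "out"),
    seed = as.integer(seed))
  write_run_config(cfg, file.path(dir, "config.yaml"))
  file.path(dir, "config.yaml")
}
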