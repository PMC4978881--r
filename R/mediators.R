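#' Classify one candidate gene from an allele-by-deletion design
#'
#' The genetic decision model for allele-specific mediation: with counts
#' for the wild type and the candidate deletion in both the
#' high-sporulating ("high") and low-sporulating ("low") backgrounds,
#' three quasi-binomial tests are run — the deletion pair test in each
#' background and the allele-by-deletion interaction test (high wild type
#' as reference) — and combined:
#'
#' * no significant deletion effect in the high background ->
#'   `no_effect` (the gene tracks genotype or phenotype without mediating
#'   it);
#' * deletion significantly *lowers* the high background AND the
#'   interaction is significant -> `mediator` (the deletion effect depends
#'   on the allele);
#' * deletion significantly lowers both backgrounds and the interaction is
#'   not significant -> `allele_independent`;
#' * any other pattern -> `ambiguous`.
#'
#' "Lowers" is enforced by the sign of the deletion-effect estimate, not
#' just its significance.
#'
#' @param wt_hi,wt_lo,del_hi,del_lo count tables for the four design cells
#'   (wild type / deletion in the high / low background), each with at
#'   least 2 replicates.
#' @param alpha per-test significance level (default 0.05; the three
#'   tests within a gene are not multiplicity-corrected).
#' @param gene optional gene id carried into the result.
#' @return List of class `"mediator_call"`: `gene`, `call`, `tests` (the
#'   three `"spore_test"` results), `alpha`.
#' @export
classify_mediator <- function(wt_hi, wt_lo, del_hi, del_lo, alpha = 0.05,
                              gene = NA_character_) {
  check_number(alpha, "alpha", lower = 0, upper = 1)
  cells <- list(wt_hi = wt_hi, wt_lo = wt_lo, del_hi = del_hi,
                del_lo = del_lo)
  for (nm in names(cells)) {
    cells[[nm]] <- as_sporulation_counts(cells[[nm]])
    if (nrow(cells[[nm]]) < 2L)
      stop_sporeffect("design cell '", nm, "' needs at least 2 replicates")
    cells[[nm]]$strain <- nm   # normalize ids to the design role
  }
  test_hi <- pair_test(rbind(cells$del_hi, cells$wt_hi), "del_hi", "wt_hi")
  test_lo <- pair_test(rbind(cells$del_lo, cells$wt_lo), "del_lo", "wt_lo")
  all4 <- do.call(rbind, cells)
  coding <- data.frame(strain = c("wt_hi", "wt_lo", "del_hi", "del_lo"),
                       A = c(0, 1, 0, 1),   # low-background allele
                       B = c(0, 0, 1, 1))   # deletion
  test_int <- interaction_test(all4, coding)

  sig_hi <- test_hi$p_value <= alpha
  sig_lo <- test_lo$p_value <= alpha
  sig_int <- test_int$p_value <= alpha
  call <- if (!sig_hi) "no_effect"
  else if (test_hi$estimate < 0 && sig_int) "mediator"
  else if (test_hi$estimate < 0 && sig_lo && test_lo$estimate < 0 &&
           !sig_int) "allele_independent"
  else "ambiguous"
  structure(list(gene = gene, call = call,
                 tests = list(deletion_high = test_hi,
                              deletion_low = test_lo,
                              interaction = test_int),
                 alpha = alpha),
            class = "mediator_call")
}

#' @export
print.mediator_call <- function(x, ...) {
  cat(sprintf("%s: %s (del|high p = %.3g, del|low p = %.3g, interaction p = %.3g, alpha = %g)\n",
              x$gene, x$call, x$tests$deletion_high$p_value,
              x$tests$deletion_low$p_value, x$tests$interaction$p_value,
              x$alpha))
  invisible(x)
}

#' Screen a panel of candidate genes for allele-specific mediation
#'
#' Applies [classify_mediator()] to every gene of an allele-by-deletion
#' panel.  Wild-type strains (deletion `"none"`) in both backgrounds are
#' shared across genes.
#'
#' @param counts count table covering the wild types and every deletion in
#'   both backgrounds.
#' @param design data.frame mapping `strain` to `background` (`"high"` or
#'   `"low"`) and `deletion` (gene id, or `"none"` for wild type).
#' @param alpha per-test significance level.
#' @param adjust if `TRUE`, Holm-adjust the three p-value columns across
#'   genes before applying the decision table.
#' @return data.frame with one row per gene: `gene`, `call`, the three
#'   estimates and p-values, and `alpha`.  Genes missing a design cell are
#'   skipped with a warning.
#' @export
screen_candidates <- function(counts, design, alpha = 0.05, adjust = FALSE) {
  counts <- as_sporulation_counts(counts)
  if (!all(c("strain", "background", "deletion") %in% names(design)))
    stop_sporeffect("'design' needs columns strain, background, deletion")
  if (!all(design$background %in% c("high", "low")))
    stop_sporeffect("'background' must be 'high' or 'low'")
  design$strain <- as.character(design$strain)
  idx <- match(counts$strain, design$strain)
  if (anyNA(idx))
    stop_sporeffect("strains without design rows: ",
                    paste(unique(counts$strain[is.na(idx)]), collapse = ", "))
  bg <- design$background[idx]
  del <- as.character(design$deletion[idx])
  cell <- function(b, g) counts[bg == b & del == g, , drop = FALSE]
  wt_hi <- cell("high", "none"); wt_lo <- cell("low", "none")
  genes <- setdiff(unique(del), "none")

  calls <- list()
  for (g in genes) {
    del_hi <- cell("high", g); del_lo <- cell("low", g)
    if (nrow(del_hi) < 2L || nrow(del_lo) < 2L ||
        nrow(wt_hi) < 2L || nrow(wt_lo) < 2L) {
      warning("gene '", g, "' skipped: incomplete design cells",
              call. = FALSE)
      next
    }
    mc <- classify_mediator(wt_hi, wt_lo, del_hi, del_lo, alpha = alpha,
                            gene = g)
    tst <- mc$tests
    calls[[g]] <- data.frame(
      gene = g, call = mc$call,
      est_del_high = tst$deletion_high$estimate,
      p_del_high = tst$deletion_high$p_value,
      est_del_low = tst$deletion_low$estimate,
      p_del_low = tst$deletion_low$p_value,
      est_interaction = tst$interaction$estimate,
      p_interaction = tst$interaction$p_value,
      alpha = alpha)
  }
  out <- do.call(rbind, calls)
  if (is.null(out)) return(out)
  rownames(out) <- NULL
  if (adjust && nrow(out) > 1L) {
    out$p_del_high <- adjust_pvalues(out$p_del_high, "holm")
    out$p_del_low <- adjust_pvalues(out$p_del_low, "holm")
    out$p_interaction <- adjust_pvalues(out$p_interaction, "holm")
    out$call <- apply_decision_table(out, alpha)
  }
  out
}

# re-derive calls from (possibly adjusted) test columns
apply_decision_table <- function(df, alpha) {
  mapply(function(ph, eh, pl, el, pi_) {
    if (ph > alpha) "no_effect"
    else if (eh < 0 && pi_ <= alpha) "mediator"
    else if (eh < 0 && pl <= alpha && el < 0 && pi_ > alpha)
      "allele_independent"
    else "ambiguous"
  }, df$p_del_high, df$est_del_high, df$p_del_low, df$est_del_low,
  df$p_interaction)
}
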