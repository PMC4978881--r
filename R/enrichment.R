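#' Build a 2x2 membership table for a cluster and a target set
#'
#' Partitions the universe into in-cluster targets (`a`), in-cluster
#' non-targets (`b`), out-of-cluster targets (`c`) and the rest (`d`).
#' Target genes absent from the universe are dropped; their number is
#' attached as attribute `"dropped"`.
#'
#' @param cluster gene set (must be contained in `universe`).
#' @param targets gene set (intersected with `universe`).
#' @param universe background gene set (non-empty).
#' @return Named integer vector `c(a, b, c, d)` of class
#'   `"contingency_table"`.
#' @export
contingency <- function(cluster, targets, universe) {
  if (length(universe) == 0L) stop_sporeffect("'universe' is empty")
  universe <- unique(as.character(universe))
  cluster <- unique(as.character(cluster))
  targets <- unique(as.character(targets))
  if (!all(cluster %in% universe))
    stop_sporeffect("cluster contains genes outside the universe")
  dropped <- sum(!targets %in% universe)
  targets <- intersect(targets, universe)
  a <- length(intersect(cluster, targets))
  b <- length(cluster) - a
  cc <- length(targets) - a
  d <- length(universe) - a - b - cc
  structure(c(a = a, b = b, c = cc, d = d), dropped = dropped,
            class = "contingency_table")
}

#' Odds ratio of a 2x2 table
#'
#' `(a*d)/(b*c)`; when any cell is zero the Haldane correction
#' `(a+.5)(d+.5)/((b+.5)(c+.5))` is used and the result carries attribute
#' `haldane = TRUE`.
#'
#' @param table a [contingency()] table (or named vector a/b/c/d).
#' @return The odds ratio (>= 0).
#' @export
odds_ratio <- function(table) {
  a <- table[["a"]]; b <- table[["b"]]; cc <- table[["c"]]; d <- table[["d"]]
  if (a == 0 || b == 0 || cc == 0 || d == 0) {
    structure((a + 0.5) * (d + 0.5) / ((b + 0.5) * (cc + 0.5)),
              haldane = TRUE)
  } else {
    structure((a * d) / (b * cc), haldane = FALSE)
  }
}

#' One-sided enrichment p-value for a 2x2 table
#'
#' Upper-tail hypergeometric probability of observing at least `a`
#' in-cluster targets, i.e. Fisher's exact test in the enrichment
#' direction.
#'
#' @param table a [contingency()] table.
#' @return p-value in `[0, 1]`.
#' @export
fisher_enrichment_p <- function(table) {
  a <- table[["a"]]; b <- table[["b"]]; cc <- table[["c"]]; d <- table[["d"]]
  phyper(a - 1, m = a + cc, n = b + d, k = a + b, lower.tail = FALSE)
}

#' Bonferroni or Holm adjustment of p-values
#'
#' @param pvals p-values in `[0, 1]`.
#' @param method `"bonferroni"` (`min(1, m p)`) or `"holm"` (step-down with
#'   monotonicity enforcement).
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(pvals, method = c("bonferroni", "holm")) {
  method <- match.arg(method)
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop_sporeffect("p-values must lie in [0, 1]")
  p.adjust(pvals, method = method)
}

#' Screen transcription-factor regulons for cluster over-representation
#'
#' For every trend cluster and every regulon, builds the 2x2 table against
#' the universe, computes the odds ratio and the one-sided enrichment
#' p-value, and flags regulons passing both thresholds (the candidate-gene
#' criterion: `p <= p_cut` and `odds_ratio >= or_cut`).  A Holm-adjusted
#' p-value across the regulons of each cluster is reported alongside.
#'
#' @param cluster_lists named list of gene vectors (one per cluster), e.g.
#'   the `clusters` element of [cluster_genes()].
#' @param regulons named list of target-gene vectors (one per TF), e.g.
#'   from [read_gmt()].
#' @param universe background gene set; defaults to all genes appearing in
#'   `cluster_lists`.
#' @param p_cut,or_cut pass thresholds (defaults 0.05 and 1.5).
#' @return data.frame sorted by p-value within cluster: `cluster`, `set`,
#'   `a`, `b`, `c`, `d`, `odds_ratio`, `p_value`, `adjusted_p`, `pass`.
#' @export
candidate_regulators <- function(cluster_lists, regulons, universe = NULL,
                                 p_cut = 0.05, or_cut = 1.5) {
  if (length(regulons) == 0L) stop_sporeffect("'regulons' is empty")
  universe <- universe %||% unique(unlist(cluster_lists, use.names = FALSE))
  res <- list()
  for (cl in names(cluster_lists)) {
    rows <- lapply(names(regulons), function(tf) {
      tab <- contingency(cluster_lists[[cl]], regulons[[tf]], universe)
      data.frame(cluster = cl, set = tf,
                 a = tab[["a"]], b = tab[["b"]], c = tab[["c"]],
                 d = tab[["d"]],
                 odds_ratio = as.numeric(odds_ratio(tab)),
                 p_value = fisher_enrichment_p(tab))
    })
    df <- do.call(rbind, rows)
    df$adjusted_p <- adjust_pvalues(df$p_value, "holm")
    df$pass <- df$p_value <= p_cut & df$odds_ratio >= or_cut
    res[[cl]] <- df[order(df$p_value), ]
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
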