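#' Abstract a curve into rise/steady/fall symbols
#'
#' One symbol per consecutive time interval: `+` when the change exceeds
#' `epsilon`, `-` when it falls below `-epsilon`, `0` otherwise.
#'
#' @param curve base-transformed values over the time grid (length >= 3).
#' @param epsilon change threshold in log2 units (> 0).
#' @return Character vector of symbols, one per interval.
#' @export
abstract_trend <- function(curve, epsilon = 0.25) {
  if (length(curve) < 3L) stop_sporeffect("need at least 3 time points")
  check_number(epsilon, "epsilon", lower = 0, allow_boundary = c(FALSE, TRUE))
  d <- diff(curve)
  ifelse(d > epsilon, "+", ifelse(d < -epsilon, "-", "0"))
}

#' Classify a symbol sequence into a temporal trend label
#'
#' Deterministic rule table over the abstraction symbols, matching the
#' four qualitative cluster morphologies plus `unclassified`:
#' * `repressing` — at least one fall and no rise;
#' * `early` — rises only in intervals starting within the first third of
#'   the time range (the rise is completed early);
#' * `late` — no change in any interval ending in the first half, then a
#'   rise with no fall after the last rise;
#' * `increasing` — a rise with no fall after the last rise and at least
#'   as many rises as falls;
#' * `unclassified` — anything else (including all-steady curves).
#'
#' Rules are applied in that order.
#'
#' @param symbols output of [abstract_trend()].
#' @param times the time grid (length = `length(symbols) + 1`).
#' @return One of `"early"`, `"increasing"`, `"late"`, `"repressing"`,
#'   `"unclassified"`.
#' @export
classify_trend <- function(symbols, times) {
  if (length(symbols) != length(times) - 1L)
    stop_sporeffect("'symbols' must have one entry per time interval")
  plus <- symbols == "+"
  minus <- symbols == "-"
  if (!any(plus) && !any(minus)) return("unclassified")
  if (!any(plus)) return("repressing")
  t_min <- min(times)
  span <- max(times) - t_min
  starts <- times[-length(times)]
  ends <- times[-1]
  if (all(starts[plus] <= t_min + span / 3)) return("early")
  last_plus <- max(which(plus))
  minus_after <- any(minus & seq_along(symbols) > last_plus)
  if (!minus_after && all(ends[plus | minus] > t_min + span / 2))
    return("late")
  if (!minus_after && sum(plus) >= sum(minus)) return("increasing")
  "unclassified"
}

#' Cluster genes by their qualitative temporal trend
#'
#' Applies [abstract_trend()] and [classify_trend()] to every gene of a
#' base-transformed (typically smoothed) series.  The labels partition the
#' gene set; multiplying all values and `epsilon` by the same positive
#' constant leaves them unchanged.
#'
#' @param series a base-transformed [expression_series()].
#' @param epsilon symbol threshold in log2 units (default 0.25, sized for
#'   smoothed curves; see the methods vignette).
#' @return List with `labels` (data.frame gene/label) and `clusters`
#'   (named list of gene vectors, one per label).
#' @export
cluster_genes <- function(series, epsilon = 0.25) {
  stopifnot(inherits(series, "expression_series"))
  if (series$stage != "base_transformed")
    stop_sporeffect("clustering expects a base_transformed series")
  labels <- apply(series$values, 1L, function(v)
    classify_trend(abstract_trend(v, epsilon), series$times))
  lab_df <- data.frame(gene = rownames(series$values), label = labels,
                       row.names = NULL)
  lev <- c("early", "increasing", "late", "repressing", "unclassified")
  clusters <- lapply(setNames(lev, lev),
                     function(l) lab_df$gene[lab_df$label == l])
  list(labels = lab_df, clusters = clusters)
}
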