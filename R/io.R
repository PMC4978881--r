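# tabular I/O: all formats are headered TSV; gene sets are GMT

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop_sporeffect("file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop_sporeffect(path, ": missing column(s) ",
                    paste(missing_cols, collapse = ", "))
  df
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sporulation count tables
#'
#' TSV with columns `strain`, `replicate`, `y`, `n`; rows violating
#' `0 <= y <= n` are rejected with their row numbers.
#'
#' @param path file path.
#' @return [read_counts_tsv()]: a validated count table.
#' @export
read_counts_tsv <- function(path) {
  as_sporulation_counts(read_tsv_checked(path, c("strain", "replicate",
                                                 "y", "n")))
}

#' @rdname read_counts_tsv
#' @param counts a count table.
#' @export
write_counts_tsv <- function(counts, path) {
  write_tsv(as.data.frame(as_sporulation_counts(counts)), path)
}

#' Read / write nuclei-state time courses
#'
#' TSV with columns `time_h`, `c1`, `c2`, `c4` (and optionally
#' `replicate`).
#'
#' @param path file path.
#' @export
read_nuclei_tsv <- function(path) {
  validate_nuclei_timecourse(read_tsv_checked(path, c("time_h", "c1",
                                                      "c2", "c4")))
}

#' @rdname read_nuclei_tsv
#' @param tc a nuclei time course.
#' @export
write_nuclei_tsv <- function(tc, path) {
  write_tsv(validate_nuclei_timecourse(tc), path)
}

#' Read / write genes-by-times expression matrices
#'
#' TSV whose first column is `gene` and whose remaining column names are
#' the sampling times in hours.
#'
#' @param path file path.
#' @param stage stage tag for the returned series.
#' @export
read_expression_tsv <- function(path, stage = "raw") {
  df <- read_tsv_checked(path, "gene")
  times <- suppressWarnings(as.numeric(setdiff(names(df), "gene")))
  if (anyNA(times))
    stop_sporeffect(path, ": non-numeric time column names")
  M <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  rownames(M) <- df$gene
  expression_series(M, times, stage = stage)
}

#' @rdname read_expression_tsv
#' @param series an [expression_series()].
#' @export
write_expression_tsv <- function(series, path) {
  stopifnot(inherits(series, "expression_series"))
  df <- data.frame(gene = rownames(series$values), series$values,
                   check.names = FALSE)
  write_tsv(df, path)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: id, description, then tab-separated members.  Lines
#' with fewer than three fields are rejected with their line number.
#'
#' @param path file path.
#' @return [read_gmt()]: named list of character vectors; descriptions in
#'   attribute `"description"`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_sporeffect("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop_sporeffect(path, ": GMT line(s) with fewer than 3 fields: line ",
                    paste(bad, collapse = ", "))
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  attr(sets, "description") <- vapply(fields, `[`, character(1), 2L)
  sets
}

#' @rdname read_gmt
#' @param sets named list of gene vectors.
#' @param descriptions optional per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write one plain-text gene list per cluster
#'
#' @param clusters named list of gene vectors.
#' @param dir output directory (created if needed).
#' @return The file paths, invisibly.
#' @export
write_gene_lists <- function(clusters, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(clusters), function(cl) {
    p <- file.path(dir, paste0("cluster_", cl, ".txt"))
    writeLines(clusters[[cl]], p)
    p
  }, character(1))
  invisible(paths)
}

#' Minor allele frequency of a biallelic site across strains
#'
#' @param table data.frame with columns `strain` and `allele`, one row per
#'   strain.
#' @return Frequency of the less common allele in `[0, 0.5]`; exactly 0
#'   for a monomorphic site and 0.5 for an even split.  Multi-allelic
#'   input is an error.
#' @examples
#' minor_allele_frequency(tao3_allele_table())  # 1/62, about 1.6%
#' @export
minor_allele_frequency <- function(table) {
  if (!all(c("strain", "allele") %in% names(table)))
    stop_sporeffect("'table' needs columns strain and allele")
  if (anyDuplicated(table$strain))
    stop_sporeffect("one record per strain required")
  if (nrow(table) < 2L) stop_sporeffect("need at least 2 strains")
  tab <- table(as.character(table$allele))
  if (length(tab) > 2L)
    stop_sporeffect("site is multi-allelic (alleles: ",
                    paste(names(tab), collapse = ", "), ")")
  if (length(tab) == 1L) return(0)
  min(tab) / sum(tab)
}

#' Surveyed-collection allele table for the TAO3 position 4477 site
#'
#' Reconstructs, from the published survey composition, the strain-by-
#' allele table of the causative TAO3 coding site across 62 surveyed
#' strains (38 from the SGRP collection plus 24 from SGD): the
#' high-sporulating SK1 strain is the sole carrier of the rare 4477C
#' allele, all other strains carry 4477G.  Strain identities other than
#' SK1 are synthetic placeholder labels; only the allele counts are
#' faithful.
#'
#' @return data.frame with columns `strain` and `allele` (62 rows).
#' @export
tao3_allele_table <- function() {
  data.frame(
    strain = c("SK1", sprintf("SGRP_%02d", 1:37), sprintf("SGD_%02d", 1:24)),
    allele = c("C", rep("G", 61)),
    stringsAsFactors = FALSE)
}
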