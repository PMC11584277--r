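#' Count high-quality reads per genome and sample
#'
#' @param hits data.frame with one row per aligned read: columns
#'   `sample`, `genome` and `mapq`. Only alignments with mapping
#'   quality strictly above `min_mapq` are counted (the study counts
#'   Q>30 reads per MAG).
#' @param genomes,samples optional level sets fixing the table
#'   dimensions (genomes/samples with zero counts are then retained).
#' @param min_mapq mapping-quality threshold (strict).
#' @return genome x sample integer count matrix.
#' @export
count_by_genome <- function(hits, genomes = NULL, samples = NULL,
                            min_mapq = 30L) {
  stopifnot(all(c("sample", "genome", "mapq") %in% names(hits)))
  keep <- hits$mapq > min_mapq
  g <- factor(hits$genome[keep], levels = genomes %||% sort(unique(hits$genome)))
  s <- factor(hits$sample[keep], levels = samples %||% sort(unique(hits$sample)))
  tab <- table(g, s)
  m <- matrix(as.integer(tab), nrow = nlevels(g),
              dimnames = list(levels(g), levels(s)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Presence/absence from a count table
#'
#' @param counts genome x sample count matrix.
#' @param threshold minimum count for presence (default 1 read).
#' @param warn_below presence calls resting on fewer than this many
#'   reads trigger a warning — absence (and near-absence) calls from
#'   shallow ancient data deserve caution.
#' @return logical genome x sample matrix.
#' @export
presence_absence <- function(counts, threshold = 1L, warn_below = 10L) {
  pres <- counts >= threshold
  weak <- pres & counts < warn_below
  if (any(weak))
    warning(sum(weak), " presence call(s) rest on fewer than ",
            warn_below, " reads")
  pres
}

#' Restrict a count table to genomes present in ancient samples
#'
#' @param counts genome x sample count matrix.
#' @param ancient_ids column names of the ancient samples.
#' @param threshold minimum read count for presence.
#' @return the row-filtered matrix (possibly 0 rows, with a warning).
#' @export
restrict_to_ancient_present <- function(counts, ancient_ids, threshold = 1L) {
  stopifnot(all(ancient_ids %in% colnames(counts)))
  keep <- rowSums(counts[, ancient_ids, drop = FALSE] >= threshold) > 0
  if (!any(keep)) warning("no genome is present in any ancient sample")
  counts[keep, , drop = FALSE]
}

#' Per-sample relative abundance
#'
#' @param counts genome x sample count matrix (typically restricted to
#'   ancient-present genomes first).
#' @return proportion matrix; per-sample columns sum to 1, except
#'   zero-total samples which stay all-zero and are listed in attribute
#'   `zero_samples`.
#' @export
relative_abundance <- function(counts) {
  tot <- colSums(counts)
  out <- sweep(counts, 2, ifelse(tot == 0, 1, tot), "/")
  attr(out, "zero_samples") <- colnames(counts)[tot == 0]
  out
}

#' Exact test of genome-presence overlap between two sample groups
#'
#' The unit of observation is the genome: each genome is cross-
#' classified as present/absent in group 1 (any sample) versus group 2
#' (any sample), and the resulting 2x2 table is tested with a two-sided
#' Fisher exact test — the p-value sums the hypergeometric
#' probabilities of all tables (at the observed margins) no more
#' probable than the observed one.
#'
#' @param presence logical genome x sample matrix (see
#'   [presence_absence()]).
#' @param group1,group2 disjoint, non-empty character vectors of sample
#'   column names.
#' @return list with `table` (2x2, genomes), `p_value` and the group
#'   presence vectors.
#' @export
overlap_fisher <- function(presence, group1, group2) {
  stopifnot(nrow(presence) > 0, length(group1) > 0, length(group2) > 0,
            length(intersect(group1, group2)) == 0,
            all(c(group1, group2) %in% colnames(presence)))
  g1 <- rowSums(presence[, group1, drop = FALSE]) > 0
  g2 <- rowSums(presence[, group2, drop = FALSE]) > 0
  tab <- matrix(c(sum(g1 & g2), sum(!g1 & g2),
                  sum(g1 & !g2), sum(!g1 & !g2)), 2, 2,
                dimnames = list(group1 = c("present", "absent"),
                                group2 = c("present", "absent")))
  list(table = tab, p_value = fisher_exact_p(tab), group1 = g1, group2 = g2)
}

#' Two-sided Fisher exact p-value of a 2x2 table
#'
#' Sums `dhyper` probabilities over all tables with the observed
#' margins whose probability does not exceed the observed table's
#' (with the conventional `1 + 1e-7` relative tolerance for
#' floating-point ties).
#'
#' @param tab 2x2 non-negative integer matrix.
#' @return the exact two-sided p-value.
#' @export
fisher_exact_p <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  a <- tab[1, 1]
  row1 <- sum(tab[1, ]); row2 <- sum(tab[2, ]); col1 <- sum(tab[, 1])
  support <- max(0, col1 - row2):min(row1, col1)
  probs <- dhyper(support, row1, row2, col1)
  p_obs <- dhyper(a, row1, row2, col1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}
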