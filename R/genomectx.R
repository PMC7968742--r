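#' Fisher enrichment of a gene set within a stratum
#'
#' Builds the 2x2 table of gene-set membership against stratum membership
#' over a common universe and reports the two-sided Fisher exact p-value, the
#' sample odds ratio and its log2. The dual significance rule flags results
#' with `p < p_cut` AND `|log2 OR| > lor_cut`. When any cell is zero the
#' Haldane-Anscombe +0.5 correction is applied to all four cells for the odds
#' ratio only — the p-value always comes from the uncorrected table. No
#' multiple-testing correction is applied to enrichment p-values.
#'
#' @param set_membership,stratum_membership Logical vectors over the same
#'   gene universe.
#' @param p_cut,lor_cut Dual-rule thresholds (defaults 0.05 and 0.5).
#' @param set_label,stratum_label Labels carried into the result.
#' @return One-row `data.frame`: labels, the four cell counts
#'   (`n11` in-set in-stratum, `n10` in-set out, `n01`, `n00`), `odds_ratio`,
#'   `log2_or`, `p`, `flagged`.
#' @export
fisher_enrichment <- function(set_membership, stratum_membership,
                              p_cut = 0.05, lor_cut = 0.5,
                              set_label = "set", stratum_label = "stratum") {
  stopifnot(length(set_membership) == length(stratum_membership))
  if (length(set_membership) == 0L) stop("empty gene universe")
  s <- as.logical(set_membership); g <- as.logical(stratum_membership)
  n11 <- sum(s & g); n10 <- sum(s & !g); n01 <- sum(!s & g); n00 <- sum(!s & !g)
  tbl <- matrix(c(n11, n01, n10, n00), 2)
  p <- stats::fisher.test(tbl)$p.value
  cells <- c(n11, n10, n01, n00)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  lor <- log2(or)
  data.frame(gene_set = set_label, stratum = stratum_label,
             n11 = n11, n10 = n10, n01 = n01, n00 = n00,
             odds_ratio = or, log2_or = lor, p = p,
             flagged = p < p_cut & abs(lor) > lor_cut,
             stringsAsFactors = FALSE)
}

#' Enrichment of one gene set within another
#'
#' Same machinery as [fisher_enrichment()] on the membership cross-table,
#' additionally reporting fold enrichment = observed / expected overlap under
#' independence.
#'
#' @param set_a,set_b Character vectors of gene ids (subsets of `universe`).
#' @param universe Character vector of all gene ids.
#' @inheritParams fisher_enrichment
#' @return One-row `data.frame` as in [fisher_enrichment()], plus
#'   `fold_enrichment`.
#' @export
set_overlap_enrichment <- function(set_a, set_b, universe,
                                   p_cut = 0.05, lor_cut = 0.5,
                                   set_label = "set_a", stratum_label = "set_b") {
  stopifnot(all(set_a %in% universe), all(set_b %in% universe))
  ina <- universe %in% set_a
  inb <- universe %in% set_b
  res <- fisher_enrichment(ina, inb, p_cut, lor_cut, set_label, stratum_label)
  expected <- sum(ina) * sum(inb) / length(universe)
  res$fold_enrichment <- if (expected > 0) res$n11 / expected else NA_real_
  res
}

#' Assign genes to chromosome arm/center domains
#'
#' Labels each gene by the domain whose interval contains the midpoint of the
#' gene's coordinates. Intervals are half-open on the right
#' (left-closed), so a midpoint exactly on a boundary belongs to the interval
#' starting there.
#'
#' @param genes `data.frame` with `gene`, `chrom`, `start`, `end` (0-based
#'   half-open gene coordinates).
#' @param boundaries `data.frame` with `chrom`, `start`, `end`, `domain`
#'   (e.g. `"arm"`/`"center"`); intervals must tile each chromosome without
#'   overlap.
#' @return Character vector of domain labels aligned with `genes` rows
#'   (`NA` where no interval covers the midpoint).
#' @export
assign_domains <- function(genes, boundaries) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(genes)),
            all(c("chrom", "start", "end", "domain") %in% names(boundaries)))
  mid <- floor((genes$start + genes$end) / 2)
  out <- rep(NA_character_, nrow(genes))
  for (ch in unique(genes$chrom)) {
    b <- boundaries[boundaries$chrom == ch, , drop = FALSE]
    gi <- which(genes$chrom == ch)
    for (k in seq_len(nrow(b))) {
      hit <- mid[gi] >= b$start[k] & mid[gi] < b$end[k]
      out[gi[hit]] <- b$domain[k]
    }
  }
  out
}
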