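#' Compare one read's alignments against the two parental references
#'
#' Competitive assignment rule: a read mapped on one side only goes to that
#' side; when mapped on both, the higher alignment score (AS) wins; on an AS
#' tie the fewer mismatches (nM) win; a tie on both is `AMBIGUOUS`; a read
#' mapped on neither side is `UNMAPPED`. All arguments are vectorized.
#'
#' @param AS_a,AS_b Integer alignment scores (higher = better).
#' @param nM_a,nM_b Integer mismatch counts.
#' @param mapped_a,mapped_b Logical; whether the read mapped to each
#'   reference.
#' @return Character vector in `{"A","B","AMBIGUOUS","UNMAPPED"}`.
#' @export
compare_alignments <- function(AS_a, AS_b, nM_a, nM_b,
                               mapped_a = TRUE, mapped_b = TRUE) {
  n <- max(length(AS_a), length(AS_b), length(mapped_a), length(mapped_b))
  AS_a <- rep_len(AS_a, n); AS_b <- rep_len(AS_b, n)
  nM_a <- rep_len(nM_a, n); nM_b <- rep_len(nM_b, n)
  mapped_a <- rep_len(mapped_a, n); mapped_b <- rep_len(mapped_b, n)
  out <- rep("AMBIGUOUS", n)
  out[!mapped_a & !mapped_b] <- "UNMAPPED"
  out[mapped_a & !mapped_b] <- "A"
  out[!mapped_a & mapped_b] <- "B"
  both <- mapped_a & mapped_b
  out[both & AS_a > AS_b] <- "A"
  out[both & AS_b > AS_a] <- "B"
  tie <- both & AS_a == AS_b
  out[tie & nM_a < nM_b] <- "A"
  out[tie & nM_b < nM_a] <- "B"
  out
}

#' Proportional redistribution of ambiguous reads
#'
#' Ambiguous reads at a feature are split between the two references in
#' proportion to the reads already assigned to each:
#' `c_a = n_a + n_amb * n_a / (n_a + n_b)` and symmetrically for `c_b`. When
#' no read was assigned to either side the ambiguous pool is split equally.
#' Counts are conserved exactly: `c_a + c_b = n_a + n_b + n_amb`.
#'
#' @param n_a,n_b,n_amb Non-negative counts (vectorized).
#' @return `data.frame` with columns `c_a`, `c_b`.
#' @export
redistribute <- function(n_a, n_b, n_amb) {
  stopifnot(all(n_a >= 0), all(n_b >= 0), all(n_amb >= 0))
  tot <- n_a + n_b
  frac_a <- ifelse(tot > 0, n_a / tot, 0.5)
  data.frame(c_a = n_a + n_amb * frac_a, c_b = n_b + n_amb * (1 - frac_a))
}

# reference-consumed width of a CIGAR string (M, D, N, =, X ops)
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    w <- 0L
    for (t in toks) {
      op <- substr(t, nchar(t), nchar(t))
      if (op %in% c("M", "D", "N", "=", "X"))
        w <- w + as.integer(substr(t, 1, nchar(t) - 1L))
    }
    w
  }, integer(1), USE.NAMES = FALSE)
}

# load primary alignments from a SAM/BAM file into a data.frame
read_alignment_table <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"),
    tag = c("AS", "nM", "NM"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  secondary <- bitwAnd(b$flag, 0x100L) != 0L | bitwAnd(b$flag, 0x800L) != 0L
  unmapped <- bitwAnd(b$flag, 0x4L) != 0L
  keep <- !secondary & !unmapped
  nm <- b$tag$nM
  if (is.null(nm)) nm <- b$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, length(b$qname))
  as_ <- b$tag$AS
  if (is.null(as_)) as_ <- rep(NA_integer_, length(b$qname))
  df <- data.frame(qname = b$qname[keep], chrom = as.character(b$rname)[keep],
                   pos = b$pos[keep], cigar = b$cigar[keep],
                   AS = as_[keep], nM = nm[keep], stringsAsFactors = FALSE)
  df[!duplicated(df$qname), , drop = FALSE]
}

read_bed_features <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$name) || anyNA(gr$name))
    stop("BED features must carry names: ", path)
  gr
}

#' Competitive allele-specific counting over paired alignments
#'
#' Reads the same set of F1 reads aligned against the two parental
#' references, decides each read's side with [compare_alignments()], counts
#' overlaps of the chosen-side alignment with the reference's features
#' (half-open intervals, any overlap of >= 1 bp; a read overlapping several
#' features contributes once to each), and redistributes ambiguous reads per
#' feature with [redistribute()]. Ambiguous reads are attributed to the union
#' of the features they overlap on either side, keeping the operation
#' symmetric under swapping the references. Secondary and supplementary
#' alignment records are ignored.
#'
#' @param aln_a,aln_b Paths to SAM or BAM files of the same reads against
#'   references A and B (tags `AS` and `nM`/`NM` required).
#' @param bed_a,bed_b Paths to BED files with identical feature-id sets.
#' @return `data.frame` with one row per feature: `feature`, `n_a`, `n_b`,
#'   `n_amb`, `c_a`, `c_b`. A summary of unmapped/featureless reads is
#'   attached as attribute `"log"`.
#' @export
count_features <- function(aln_a, aln_b, bed_a, bed_b) {
  feats_a <- read_bed_features(bed_a)
  feats_b <- read_bed_features(bed_b)
  if (!setequal(feats_a$name, feats_b$name))
    stop("feature id sets differ between the two BED files")
  ta <- read_alignment_table(aln_a)
  tb <- read_alignment_table(aln_b)
  reads <- union(ta$qname, tb$qname)
  ia <- match(reads, ta$qname); ib <- match(reads, tb$qname)
  mapped_a <- !is.na(ia); mapped_b <- !is.na(ib)
  AS_a <- ifelse(mapped_a, ta$AS[ia], -Inf)
  AS_b <- ifelse(mapped_b, tb$AS[ib], -Inf)
  nM_a <- ifelse(mapped_a, ta$nM[ia], NA_integer_)
  nM_b <- ifelse(mapped_b, tb$nM[ib], NA_integer_)
  verdict <- compare_alignments(AS_a, AS_b, nM_a, nM_b, mapped_a, mapped_b)

  feat_ids <- sort(feats_a$name)
  tally <- matrix(0, length(feat_ids), 3,
                  dimnames = list(feat_ids, c("n_a", "n_b", "n_amb")))
  overlap_features <- function(tab, idx, feats) {
    # returns list: for each element of idx, features overlapped
    sel <- idx[!is.na(idx)]
    gr <- GenomicRanges::GRanges(
      tab$chrom[sel],
      IRanges::IRanges(start = tab$pos[sel],
                       width = pmax(cigar_ref_width(tab$cigar[sel]), 1L)))
    hits <- GenomicRanges::findOverlaps(gr, feats, minoverlap = 1L)
    split(feats$name[S4Vectors::subjectHits(hits)],
          factor(S4Vectors::queryHits(hits), levels = seq_along(sel)))
  }
  no_feature <- 0L
  for (side in c("A", "B", "AMBIGUOUS")) {
    rows <- which(verdict == side)
    if (length(rows) == 0L) next
    if (side == "A") {
      ov <- overlap_features(ta, ia[rows], feats_a)
      col <- "n_a"
    } else if (side == "B") {
      ov <- overlap_features(tb, ib[rows], feats_b)
      col <- "n_b"
    } else {
      ova <- overlap_features(ta, ia[rows], feats_a)
      ovb <- overlap_features(tb, ib[rows], feats_b)
      ov <- mapply(function(x, y) unique(c(x, y)), ova, ovb, SIMPLIFY = FALSE)
      col <- "n_amb"
    }
    counts <- table(unlist(ov))
    hit_any <- vapply(ov, length, integer(1)) > 0
    no_feature <- no_feature + sum(!hit_any)
    if (length(counts))
      tally[names(counts), col] <- tally[names(counts), col] +
        as.integer(counts)
  }
  red <- redistribute(tally[, "n_a"], tally[, "n_b"], tally[, "n_amb"])
  out <- data.frame(feature = feat_ids, n_a = tally[, "n_a"],
                    n_b = tally[, "n_b"], n_amb = tally[, "n_amb"],
                    c_a = red$c_a, c_b = red$c_b, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "log") <- list(
    n_reads = length(reads),
    n_unmapped = sum(verdict == "UNMAPPED"),
    n_no_feature = no_feature,
    n_zero_assigned_features = sum(tally[, "n_a"] + tally[, "n_b"] == 0 &
                                   tally[, "n_amb"] > 0))
  out
}

#' Export allele counts as count-table columns
#'
#' Fractional counts from redistribution are preserved by default; optional
#' nearest-integer rounding (ties away from zero) is available for strictly
#' integer downstream models.
#'
#' @param allele_counts Output of [count_features()].
#' @param rounding Round to nearest integer (default `FALSE`).
#' @return `data.frame` with `feature`, `count_a`, `count_b`, `n_ambiguous`.
#' @export
export_counts <- function(allele_counts, rounding = FALSE) {
  ca <- allele_counts$c_a; cb <- allele_counts$c_b
  if (rounding) {
    ca <- sign(ca) * floor(abs(ca) + 0.5)
    cb <- sign(cb) * floor(abs(cb) + 0.5)
  }
  data.frame(feature = allele_counts$feature, count_a = ca, count_b = cb,
             n_ambiguous = allele_counts$n_amb, stringsAsFactors = FALSE)
}
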