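NUC <- c("A", "C", "G", "T")

# split a cds string into codons, dropping triplets with gaps/ambiguity
codon_split <- function(s) {
  s <- toupper(s)
  n <- nchar(s) %/% 3L
  cods <- substring(s, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
  cods
}

translate_codon <- function(cod) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[cod])
}

# fraction of synonymous sites per codon position (NG86 site counting);
# changes producing stop codons count as nonsynonymous
codon_syn_sites <- function(cod) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[cod]
  s <- 0
  for (p in 1:3) {
    from <- substr(cod, p, p)
    for (to in setdiff(NUC, from)) {
      alt <- cod
      substr(alt, p, p) <- to
      if (gc[alt] == aa) s <- s + 1 / 3
    }
  }
  s
}

# syn/nonsyn substitution counts between two codons, averaged over minimal
# mutational path orderings; paths through stop codons are excluded unless
# every path is blocked
codon_sub_counts <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(syn = 0, nonsyn = 0))
  paths <- if (k == 1L) list(pos) else {
    perms <- function(v) {
      if (length(v) == 1L) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
      out
    }
    perms(pos)
  }
  walk <- function(order) {
    cur <- c1; sy <- 0; ns <- 0; blocked <- FALSE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (gc[nxt] == "*") blocked <- TRUE
      if (gc[nxt] == gc[cur]) sy <- sy + 1 else ns <- ns + 1
      cur <- nxt
    }
    list(syn = sy, nonsyn = ns, blocked = blocked)
  }
  res <- lapply(paths, walk)
  ok <- !vapply(res, `[[`, logical(1), "blocked")
  if (!any(ok)) ok <- rep(TRUE, length(res))
  sy <- mean(vapply(res[ok], `[[`, numeric(1), "syn"))
  ns <- mean(vapply(res[ok], `[[`, numeric(1), "nonsyn"))
  c(syn = sy, nonsyn = ns)
}

jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Nonsynonymous and synonymous divergence of an aligned codon pair
#'
#' Deterministic substitution counting over the codon table: synonymous and
#' nonsynonymous sites are counted per codon from its degeneracy (fractional
#' sites, averaged over the two sequences) and substitutions are tallied
#' along minimal mutational paths between differing codons, averaged over
#' path orderings (paths through stop codons are excluded when avoidable).
#' Proportions are corrected for multiple hits with the Jukes-Cantor formula
#' `d = -3/4 log(1 - 4p/3)`; saturation (`p >= 3/4`) yields `NA` with
#' `saturated = TRUE`. Codon triplets containing gaps or ambiguity codes are
#' dropped pairwise.
#'
#' @param seq_a,seq_b Aligned in-frame CDS strings of equal length.
#' @return List: `Ka`, `Ks`, site counts `N`, `S`, substitution counts `Nd`,
#'   `Sd`, and `saturated`.
#' @export
kaks <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) stop("sequences must be aligned")
  if (nchar(seq_a) %% 3L != 0L) stop("alignment length not a multiple of 3")
  ca <- codon_split(seq_a); cb <- codon_split(seq_b)
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  ca <- ca[clean]; cb <- cb[clean]
  gc <- Biostrings::GENETIC_CODE
  if (any(gc[ca] == "*" & seq_along(ca) < length(ca)) ||
      any(gc[cb] == "*" & seq_along(cb) < length(cb)))
    stop("internal stop codon in alignment")
  syn_tbl <- vapply(unique(c(ca, cb)), codon_syn_sites, numeric(1))
  S <- (sum(syn_tbl[ca]) + sum(syn_tbl[cb])) / 2
  N <- 3 * length(ca) - S
  subs <- mapply(function(x, y) codon_sub_counts(x, y), ca, cb)
  Sd <- sum(subs["syn", ]); Nd <- sum(subs["nonsyn", ])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  Ks <- jc_correct(pS); Ka <- jc_correct(pN)
  list(Ka = Ka, Ks = Ks, N = N, S = S, Nd = Nd, Sd = Sd,
       saturated = is.na(Ks) || is.na(Ka))
}

#' Effective number of codons (ENC)
#'
#' Wright's codon-usage statistic from per-amino-acid-family homozygosities.
#' Families are grouped by degeneracy under the standard code (2
#' non-degenerate amino acids, nine two-fold, one three-fold, five four-fold
#' and three six-fold families); homozygosity uses the small-sample form
#' `F = (n * sum(p^2) - 1) / (n - 1)`, falling back to `sum(p^2)` when a
#' family is observed exactly once. Unobserved families are imputed with the
#' mean of observed families of the same degeneracy class (the three-fold
#' class, if missing, by the mean of the two- and four-fold class means).
#' The result is clamped to the theoretical range \[20, 61\].
#'
#' @param cds CDS string (length a multiple of 3; stops and ambiguous codons
#'   ignored).
#' @return ENC value in \[20, 61\].
#' @export
enc <- function(cds) {
  gc <- Biostrings::GENETIC_CODE
  cods <- codon_split(cds)
  cods <- cods[grepl("^[ACGT]{3}$", cods)]
  cods <- cods[gc[cods] != "*"]
  if (length(cods) == 0L) stop("no usable codons")
  aa_deg <- table(gc[gc != "*"])
  fam_class <- stats::setNames(as.integer(aa_deg), names(aa_deg))
  counts <- table(factor(gc[cods], levels = names(fam_class)), cods)
  famF <- function(aa) {
    cc <- table(cods[gc[cods] == aa])
    n <- sum(cc)
    if (n == 0L) return(NA_real_)
    p <- as.numeric(cc) / n
    # pad unobserved codons implicitly (they contribute 0 to sum p^2)
    if (n == 1L) return(sum(p^2))
    (n * sum(p^2) - 1) / (n - 1)
  }
  classes <- list(`2` = names(fam_class)[fam_class == 2],
                  `3` = names(fam_class)[fam_class == 3],
                  `4` = names(fam_class)[fam_class == 4],
                  `6` = names(fam_class)[fam_class == 6])
  n_fam <- c(`2` = 9, `3` = 1, `4` = 5, `6` = 3)
  Fbar <- sapply(names(classes), function(k) {
    fs <- vapply(classes[[k]], famF, numeric(1))
    fs <- fs[!is.na(fs) & fs > 0]
    if (length(fs) == 0L) NA_real_ else mean(fs)
  })
  if (is.na(Fbar["3"])) Fbar["3"] <- mean(c(Fbar["2"], Fbar["4"]), na.rm = TRUE)
  if (any(is.na(Fbar))) {
    overall <- mean(Fbar, na.rm = TRUE)
    Fbar[is.na(Fbar)] <- overall
  }
  val <- 2 + sum(n_fam / Fbar)
  min(max(val, 20), 61)
}

#' Codon-usage correction of synonymous divergence (Ks')
#'
#' Removes the linear dependence of Ks on codon-usage bias by ordinary least
#' squares: fit `Ks ~ ENC`, predict Ks at ENC = 60, and add each gene's
#' residual to that idealized value. Algebraically
#' `Ks'_i = Ks_i + b * (60 - ENC_i)` where `b` is the fitted slope, so the
#' OLS slope of Ks' on ENC is exactly zero.
#'
#' @param ks,enc_values Numeric vectors of equal length (>= 3, finite values
#'   used for the fit).
#' @param anchor ENC value at which Ks is predicted (default 60).
#' @return Numeric vector of corrected Ks' values (NA where ks is NA).
#' @export
ks_correct <- function(ks, enc_values, anchor = 60) {
  stopifnot(length(ks) == length(enc_values))
  ok <- is.finite(ks) & is.finite(enc_values)
  if (sum(ok) < 3L) stop("need >= 3 finite (Ks, ENC) pairs")
  fit <- stats::lm(ks[ok] ~ enc_values[ok])
  b <- unname(stats::coef(fit)[2])
  if (is.na(b)) b <- 0  # constant ENC: nothing to correct
  ks + b * (anchor - enc_values)
}

#' Expected nucleotide differences in coding sequence
#'
#' One-line utility for the power heuristic behind allele-specific read
#' assignment: at a given synonymous-site divergence and fraction of
#' synonymous sites, the expected number of diagnostic differences in `bp`
#' bases of coding sequence is `divergence * syn_fraction * bp` — e.g. 20%
#' synonymous-site divergence with 25% synonymous sites gives 5 differences
#' per 100 bp.
#'
#' @param divergence Synonymous-site divergence (proportion).
#' @param syn_fraction Fraction of coding sites that are synonymous.
#' @param bp Sequence length in base pairs (default 100).
#' @return Expected number of nucleotide differences.
#' @export
expected_coding_differences <- function(divergence, syn_fraction, bp = 100) {
  divergence * syn_fraction * bp
}

#' Upstream-window conservation score
#'
#' Partitions the first 500 columns of an aligned upstream pair into 100
#' non-overlapping 5-column windows; a window is conserved iff all five
#' columns match exactly and contain no gap. `P_cons` is the conserved
#' fraction; `1 - P_cons` is the upstream-divergence score.
#'
#' @param seq_a,seq_b Aligned sequences (>= 500 columns; extra columns
#'   ignored).
#' @param n_cols Number of leading columns used (default 500).
#' @param window Window width (default 5).
#' @return List: `P_cons`, `one_minus_pcons`, `n_windows`.
#' @export
upstream_conservation <- function(seq_a, seq_b, n_cols = 500, window = 5) {
  if (nchar(seq_a) < n_cols || nchar(seq_b) < n_cols)
    stop("aligned block shorter than ", n_cols, " columns")
  a <- strsplit(toupper(substr(seq_a, 1, n_cols)), "")[[1]]
  b <- strsplit(toupper(substr(seq_b, 1, n_cols)), "")[[1]]
  nw <- n_cols %/% window
  idx <- matrix(seq_len(nw * window), nrow = window)
  cons <- vapply(seq_len(nw), function(w) {
    i <- idx[, w]
    all(a[i] == b[i]) && !any(a[i] == "-") && !any(b[i] == "-")
  }, logical(1))
  list(P_cons = mean(cons), one_minus_pcons = 1 - mean(cons), n_windows = nw)
}

#' Conservation scores for a list of aligned pairs
#'
#' @param pairs List of `list(gene_id, seq_a, seq_b)` as returned by
#'   [read_maf()] or [simulate_upstream_alignments()].
#' @return `data.frame` with `gene`, `P_cons`, `one_minus_pcons`,
#'   `n_windows`.
#' @export
conservation_scores <- function(pairs) {
  rows <- lapply(pairs, function(p) {
    sc <- upstream_conservation(p$seq_a, p$seq_b)
    data.frame(gene = p$gene_id, P_cons = sc$P_cons,
               one_minus_pcons = sc$one_minus_pcons,
               n_windows = sc$n_windows, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Strand-aware 500-bp upstream flank intervals
#'
#' Computes the interval immediately 5' of each gene (0-based half-open
#' coordinates): `[start - len, start)` for plus-strand genes and
#' `[end, end + len)` for minus-strand genes, truncated at chromosome edges
#' with the truncation flagged.
#'
#' @param annotation `data.frame` with `gene`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param len Flank length (default 500).
#' @param genome Optional `Biostrings::DNAStringSet` (or FASTA path); when
#'   given, flank sequences are returned promoter-sense (reverse-complemented
#'   for minus-strand genes).
#' @return `data.frame` with `gene`, `chrom`, `flank_start`, `flank_end`,
#'   `strand`, `length`, `truncated` and, if `genome` was supplied, `seq`.
#' @export
extract_flanks <- function(annotation, chrom_lengths, len = 500,
                           genome = NULL) {
  stopifnot(all(c("gene", "chrom", "start", "end", "strand") %in%
                names(annotation)))
  cl <- chrom_lengths[annotation$chrom]
  if (any(is.na(cl))) stop("missing chromosome length for some genes")
  if (any(annotation$start < 0 | annotation$end > cl))
    stop("gene coordinates outside chromosome bounds")
  plus <- annotation$strand == "+"
  fs <- ifelse(plus, pmax(annotation$start - len, 0L), annotation$end)
  fe <- ifelse(plus, annotation$start, pmin(annotation$end + len, cl))
  out <- data.frame(gene = annotation$gene, chrom = annotation$chrom,
                    flank_start = as.integer(fs), flank_end = as.integer(fe),
                    strand = annotation$strand,
                    length = as.integer(fe - fs),
                    truncated = (fe - fs) < len, stringsAsFactors = FALSE)
  if (!is.null(genome)) {
    if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*", "", names(genome))
    seqs <- vapply(seq_len(nrow(out)), function(i) {
      if (out$length[i] == 0L) return("")
      s <- Biostrings::subseq(genome[[out$chrom[i]]],
                              out$flank_start[i] + 1L, out$flank_end[i])
      if (out$strand[i] == "-") s <- Biostrings::reverseComplement(s)
      as.character(s)
    }, character(1))
    out$seq <- seqs
  }
  out
}

#' Per-gene molecular-evolution statistics for CDS pairs
#'
#' Runs [kaks()] and [enc()] over a list of aligned ortholog pairs and applies
#' the ENC-based [ks_correct()] across genes. ENC is reported as the mean of
#' the two orthologs' values.
#'
#' @param pairs List of `list(seq_a, seq_b)` (ids taken from names or
#'   `gene_id` fields).
#' @return `data.frame`: `gene`, `Ka`, `Ks`, `ENC`, `Ks_prime`, `ratio`
#'   (Ka/Ks'), `saturated`.
#' @export
molevol_stats <- function(pairs) {
  ids <- names(pairs)
  if (is.null(ids))
    ids <- vapply(seq_along(pairs), function(i)
      if (!is.null(pairs[[i]]$gene_id)) pairs[[i]]$gene_id
      else sprintf("pair%04d", i), character(1))
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    kk <- kaks(p$seq_a, p$seq_b)
    e <- mean(c(enc(p$seq_a), enc(p$seq_b)))
    data.frame(gene = ids[i], Ka = kk$Ka, Ks = kk$Ks, ENC = e,
               saturated = kk$saturated, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$Ks_prime <- if (sum(is.finite(out$Ks)) >= 3)
    ks_correct(out$Ks, out$ENC) else NA_real_
  out$ratio <- out$Ka / out$Ks_prime
  out[, c("gene", "Ka", "Ks", "ENC", "Ks_prime", "ratio", "saturated")]
}
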