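#' Configuration for the synthetic-data generator
#'
#' Bundles every tunable of the simulation: the regulatory-category mixture,
#' effect-size and depth ranges, negative-binomial dispersion, replication and
#' the trans-dominance weight used for F1 allele means. Defaults describe a
#' two-species hybrid experiment with moderate regulatory divergence:
#' absolute cis/trans effects uniform on 0.5-2 log2 units, per-gene mean depth
#' log-uniform between 100 and 1000 counts, dispersion 0.05 and triplicate
#' libraries.
#'
#' @param n_genes Number of genes to simulate.
#' @param category_proportions Named or positional non-negative weights for the
#'   six regulatory categories (`conserved`, `cis_only`, `trans_only`,
#'   `cis_plus_trans`, `cis_x_trans`, `compensatory`); normalized to sum to 1.
#' @param effect_range Interval (log2 units) from which absolute cis/trans
#'   effect magnitudes are drawn uniformly; signs are random subject to the
#'   category constraints.
#' @param mu_range Interval of per-gene baseline mean counts; baselines are
#'   drawn log-uniformly across it.
#' @param phi Negative-binomial dispersion (variance = m + phi * m^2).
#' @param n_replicates Libraries per condition (>= 2).
#' @param h Trans-dominance weight for the hybrid trans environment: F1 allele
#'   channels receive `h * t` of the trans effect. 0.5 models an additive trans
#'   background.
#' @param sexes Character vector of sexes to simulate (`"female"`,
#'   `"male"` or both).
#' @param prop_sex_biased Fraction of genes given a nonzero sex effect.
#' @param sex_effect_range Interval of absolute sex-effect magnitudes (log2).
#' @param prop_interaction Fraction of genes given a species-by-sex
#'   interaction term.
#' @param interaction_range Interval of absolute interaction magnitudes (log2).
#' @param libsize_sd Standard deviation (log scale) of log-normal library-size
#'   multipliers; exercises normalization.
#' @param seed Integer seed; every generator is deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       category_proportions = c(conserved = 1, cis_only = 1,
                                                trans_only = 1, cis_plus_trans = 1,
                                                cis_x_trans = 1, compensatory = 1),
                       effect_range = c(0.5, 2.0),
                       mu_range = c(100, 1000),
                       phi = 0.05,
                       n_replicates = 3,
                       h = 0.5,
                       sexes = "female",
                       prop_sex_biased = 0,
                       sex_effect_range = c(0.5, 2.0),
                       prop_interaction = 0,
                       interaction_range = c(0.5, 2.0),
                       libsize_sd = 0.1,
                       seed = 1L) {
  p <- as.numeric(category_proportions)
  if (length(p) != 6L || any(p < 0) || any(!is.finite(p)))
    stop("category_proportions must be 6 finite non-negative weights")
  if (sum(p) == 0) stop("category_proportions are all zero")
  if (diff(range(effect_range)) < 0 || effect_range[1] > effect_range[2])
    stop("effect_range must be a non-empty interval")
  if (mu_range[1] <= 0 || mu_range[1] > mu_range[2])
    stop("mu_range must be a positive non-empty interval")
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  if (phi < 0) stop("phi must be non-negative")
  stopifnot(all(sexes %in% c("female", "male")))
  structure(list(
    n_genes = as.integer(n_genes),
    category_proportions = p / sum(p),
    effect_range = effect_range, mu_range = mu_range, phi = phi,
    n_replicates = as.integer(n_replicates), h = h, sexes = sexes,
    prop_sex_biased = prop_sex_biased, sex_effect_range = sex_effect_range,
    prop_interaction = prop_interaction, interaction_range = interaction_range,
    libsize_sd = libsize_sd, seed = as.integer(seed)
  ), class = "sim_config")
}

REGULATORY_CATEGORIES <- c("conserved", "cis_only", "trans_only",
                           "cis_plus_trans", "cis_x_trans", "compensatory")

#' Draw per-gene regulatory ground truth
#'
#' Assigns each gene one of the six regulatory categories (multinomial in the
#' configured proportions) together with cis (`c`) and trans (`t`) log2
#' effects obeying the category sign constraints: conserved genes have
#' c = t = 0; cis-only t = 0; trans-only c = 0; cis + trans effects share a
#' sign; cis x trans effects oppose in sign; compensatory effects cancel
#' exactly (t = -c).
#'
#' @param config A [sim_config()].
#' @return `data.frame` with columns `gene_id`, `category`, `c`, `t`, `mu`
#'   (baseline log2 mean count), `phi`, `sex_effect`, `interaction`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  category <- sample(REGULATORY_CATEGORIES, n, replace = TRUE,
                     prob = config$category_proportions)
  rmag <- function(k) stats::runif(k, config$effect_range[1], config$effect_range[2])
  rsign <- function(k) sample(c(-1, 1), k, replace = TRUE)
  cc <- numeric(n); tt <- numeric(n)
  i <- category == "cis_only"
  cc[i] <- rmag(sum(i)) * rsign(sum(i))
  i <- category == "trans_only"
  tt[i] <- rmag(sum(i)) * rsign(sum(i))
  i <- category == "cis_plus_trans"
  s <- rsign(sum(i)); cc[i] <- rmag(sum(i)) * s; tt[i] <- rmag(sum(i)) * s
  i <- category == "cis_x_trans"
  s <- rsign(sum(i)); cc[i] <- rmag(sum(i)) * s; tt[i] <- -rmag(sum(i)) * s
  i <- category == "compensatory"
  cc[i] <- rmag(sum(i)) * rsign(sum(i)); tt[i] <- -cc[i]
  mu <- stats::runif(n, log2(config$mu_range[1]), log2(config$mu_range[2]))
  sex_effect <- numeric(n); interaction <- numeric(n)
  if (config$prop_sex_biased > 0) {
    i <- stats::runif(n) < config$prop_sex_biased
    sex_effect[i] <- stats::runif(sum(i), config$sex_effect_range[1],
                                  config$sex_effect_range[2]) * rsign(sum(i))
  }
  if (config$prop_interaction > 0) {
    i <- stats::runif(n) < config$prop_interaction
    interaction[i] <- stats::runif(sum(i), config$interaction_range[1],
                                   config$interaction_range[2]) * rsign(sum(i))
  }
  data.frame(gene_id = sprintf("g%05d", seq_len(n)), category = category,
             c = cc, t = tt, mu = mu, phi = config$phi,
             sex_effect = sex_effect, interaction = interaction,
             stringsAsFactors = FALSE)
}

# NB sampler degrading gracefully to Poisson as phi -> 0
rnbinom_phi <- function(n, mu, phi) {
  if (phi < 1e-12) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / phi)
}

#' Simulate a count table from regulatory ground truth
#'
#' Per-gene negative-binomial counts with log2 means following the additive
#' cis/trans mean model: parental CBR at `mu`, parental CNI at `mu + c + t`,
#' the F1 CBR allele channel at `mu + h*t` and the F1 CNI allele channel at
#' `mu + c + h*t`. In expectation the parental log2 ratio is `P = c + t`, the
#' allelic ratio is `A = c`, and their difference `T = P - A = t` for any
#' trans-dominance weight `h`. Male samples add `sex_effect`; parental CNI
#' males additionally add `interaction`. Log-normal library-size multipliers
#' are applied per sample.
#'
#' @param truth Output of [generate_truth()] (or a compatible data.frame).
#' @param config The [sim_config()] used; replication, dispersion, `h`,
#'   sexes and library-size noise are read from it.
#' @param seed Seed for the count draws; defaults to `config$seed + 1` so that
#'   truth and counts come from distinct but reproducible streams.
#' @return A [count_table()] whose design covers, per sex: parental CBR and
#'   CNI totals and the two F1 allele channels, `n_replicates` each.
#' @export
simulate_counts <- function(truth, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"), nrow(truth) > 0)
  set.seed(seed)
  reps <- config$n_replicates
  h <- config$h
  conds <- expand.grid(rep = seq_len(reps),
                       group = c("CBR_total", "CNI_total", "F1_CBR", "F1_CNI"),
                       sex = config$sexes, stringsAsFactors = FALSE)
  geno <- c(CBR_total = "CBR", CNI_total = "CNI", F1_CBR = "F1", F1_CNI = "F1")
  chan <- c(CBR_total = "total", CNI_total = "total",
            F1_CBR = "allele_CBR", F1_CNI = "allele_CNI")
  design <- data.frame(
    sample = paste(conds$group, substr(conds$sex, 1, 1), conds$rep, sep = "_"),
    genotype = geno[conds$group], sex = conds$sex, replicate = conds$rep,
    channel = chan[conds$group], stringsAsFactors = FALSE)
  rownames(design) <- NULL
  libsize <- exp(stats::rnorm(nrow(design), 0, config$libsize_sd))
  # log2 mean per gene x condition group
  base <- cbind(CBR_total = truth$mu,
                CNI_total = truth$mu + truth$c + truth$t,
                F1_CBR    = truth$mu + h * truth$t,
                F1_CNI    = truth$mu + truth$c + h * truth$t)
  counts <- matrix(0, nrow(truth), nrow(design),
                   dimnames = list(truth$gene_id, design$sample))
  for (j in seq_len(nrow(design))) {
    grp <- conds$group[j]
    lm2 <- base[, grp]
    if (conds$sex[j] == "male") {
      lm2 <- lm2 + truth$sex_effect
      if (grp == "CNI_total") lm2 <- lm2 + truth$interaction
    }
    mu_j <- libsize[j] * 2^lm2
    if (any(mu_j < 0)) stop("negative mean encountered")
    counts[, j] <- rnbinom_phi(nrow(truth), mu_j, config$phi)
  }
  count_table(counts, design)
}

#' Append summed F1 totals to a count table
#'
#' F1 total expression per library is the sum of its two allele channels; this
#' mirrors combining allele-specific counts into a single per-gene count
#' before parent-vs-hybrid contrasts.
#'
#' @param ct A `count_table` containing paired `allele_CBR`/`allele_CNI`
#'   channels for genotype `F1`.
#' @return The same table with extra `F1 total` columns (one per sex and
#'   replicate pair).
#' @export
with_f1_totals <- function(ct) {
  stopifnot(inherits(ct, "count_table"))
  d <- ct$design
  f1a <- d$genotype == "F1" & d$channel == "allele_CBR"
  if (!any(f1a)) stop("no F1 allele channels present")
  add <- list(); addd <- list()
  for (i in which(f1a)) {
    j <- which(d$genotype == "F1" & d$channel == "allele_CNI" &
               d$sex == d$sex[i] & d$replicate == d$replicate[i])
    if (length(j) != 1L) stop("unpaired F1 allele channel: ", d$sample[i])
    nm <- paste0("F1_total_", substr(d$sex[i], 1, 1), "_", d$replicate[i])
    add[[nm]] <- ct$counts[, i] + ct$counts[, j]
    addd[[nm]] <- data.frame(sample = nm, genotype = "F1", sex = d$sex[i],
                             replicate = d$replicate[i], channel = "total")
  }
  counts <- cbind(ct$counts, do.call(cbind, add))
  design <- rbind(d, do.call(rbind, addd))
  count_table(counts, design)
}

#' Simulate read-level alignment-score pairs against two references
#'
#' Emits one record per read carrying the alignment score (AS) and mismatch
#' count (nM) against each of two parental references, plus its true allele of
#' origin. Non-ambiguous reads align strictly better to their true reference
#' (higher AS, or equal AS with fewer mismatches); ambiguous reads carry
#' identical (AS, nM) pairs. Features are laid out on a single toy chromosome
#' shared by both references so that the paired BED annotations are identical.
#'
#' @param n_features Number of features.
#' @param reads_per_feature Reads simulated per feature.
#' @param p_ambiguous Probability a read is unresolvable.
#' @param allele_mix Probability a read originates from reference B; either a
#'   scalar or one value per feature (allele-specific expression varies by
#'   gene).
#' @param seed Integer seed.
#' @param p_as_tie Among resolvable reads, probability the resolution is via
#'   the mismatch tie-break (equal AS, fewer nM) rather than AS itself.
#' @param sam_a,sam_b,bed_a,bed_b Optional output paths; when given, reads are
#'   serialized as single-end SAM records with `AS:i`/`nM:i` tags and the
#'   feature intervals as BED6.
#' @return `data.frame` with columns `read_id`, `feature`, `true_origin`
#'   (`"a"`/`"b"`), `pos` (0-based leftmost), `AS_a`, `nM_a`, `AS_b`, `nM_b`,
#'   `mapped_a`, `mapped_b`.
#' @export
simulate_read_alignments <- function(n_features, reads_per_feature,
                                     p_ambiguous = 0.05, allele_mix = 0.5,
                                     seed = 1L, p_as_tie = 0.2,
                                     sam_a = NULL, sam_b = NULL,
                                     bed_a = NULL, bed_b = NULL) {
  stopifnot(p_ambiguous >= 0, p_ambiguous <= 1,
            all(allele_mix >= 0), all(allele_mix <= 1),
            length(allele_mix) %in% c(1L, n_features))
  set.seed(seed)
  allele_mix <- rep_len(allele_mix, n_features)
  feat_start <- (seq_len(n_features) - 1L) * 1000L + 200L  # 0-based
  feat_end <- feat_start + 500L
  n <- n_features * reads_per_feature
  feature <- rep(seq_len(n_features), each = reads_per_feature)
  read_len <- 100L
  pos <- feat_start[feature] + floor(stats::runif(n, 0, 500 - read_len))
  origin <- ifelse(stats::runif(n) < allele_mix[feature], "b", "a")
  amb <- stats::runif(n) < p_ambiguous
  as_tie <- !amb & stats::runif(n) < p_as_tie
  k <- 1L + stats::rpois(n, 1)           # mismatches on the losing side
  AS_true <- rep(2L * read_len, n)       # perfect-match score
  AS_other <- ifelse(amb, AS_true, ifelse(as_tie, AS_true, AS_true - 4L * k))
  nM_true <- rep(0L, n)
  nM_other <- ifelse(amb, 0L, k)
  a_is_true <- origin == "a"
  df <- data.frame(
    read_id = sprintf("r%07d", seq_len(n)), feature = sprintf("f%04d", feature),
    true_origin = origin, pos = as.integer(pos),
    AS_a = ifelse(a_is_true, AS_true, AS_other),
    nM_a = ifelse(a_is_true, nM_true, nM_other),
    AS_b = ifelse(a_is_true, AS_other, AS_true),
    nM_b = ifelse(a_is_true, nM_other, nM_true),
    mapped_a = TRUE, mapped_b = TRUE, stringsAsFactors = FALSE)
  chrom_len <- n_features * 1000L + 1000L
  if (!is.null(sam_a)) write_sim_sam(df, "a", sam_a, chrom_len)
  if (!is.null(sam_b)) write_sim_sam(df, "b", sam_b, chrom_len)
  bed <- data.frame(chrom = "chrS", start = feat_start, end = feat_end,
                    name = sprintf("f%04d", seq_len(n_features)),
                    score = 0L, strand = "+")
  if (!is.null(bed_a)) utils::write.table(bed, bed_a, sep = "\t", quote = FALSE,
                                          row.names = FALSE, col.names = FALSE)
  if (!is.null(bed_b)) utils::write.table(bed, bed_b, sep = "\t", quote = FALSE,
                                          row.names = FALSE, col.names = FALSE)
  df
}

# serialize one side of a simulated read stream as SAM (AS:i / nM:i tags)
write_sim_sam <- function(df, side, path, chrom_len) {
  AS <- df[[paste0("AS_", side)]]; nM <- df[[paste0("nM_", side)]]
  mapped <- df[[paste0("mapped_", side)]]
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:chrS\tLN:", chrom_len))
  seq100 <- paste(rep("A", 100L), collapse = "")
  o <- order(df$pos, df$read_id)
  rec <- vapply(o, function(i) {
    if (!mapped[i]) return(NA_character_)
    paste(df$read_id[i], 0L, "chrS", df$pos[i] + 1L, 60L, "100M", "*", 0L, 0L,
          seq100, "*", paste0("AS:i:", AS[i]), paste0("nM:i:", nM[i]),
          sep = "\t")
  }, character(1))
  writeLines(c(hdr, rec[!is.na(rec)]), path)
  invisible(path)
}

#' Simulate competitive assignment directly at the count level
#'
#' Given true per-feature allele counts, draws which reads are ambiguous
#' (binomial with probability `p_ambiguous`, independently per read) and
#' applies proportional redistribution of the ambiguous pool — the same
#' distribution of outcomes as materializing individual alignment-score pairs
#' and running [compare_alignments()] + [redistribute()], without read-level
#' bookkeeping. Used to exercise the full pipeline at realistic depth.
#'
#' @param n_a,n_b Integer vectors of true reads per feature from each allele.
#' @param p_ambiguous Per-read probability of being unresolvable.
#' @param seed Integer seed.
#' @return `data.frame` with columns `n_a`, `n_b`, `n_amb` (resolved and
#'   ambiguous read tallies) and redistributed counts `c_a`, `c_b`.
#' @export
compmap_from_true_counts <- function(n_a, n_b, p_ambiguous, seed = 1L) {
  stopifnot(length(n_a) == length(n_b), p_ambiguous >= 0, p_ambiguous <= 1)
  set.seed(seed)
  amb_a <- stats::rbinom(length(n_a), n_a, p_ambiguous)
  amb_b <- stats::rbinom(length(n_b), n_b, p_ambiguous)
  res <- redistribute(n_a - amb_a, n_b - amb_b, amb_a + amb_b)
  data.frame(n_a = n_a - amb_a, n_b = n_b - amb_b, n_amb = amb_a + amb_b,
             c_a = res$c_a, c_b = res$c_b)
}

# ---- coding-sequence and upstream-alignment simulators ----------------------

#' Simulate aligned ortholog CDS pairs with a substitution ledger
#'
#' Generates a random in-frame coding sequence (no internal stop codons) and
#' derives its ortholog by applying exactly the requested numbers of
#' synonymous and nonsynonymous single-nucleotide substitutions, recording
#' each in a ledger. Synonymous changes are placed at third positions of
#' four-fold degenerate codons; nonsynonymous changes at first or second
#' positions, rejecting any that would create a stop codon.
#'
#' @param n_codons Codons per sequence.
#' @param syn_subs,nonsyn_subs Requested substitution counts.
#' @param seed Integer seed.
#' @return List with `seq_a`, `seq_b` (character strings) and `ledger`, a
#'   `data.frame` of `codon` (1-based index), `pos_in_codon`, `from`, `to`,
#'   `type` (`"synonymous"`/`"nonsynonymous"`).
#' @export
simulate_ortholog_pair <- function(n_codons, syn_subs = 0, nonsyn_subs = 0,
                                   seed = 1L) {
  set.seed(seed)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc != "*"]
  fourfold <- names(gc)[vapply(names(gc), function(cd) {
    stem <- substr(cd, 1, 2)
    length(unique(gc[paste0(stem, c("A", "C", "G", "T"))])) == 1L
  }, logical(1)) & gc != "*"]
  seq_codons <- sample(codons, n_codons, replace = TRUE)
  ff_idx <- which(seq_codons %in% fourfold)
  if (syn_subs > length(ff_idx))
    stop("requested ", syn_subs, " synonymous substitutions but only ",
         length(ff_idx), " four-fold sites available")
  b_codons <- seq_codons
  ledger <- list()
  if (syn_subs > 0) {
    for (i in sample(ff_idx, syn_subs)) {
      from <- substr(b_codons[i], 3, 3)
      to <- sample(setdiff(c("A", "C", "G", "T"), from), 1)
      substr(b_codons[i], 3, 3) <- to
      ledger[[length(ledger) + 1L]] <-
        data.frame(codon = i, pos_in_codon = 3L, from = from, to = to,
                   type = "synonymous")
    }
  }
  if (nonsyn_subs > 0) {
    avail <- setdiff(seq_len(n_codons), ff_idx)
    cand <- c(avail, ff_idx)  # first/second positions usable everywhere
    placed <- 0L; tried <- character(0)
    for (i in sample(cand)) {
      if (placed == nonsyn_subs) break
      for (p in sample(1:2)) {
        from <- substr(b_codons[i], p, p)
        tos <- sample(setdiff(c("A", "C", "G", "T"), from))
        ok <- FALSE
        for (to in tos) {
          cd <- b_codons[i]; substr(cd, p, p) <- to
          if (gc[cd] != "*" && gc[cd] != gc[b_codons[i]]) {
            substr(b_codons[i], p, p) <- to
            ledger[[length(ledger) + 1L]] <-
              data.frame(codon = i, pos_in_codon = p, from = from, to = to,
                         type = "nonsynonymous")
            ok <- TRUE; placed <- placed + 1L
            break
          }
        }
        if (ok) break
      }
    }
    if (placed < nonsyn_subs)
      stop("could not place ", nonsyn_subs, " nonsynonymous substitutions")
  }
  ledger <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(codon = integer(), pos_in_codon = integer(),
               from = character(), to = character(), type = character())
  list(seq_a = paste(seq_codons, collapse = ""),
       seq_b = paste(b_codons, collapse = ""), ledger = ledger)
}

#' Simulate aligned 500-bp upstream flank pairs
#'
#' Each pair is a 500-bp random sequence and a copy in which every
#' non-overlapping 5-bp window is independently spoiled (one random base
#' change) with probability `window_mismatch_prob`, so the expected fraction
#' of non-identical windows equals that probability.
#'
#' @param n Number of pairs.
#' @param window_mismatch_prob Per-window probability of a mismatch.
#' @param seed Integer seed.
#' @param maf Optional path; when given, pairs are serialized as MAF blocks.
#' @return List of `n` elements, each `list(gene_id, seq_a, seq_b)`.
#' @export
simulate_upstream_alignments <- function(n, window_mismatch_prob, seed = 1L,
                                         maf = NULL) {
  stopifnot(window_mismatch_prob >= 0, window_mismatch_prob <= 1)
  set.seed(seed)
  out <- vector("list", n)
  for (g in seq_len(n)) {
    a <- sample(c("A", "C", "G", "T"), 500, replace = TRUE)
    b <- a
    spoil <- which(stats::runif(100) < window_mismatch_prob)
    for (w in spoil) {
      j <- (w - 1L) * 5L + sample.int(5L, 1L)
      b[j] <- sample(setdiff(c("A", "C", "G", "T"), b[j]), 1)
    }
    out[[g]] <- list(gene_id = sprintf("g%05d", g),
                     seq_a = paste(a, collapse = ""),
                     seq_b = paste(b, collapse = ""))
  }
  if (!is.null(maf)) write_maf(out, maf)
  out
}

#' Write pairwise alignment blocks in MAF format
#'
#' @param pairs List as returned by [simulate_upstream_alignments()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_maf <- function(pairs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1 scoring=none", con)
  for (p in pairs) {
    len <- nchar(p$seq_a)
    writeLines(c(
      "a score=0",
      sprintf("s refA.%s 0 %d + %d %s", p$gene_id, len, len, p$seq_a),
      sprintf("s refB.%s 0 %d + %d %s", p$gene_id, len, len, p$seq_b),
      ""), con)
  }
  invisible(path)
}

#' Read pairwise alignment blocks from a MAF file
#'
#' Minimal reader for two-sequence MAF blocks as emitted by pairwise genome
#' aligners: each `a` line starts a block whose first two `s` lines are taken
#' as the aligned pair.
#'
#' @param path MAF file path.
#' @return List of `list(gene_id, seq_a, seq_b)`, `gene_id` taken from the
#'   first source name after the assembly prefix.
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (startsWith(lines[i], "a")) {
      s1 <- strsplit(lines[i + 1L], "\\s+")[[1]]
      s2 <- strsplit(lines[i + 2L], "\\s+")[[1]]
      if (s1[1] != "s" || s2[1] != "s") stop("malformed MAF block at line ", i)
      src <- sub("^[^.]*\\.", "", s1[2])
      out[[length(out) + 1L]] <- list(gene_id = src, seq_a = s1[7], seq_b = s2[7])
      i <- i + 3L
    } else i <- i + 1L
  }
  out
}

#' Write CDS pairs to FASTA files
#'
#' @param pairs List of outputs of [simulate_ortholog_pair()].
#' @param fasta_a,fasta_b Output paths for the two orthologous sequence sets.
#' @param ids Sequence ids; default `pair0001`, ...
#' @return Invisibly, `ids`.
#' @export
write_cds_pairs <- function(pairs, fasta_a, fasta_b,
                            ids = sprintf("pair%04d", seq_along(pairs))) {
  a <- Biostrings::DNAStringSet(vapply(pairs, `[[`, "", "seq_a"))
  b <- Biostrings::DNAStringSet(vapply(pairs, `[[`, "", "seq_b"))
  names(a) <- ids; names(b) <- ids
  Biostrings::writeXStringSet(a, fasta_a)
  Biostrings::writeXStringSet(b, fasta_b)
  invisible(ids)
}
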