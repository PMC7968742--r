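test_that("truth generation respects the category mixture and sign rules", {
  cfg <- sim_config(n_genes = 100,
                    category_proportions = c(1, 0, 0, 0, 0, 0), seed = 2)
  tr <- generate_truth(cfg)
  expect_equal(nrow(tr), 100)
  expect_true(all(tr$category == "conserved"))
  expect_true(all(tr$c == 0 & tr$t == 0))

  cfg <- sim_config(n_genes = 600, seed = 5)
  tr <- generate_truth(cfg)
  comp <- tr[tr$category == "compensatory", ]
  expect_true(nrow(comp) > 0)
  expect_equal(comp$t, -comp$c)
  cis <- tr[tr$category == "cis_only", ]
  expect_true(all(cis$t == 0 & abs(cis$c) >= 0.5))
  cpt <- tr[tr$category == "cis_plus_trans", ]
  expect_true(all(sign(cpt$c) == sign(cpt$t)))
  cxt <- tr[tr$category == "cis_x_trans", ]
  expect_true(all(sign(cxt$c) != sign(cxt$t) & cxt$c + cxt$t != 0))
  mags <- abs(c(tr$c[tr$c != 0], tr$t[tr$t != 0]))
  expect_true(all(mags >= 0.5 & mags <= 2))
})

test_that("category counts fall inside an exact multinomial 99% envelope", {
  cfg <- sim_config(n_genes = 6000, seed = 7)
  tr <- generate_truth(cfg)
  obs <- table(factor(tr$category, levels = hybridex:::REGULATORY_CATEGORIES))
  # independent direct multinomial sampler defines the envelope
  set.seed(99)
  draws <- stats::rmultinom(20000, 6000, rep(1 / 6, 6))
  lo <- apply(draws, 1, stats::quantile, probs = 0.005)
  hi <- apply(draws, 1, stats::quantile, probs = 0.995)
  expect_true(all(obs >= lo & obs <= hi))
})

test_that("all-zero category proportions are rejected", {
  expect_error(sim_config(category_proportions = rep(0, 6)), "zero")
})

test_that("generators are deterministic given the seed", {
  cfg <- sim_config(n_genes = 50, seed = 42)
  expect_identical(generate_truth(cfg), generate_truth(cfg))
  tr <- generate_truth(cfg)
  expect_identical(simulate_counts(tr, cfg)$counts,
                   simulate_counts(tr, cfg)$counts)
  s1 <- tempfile(fileext = ".sam"); s2 <- tempfile(fileext = ".sam")
  simulate_read_alignments(5, 20, 0.1, seed = 9, sam_a = s1)
  simulate_read_alignments(5, 20, 0.1, seed = 9, sam_a = s2)
  expect_identical(readLines(s1), readLines(s2))
})

test_that("count means follow the cis/trans mean model", {
  # null gene: both ratios converge to 0 at low dispersion and high depth
  cfg <- sim_config(n_genes = 400, category_proportions = c(1, 0, 0, 0, 0, 0),
                    mu_range = c(5000, 5000), phi = 1e-13, n_replicates = 3,
                    libsize_sd = 0, seed = 3)
  tr <- generate_truth(cfg)
  ct <- simulate_counts(tr, cfg)
  d <- ct$design
  mean_of <- function(geno, chan) rowMeans(
    ct$counts[, d$genotype == geno & d$channel == chan, drop = FALSE])
  P <- log2(mean_of("CNI", "total") / mean_of("CBR", "total"))
  A <- log2(mean_of("F1", "allele_CNI") / mean_of("F1", "allele_CBR"))
  expect_lt(abs(mean(P)), 0.05)
  expect_lt(abs(mean(A)), 0.05)

  # compensatory genes: E[P] = 0 while E[A] = c, for any h
  cfg <- sim_config(n_genes = 500, category_proportions = c(0, 0, 0, 0, 0, 1),
                    mu_range = c(5000, 5000), phi = 1e-13, h = 0.3,
                    libsize_sd = 0, seed = 8)
  tr <- generate_truth(cfg)
  ct <- simulate_counts(tr, cfg)
  d <- ct$design
  mean_of <- function(geno, chan) rowMeans(
    ct$counts[, d$genotype == geno & d$channel == chan, drop = FALSE])
  P <- log2(mean_of("CNI", "total") / mean_of("CBR", "total"))
  A <- log2(mean_of("F1", "allele_CNI") / mean_of("F1", "allele_CBR"))
  expect_lt(abs(mean(P)), 0.05)
  expect_lt(abs(mean(A - tr$c)), 0.05)
})

test_that("raw log-ratio estimate of A recovers the cis effect", {
  # Monte-Carlo oracle: average raw allele log-ratios over many cis-only genes
  cfg <- sim_config(n_genes = 2000,
                    category_proportions = c(0, 1, 0, 0, 0, 0),
                    effect_range = c(1, 1), mu_range = c(500, 500),
                    phi = 0.05, n_replicates = 3, libsize_sd = 0, seed = 13)
  tr <- generate_truth(cfg)
  ct <- simulate_counts(tr, cfg)
  d <- ct$design
  A_hat <- log2(rowMeans(ct$counts[, d$channel == "allele_CNI"]) /
                rowMeans(ct$counts[, d$channel == "allele_CBR"]))
  expect_lt(abs(mean(abs(A_hat)) - 1), 0.05)
})

test_that("read-alignment simulation honours the ambiguity contract", {
  df <- simulate_read_alignments(20, 40, p_ambiguous = 0, seed = 4)
  v <- compare_alignments(df$AS_a, df$AS_b, df$nM_a, df$nM_b)
  expect_true(all(v %in% c("A", "B")))
  expect_identical(tolower(v), df$true_origin)

  df <- simulate_read_alignments(30, 200, p_ambiguous = 0.1,
                                 allele_mix = 0.5, seed = 6)
  expect_lt(abs(mean(df$true_origin == "b") - 0.5), 0.03)
  amb <- df$AS_a == df$AS_b & df$nM_a == df$nM_b
  expect_lt(abs(mean(amb) - 0.1), 0.02)
})

test_that("count-level assignment matches the read-level path when exact", {
  # p_ambiguous = 0: both paths must reproduce the true counts exactly
  cm <- compmap_from_true_counts(c(10L, 0L, 7L), c(3L, 5L, 0L), 0, seed = 1)
  expect_equal(cm$c_a, c(10, 0, 7))
  expect_equal(cm$c_b, c(3, 5, 0))
  # conservation under ambiguity
  cm <- compmap_from_true_counts(c(40L, 10L), c(20L, 30L), 0.3, seed = 2)
  expect_equal(cm$c_a + cm$c_b, c(60, 40))
})

test_that("ortholog-pair simulation obeys its substitution ledger", {
  p <- simulate_ortholog_pair(100, 0, 0, seed = 1)
  expect_identical(p$seq_a, p$seq_b)
  expect_equal(nrow(p$ledger), 0)

  p <- simulate_ortholog_pair(300, syn_subs = 3, nonsyn_subs = 0, seed = 2)
  expect_equal(nrow(p$ledger), 3)
  # codon-table oracle via Biostrings translation of whole sequences
  aa_a <- as.character(Biostrings::translate(Biostrings::DNAString(p$seq_a), no.init.codon = TRUE))
  aa_b <- as.character(Biostrings::translate(Biostrings::DNAString(p$seq_b), no.init.codon = TRUE))
  expect_identical(aa_a, aa_b)          # all substitutions synonymous
  diffs <- which(strsplit(p$seq_a, "")[[1]] != strsplit(p$seq_b, "")[[1]])
  expect_equal(length(diffs), 3)
  expect_setequal((p$ledger$codon - 1) * 3 + p$ledger$pos_in_codon, diffs)
  expect_false(grepl("\\*", substr(aa_b, 1, nchar(aa_b))))

  p <- simulate_ortholog_pair(50, syn_subs = 2, nonsyn_subs = 4, seed = 3)
  aa_a <- strsplit(as.character(
    Biostrings::translate(Biostrings::DNAString(p$seq_a), no.init.codon = TRUE)), "")[[1]]
  aa_b <- strsplit(as.character(
    Biostrings::translate(Biostrings::DNAString(p$seq_b), no.init.codon = TRUE)), "")[[1]]
  expect_equal(sum(aa_a != aa_b), 4)

  expect_error(simulate_ortholog_pair(3, syn_subs = 10, seed = 1), "available")
})

test_that("upstream-alignment simulation hits the window mismatch rate", {
  up <- simulate_upstream_alignments(3, 0, seed = 1)
  expect_identical(up[[1]]$seq_a, up[[1]]$seq_b)
  up <- simulate_upstream_alignments(3, 1, seed = 1)
  sc <- conservation_scores(up)
  expect_true(all(sc$one_minus_pcons == 1))
  # binomial oracle: mean over 1000 pairs x 100 windows
  up <- simulate_upstream_alignments(1000, 0.2, seed = 2)
  sc <- conservation_scores(up)
  ci <- stats::qbinom(c(0.005, 0.995), 1000 * 100, 0.2) / (1000 * 100)
  expect_gte(mean(sc$one_minus_pcons), ci[1])
  expect_lte(mean(sc$one_minus_pcons), ci[2])
})

test_that("MAF serialization round-trips", {
  up <- simulate_upstream_alignments(4, 0.3, seed = 5)
  path <- tempfile(fileext = ".maf")
  write_maf(up, path)
  back <- read_maf(path)
  expect_equal(length(back), 4)
  expect_identical(vapply(back, `[[`, "", "seq_a"),
                   vapply(up, `[[`, "", "seq_a"))
  expect_identical(vapply(back, `[[`, "", "gene_id"),
                   vapply(up, `[[`, "", "gene_id"))
})
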