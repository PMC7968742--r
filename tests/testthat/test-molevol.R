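# independent mutation-enumeration oracle for synonymous site counts,
# classifying each possible point mutation via Biostrings::translate
oracle_syn_sites <- function(seq) {
  cods <- substring(seq, seq(1, nchar(seq) - 2, 3), seq(3, nchar(seq), 3))
  aa <- function(cd) as.character(Biostrings::translate(Biostrings::DNAString(cd),
                                                        no.init.codon = TRUE))
  s <- 0
  for (cd in cods) {
    for (p in 1:3) for (nt in setdiff(c("A", "C", "G", "T"), substr(cd, p, p))) {
      alt <- cd; substr(alt, p, p) <- nt
      if (aa(alt) == aa(cd)) s <- s + 1 / 3
    }
  }
  s
}

codon_string <- function(counts) {
  # counts: named vector codon -> multiplicity
  paste(rep(names(counts), counts), collapse = "")
}

test_that("identical coding pairs have zero divergence", {
  p <- simulate_ortholog_pair(300, 0, 0, seed = 3)
  kk <- kaks(p$seq_a, p$seq_b)
  expect_equal(kk$Ka, 0)
  expect_equal(kk$Ks, 0)
})

test_that("a single third-position synonymous change moves only Ks", {
  base <- paste(rep("GGTAAACTG", 20), collapse = "")  # Gly-Lys-Leu repeats
  mut <- base
  substr(mut, 3, 3) <- "C"  # GGT -> GGC, synonymous
  kk <- kaks(base, mut)
  expect_equal(kk$Ka, 0)
  expect_gt(kk$Ks, 0)
})

test_that("Ks on ledgered simulations matches the site-counting oracle", {
  p <- simulate_ortholog_pair(300, syn_subs = 3, nonsyn_subs = 0, seed = 11)
  kk <- kaks(p$seq_a, p$seq_b)
  expect_equal(kk$Ka, 0)
  S_oracle <- (oracle_syn_sites(p$seq_a) + oracle_syn_sites(p$seq_b)) / 2
  ks_oracle <- -0.75 * log(1 - 4 * (3 / S_oracle) / 3)
  expect_equal(kk$Ks, ks_oracle, tolerance = 1e-9)
})

test_that("kaks is symmetric in its arguments", {
  p <- simulate_ortholog_pair(150, syn_subs = 4, nonsyn_subs = 5, seed = 13)
  k1 <- kaks(p$seq_a, p$seq_b)
  k2 <- kaks(p$seq_b, p$seq_a)
  expect_equal(k1$Ka, k2$Ka, tolerance = 1e-12)
  expect_equal(k1$Ks, k2$Ks, tolerance = 1e-12)
})

test_that("synonymous saturation is flagged", {
  a <- paste(rep("GGT", 10), collapse = "")
  b <- paste(rep("GGC", 10), collapse = "")
  kk <- kaks(a, b)  # every synonymous site substituted: p_s = 1
  expect_true(kk$saturated)
  expect_true(is.na(kk$Ks))
})

test_that("ENC hits its theoretical extremes", {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  uniform <- codon_string(stats::setNames(rep(10, length(sense)), sense))
  expect_equal(enc(uniform), 61)
  # exactly one codon per amino acid
  one_per_aa <- vapply(unique(gc[gc != "*"]),
                       function(a) names(gc)[gc == a][1], character(1))
  minimal <- codon_string(stats::setNames(rep(10, length(one_per_aa)),
                                          one_per_aa))
  expect_equal(enc(minimal), 20)
  # permutation invariance
  set.seed(17)
  cods <- sample(sense, 200, replace = TRUE)
  s1 <- paste(cods, collapse = "")
  s2 <- paste(sample(cods), collapse = "")
  expect_equal(enc(s1), enc(s2))
})

test_that("ENC increases with codon-usage evenness", {
  gc <- Biostrings::GENETIC_CODE
  build <- function(w) {
    # every degenerate family gets usage (w, 1-w) over its first two codons
    counts <- integer(0)
    for (a in unique(gc[gc != "*"])) {
      cods <- names(gc)[gc == a]
      if (length(cods) == 1L) {
        counts[cods] <- 20L
      } else {
        counts[cods[1]] <- round(20 * w)
        counts[cods[2]] <- 20L - round(20 * w)
      }
    }
    codon_string(counts[counts > 0])
  }
  e <- vapply(c(0.95, 0.8, 0.65), function(w) enc(build(w)), numeric(1))
  expect_true(all(diff(e) > 0))
})

test_that("Ks' removes the linear ENC trend", {
  set.seed(19)
  enc_v <- runif(200, 35, 61)
  ks_v <- 0.5 - 0.01 * enc_v + rnorm(200, 0, 0.02)
  ksp <- ks_correct(ks_v, enc_v)
  # independent OLS oracle via closed-form slope
  b <- stats::cov(ks_v, enc_v) / stats::var(enc_v)
  expect_equal(ksp, ks_v + b * (60 - enc_v), tolerance = 1e-12)
  # residual slope of Ks' on ENC is exactly zero
  fit <- stats::lm(ksp ~ enc_v)
  expect_lt(abs(unname(stats::coef(fit)[2])), 1e-10)
  # linearity of the mean shift
  expect_equal(mean(ksp) - mean(ks_v), b * (60 - mean(enc_v)),
               tolerance = 1e-12)
  # all ENC at the anchor: no adjustment
  expect_equal(ks_correct(ks_v[1:5], rep(60, 5)), ks_v[1:5])
})

test_that("the coding-difference identity evaluates as printed", {
  expect_equal(expected_coding_differences(0.2, 0.25, 100), 5)
})

test_that("window conservation scores behave at the boundaries", {
  a <- paste(rep("ACGTA", 100), collapse = "")
  expect_equal(upstream_conservation(a, a)$one_minus_pcons, 0)
  b <- a
  substr(b, 7, 7) <- "T"  # one base: exactly one spoiled window
  expect_equal(upstream_conservation(a, b)$one_minus_pcons, 0.01)
  # gap windows count as non-identical
  g <- a
  substr(g, 1, 1) <- "-"
  got <- upstream_conservation(g, g)
  expect_equal(got$one_minus_pcons, 0.01)
  expect_error(upstream_conservation("ACGT", "ACGT"), "shorter")
})

test_that("flank extraction is strand-aware and truncates at edges", {
  ann <- data.frame(gene = c("p", "m", "edge"), chrom = "I",
                    start = c(1000, 1000, 100), end = c(2000, 2000, 400),
                    strand = c("+", "-", "+"))
  fl <- extract_flanks(ann, c(I = 10000))
  expect_equal(fl$flank_start, c(500, 2000, 0))
  expect_equal(fl$flank_end, c(1000, 2500, 100))
  expect_equal(fl$truncated, c(FALSE, FALSE, TRUE))
  expect_equal(fl$length, c(500, 500, 100))
})

test_that("per-gene molecular evolution table assembles correctly", {
  pairs <- lapply(1:5, function(i)
    simulate_ortholog_pair(120, syn_subs = i, nonsyn_subs = 1, seed = i))
  stats_tab <- molevol_stats(pairs)
  expect_equal(nrow(stats_tab), 5)
  expect_true(all(stats_tab$Ka >= 0 & stats_tab$Ks >= 0))
  expect_true(all(stats_tab$ENC >= 20 & stats_tab$ENC <= 61))
  expect_true(all(is.finite(stats_tab$Ks_prime)))
})
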