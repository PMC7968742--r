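test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(c(10, 20, 40,
                10, 20, 40), nrow = 3)
  expect_equal(unname(size_factors(m)), c(1, 1))

  m2 <- cbind(a = c(10, 20, 40), b = c(20, 40, 80))
  sf <- size_factors(m2)
  expect_equal(unname(sf["b"] / sf["a"]), 2)

  # direct arithmetic oracle on a 3-gene toy matrix
  m3 <- cbind(s1 = c(4, 9, 25), s2 = c(16, 36, 100), s3 = c(1, 1, 1))
  geo <- exp(rowMeans(log(m3)))
  raw <- apply(m3, 2, function(col) stats::median(col / geo))
  oracle <- raw / exp(mean(log(raw)))
  expect_equal(size_factors(m3), oracle)
})

test_that("size factors agree with the DESeq2 median-of-ratios oracle", {
  skip_if_not_installed("DESeq2")
  set.seed(7)
  m <- matrix(rnbinom(600, mu = 100, size = 10), nrow = 100)
  sf <- size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ref <- ref / exp(mean(log(ref)))
  expect_equal(unname(sf), unname(ref), tolerance = 1e-8)
})

test_that("abundance filter applies the strict scaled-count rule", {
  m <- rbind(zero = rep(0, 6),
             kept = c(11, 11, 11, 0, 0, 0),
             boundary = c(10, 10, 10, 10, 10, 10),
             two = c(100, 100, 0, 0, 0, 0))
  ct <- toy_count_table(m)
  out <- filter_genes(ct, sf = rep(1, 6))
  expect_setequal(rownames(out$counts), "kept")
})

test_that("a flat gene yields a near-zero, non-significant fold change", {
  set.seed(2)
  m <- matrix(rnbinom(200 * 6, mu = 200, size = 1e6), ncol = 6)
  rownames(m) <- sprintf("g%03d", 1:200)
  ct <- toy_count_table(m)
  res <- de_pairwise(ct, rep(TRUE, 6), ct$design$genotype, "CNI", "CBR")
  expect_lt(max(abs(res$log2FC)), 0.3)
  expect_false(any(res$significant))
})

test_that("null simulation is calibrated at raw p < 0.05", {
  cfg <- sim_config(n_genes = 3000, category_proportions = c(1, 0, 0, 0, 0, 0),
                    seed = 17)
  tr <- generate_truth(cfg)
  ct <- simulate_counts(tr, cfg)
  reg <- regulatory_contrasts(ct)
  band <- 3 * sqrt(0.05 * 0.95 / 3000)
  for (fam in c("P", "A", "T")) {
    expect_lt(abs(mean(reg[[fam]]$p < 0.05) - 0.05), band)
  }
})

test_that("large effects are detected with high power", {
  # Monte-Carlo power oracle: |log2FC| = 2, depth 500, 3 reps. Null genes are
  # mixed in so median-of-ratios normalization has a stable anchor.
  cfg <- sim_config(n_genes = 1000, category_proportions = c(1, 1, 0, 0, 0, 0),
                    effect_range = c(2, 2), mu_range = c(500, 500), seed = 19)
  tr <- generate_truth(cfg)
  ct <- simulate_counts(tr, cfg)
  reg <- regulatory_contrasts(ct)
  cis <- tr$category == "cis_only"
  expect_gt(mean(reg$A$significant[cis]), 0.95)
  expect_gt(mean(reg$P$significant[cis]), 0.95)
})

test_that("BH adjustment matches a direct step-up oracle", {
  set.seed(23)
  for (i in 1:5) {
    p <- runif(200)^(1 + i / 2)
    expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
  # padj monotone in p rank
  p <- runif(100)
  adj <- stats::p.adjust(p, "BH")
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("T equals P minus A at the estimate level", {
  cfg <- sim_config(n_genes = 150, seed = 29)
  tr <- generate_truth(cfg)
  ct <- simulate_counts(tr, cfg)
  reg <- regulatory_contrasts(ct)
  expect_equal(reg$T$log2FC, reg$P$log2FC - reg$A$log2FC, tolerance = 1e-6)
})

test_that("the trans test is centred on the true trans effect", {
  cfg <- sim_config(n_genes = 800, category_proportions = c(0, 0, 1, 0, 0, 0),
                    effect_range = c(1.5, 1.5), mu_range = c(800, 800),
                    seed = 31)
  tr <- generate_truth(cfg)
  ct <- simulate_counts(tr, cfg)
  reg <- regulatory_contrasts(ct)
  expect_lt(abs(mean(reg$T$log2FC * sign(tr$t)) - 1.5), 0.05)

  # cis-only truth: T centred at zero with calibrated rejection
  cfg0 <- sim_config(n_genes = 2000, category_proportions = c(0, 1, 0, 0, 0, 0),
                     seed = 37)
  tr0 <- generate_truth(cfg0)
  ct0 <- simulate_counts(tr0, cfg0)
  reg0 <- regulatory_contrasts(ct0)
  expect_lt(abs(mean(reg0$T$log2FC)), 0.05)
  expect_lte(mean(reg0$T$p < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("estimates converge to truth at high depth and low dispersion", {
  cfg <- sim_config(n_genes = 400, mu_range = c(1e4, 1e4), phi = 0.001,
                    n_replicates = 4, seed = 41)
  tr <- generate_truth(cfg)
  ct <- simulate_counts(tr, cfg)
  reg <- regulatory_contrasts(ct)
  m <- match(reg$A$gene, tr$gene_id)
  expect_lt(abs(mean(reg$A$log2FC - tr$c[m])), 0.02)
  expect_lt(abs(mean(reg$T$log2FC - tr$t[m])), 0.02)
})

test_that("results are invariant to column order and global rescaling", {
  cfg <- sim_config(n_genes = 80, seed = 43)
  tr <- generate_truth(cfg)
  ct <- simulate_counts(tr, cfg)
  reg <- regulatory_contrasts(ct)
  perm <- sample(ncol(ct$counts))
  ct2 <- subset_count_table(ct, samples = perm)
  reg2 <- regulatory_contrasts(ct2)
  expect_equal(reg$P$log2FC, reg2$P$log2FC, tolerance = 1e-8)
  expect_equal(reg$A$padj, reg2$A$padj, tolerance = 1e-8)

  ct3 <- ct; ct3$counts <- ct3$counts * 2
  reg3 <- regulatory_contrasts(ct3)
  expect_equal(reg$P$log2FC, reg3$P$log2FC, tolerance = 0.02)
})

test_that("species/sex model separates main effects and interaction", {
  base <- sim_config(n_genes = 300, sexes = c("female", "male"), seed = 47,
                     category_proportions = c(1, 0, 0, 0, 0, 0),
                     mu_range = c(500, 500), prop_sex_biased = 1,
                     sex_effect_range = c(1.5, 1.5))
  tr <- generate_truth(base)
  ct <- simulate_counts(tr, base)
  fits <- species_sex_fit(ct)
  expect_gt(mean(fits$sex$significant), 0.9)
  expect_lt(mean(fits$species$significant), 0.12)
  expect_lt(mean(fits$interaction$significant), 0.12)
  # recovered as male/female-biased matching the simulated sign
  bias <- call_sex_bias(fits$sex)
  m <- match(fits$sex$gene, tr$gene_id)
  want <- ifelse(tr$sex_effect[m] > 0, "male", "female")
  expect_gt(mean(bias == want), 0.9)

  # interaction-only genes: interaction significant, main effects attenuated
  cfg_i <- sim_config(n_genes = 300, sexes = c("female", "male"), seed = 53,
                      category_proportions = c(1, 0, 0, 0, 0, 0),
                      mu_range = c(500, 500), prop_interaction = 1,
                      interaction_range = c(2, 2))
  tri <- generate_truth(cfg_i)
  cti <- simulate_counts(tri, cfg_i)
  fi <- species_sex_fit(cti)
  expect_gt(mean(fi$interaction$significant), 0.9)
})
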