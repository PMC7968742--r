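#!/usr/bin/env Rscript
# Stage 2: competitive allele-specific read assignment, demonstrated at read
# level. Reads with a known allele of origin are serialized as paired SAM
# alignments against the two references, assigned back by comparing
# alignment score then mismatch count, and tallied per feature with
# proportional redistribution of ambiguous reads.

suppressMessages(library(hybridex))
dir.create("results", showWarnings = FALSE)

td <- tempfile("compmap"); dir.create(td)
set.seed(20260927)
mix <- runif(200, 0.1, 0.9)
stream <- simulate_read_alignments(
  n_features = 200, reads_per_feature = 100, p_ambiguous = 0.1,
  allele_mix = mix, seed = 20260927,
  sam_a = file.path(td, "refA.sam"), sam_b = file.path(td, "refB.sam"),
  bed_a = file.path(td, "refA.bed"), bed_b = file.path(td, "refB.bed"))

counts <- count_features(file.path(td, "refA.sam"), file.path(td, "refB.sam"),
                         file.path(td, "refA.bed"), file.path(td, "refB.bed"))
truth_a <- sapply(counts$feature, function(f)
  sum(stream$true_origin == "a" & stream$feature == f))
counts$true_a <- unname(truth_a)
hybridex:::write_tsv_with_header(counts, "results/allele_counts.tsv")

r <- cor(counts$c_a, counts$true_a)
cat("reads assigned:", sum(counts$n_a + counts$n_b),
    "ambiguous:", sum(counts$n_amb), "\n")
cat(sprintf("correlation of assigned vs true per-feature counts: %.4f\n", r))
cat(sprintf("mean absolute count error per feature: %.2f reads\n",
            mean(abs(counts$c_a - counts$true_a))))
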