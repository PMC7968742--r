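#!/usr/bin/env Rscript
# Stage 1: generate the synthetic hybrid experiment with known regulatory
# ground truth — two parental genotypes and F1 allele channels, both sexes,
# triplicate libraries — plus a toy gene annotation (chromosomes I-V and X,
# arm/center domains). All downstream stages read from results/.

suppressMessages(library(hybridex))

dir.create("results", showWarnings = FALSE)
cfg <- sim_config(n_genes = 2000, sexes = c("female", "male"),
                  prop_sex_biased = 0.6, seed = 20260927L)
truth <- generate_truth(cfg)
counts <- simulate_counts(truth, cfg)
annot <- simulate_annotation(truth$gene_id, seed = cfg$seed + 2L)

write_tsv_with_header <- hybridex:::write_tsv_with_header
write_tsv_with_header(truth, "results/truth.tsv")
write_count_table(counts, "results/counts.tsv", "results/design.tsv")
write_tsv_with_header(annot, "results/annotation.tsv")

cat("simulated", nrow(truth), "genes x", ncol(counts$counts), "samples\n")
print(table(truth$category))
cat("median baseline depth:",
    round(stats::median(2^truth$mu)), "counts\n")
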