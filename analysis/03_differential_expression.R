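#!/usr/bin/env Rscript
# Stage 3: normalization, abundance filtering and negative-binomial Wald
# contrasts. Per sex: the joint parental/allelic model giving the parental
# ratio P, the allelic (cis) ratio A and the trans effect T = P - A; plus
# the species*sex factorial on parental totals.

suppressMessages(library(hybridex))
counts <- read_count_table("results/counts.tsv", "results/design.tsv")

for (sx in c("female", "male")) {
  sub <- subset_count_table(counts, samples = counts$design$sex == sx)
  sub <- filter_genes(with_f1_totals(sub))
  reg <- regulatory_contrasts(sub, sex = sx)
  for (nm in names(reg))
    write_contrast(reg[[nm]],
                   sprintf("results/de_%s_%s.tsv", sx, nm),
                   contrast = nm)
  cat(sprintf("[%s] %d genes kept; significant at 5%% FDR: P %d, A %d, T %d\n",
              sx, nrow(sub$counts), sum(reg$P$significant),
              sum(reg$A$significant), sum(reg$T$significant)))
}

fct <- filter_genes(counts)
fits <- species_sex_fit(fct)
for (nm in names(fits))
  write_contrast(fits[[nm]], sprintf("results/de_species_sex_%s.tsv", nm),
                 contrast = nm)
bias <- call_sex_bias(fits$sex)
cat(sprintf("species*sex on %d genes: %.1f%% sex-biased, %d interactions\n",
            nrow(fct$counts), 100 * mean(bias != "neutral"),
            sum(fits$interaction$significant)))
groups <- call_species_sex_group(fits$species, fits$sex, fits$interaction)
hybridex:::write_tsv_with_header(
  data.frame(gene = fits$species$gene, group = groups, sex_bias = bias),
  "results/species_sex_groups.tsv")
print(sort(table(groups), decreasing = TRUE)[1:6])
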