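#!/usr/bin/env Rscript
# Stage 4: per-gene classification. Expression inheritance (additive /
# dominant / transgressive, with Euclidean misexpression distance),
# cis/trans regulatory divergence from the P/A/T significance patterns, and
# the hemizygous-X scheme for X-linked genes in males (F1 males carry the
# C. nigoni X, so allelic contrasts are impossible there).

suppressMessages(library(hybridex))
counts <- read_count_table("results/counts.tsv", "results/design.tsv")
annot <- read.delim("results/annotation.tsv", comment.char = "#")
truth <- read.delim("results/truth.tsv", comment.char = "#")

for (sx in c("female", "male")) {
  cl <- classify_regulation(counts, sex = sx)
  an <- annot[match(cl$cis_trans$gene, annot$gene), ]
  tab <- cbind(cl$cis_trans, chrom = an$chrom, domain = an$domain, sex = sx,
               inheritance = cl$inheritance$category, d = cl$inheritance$d)
  tab$x_male_category <- "not_applicable"
  if (sx == "male") {
    xi <- which(tab$chrom == "X")
    tab$x_male_category[xi] <- call_x_male(cl$contrasts$P[xi, ],
                                           cl$inheritance[xi, ])
  }
  hybridex:::write_tsv_with_header(tab,
                                   sprintf("results/classification_%s.tsv", sx))
  cat(sprintf("[%s] %d genes classified\n", sx, nrow(tab)))
  print(table(tab$category))
  agree <- mean(tab$category ==
                sub("^cis_x_trans$", "cis_x_trans_compensatory",
                    truth$category[match(tab$gene, truth$gene_id)]))
  cat(sprintf("  agreement with generative truth: %.1f%%\n", 100 * agree))
  cat(sprintf("  mean misexpression distance d: %.2f log2 units\n",
              mean(tab$d, na.rm = TRUE)))
  if (sx == "male")
    print(table(tab$x_male_category[tab$chrom == "X"]))
  sm <- summarize_categories(tab, by = "chrom")
  hybridex:::write_tsv_with_header(sm,
    sprintf("results/category_by_chromosome_%s.tsv", sx))
}
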