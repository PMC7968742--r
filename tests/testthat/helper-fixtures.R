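# Shared fixtures: contrast-result stubs and tiny count tables built in code.

# hand-assembled contrast_result rows for classifier truth-table tests
stub_result <- function(log2FC, significant, gene = NULL) {
  n <- max(length(log2FC), length(significant))
  log2FC <- rep_len(log2FC, n); significant <- rep_len(significant, n)
  if (is.null(gene)) gene <- sprintf("g%03d", seq_len(n))
  res <- data.frame(gene = gene, log2FC = log2FC, SE = 0.1,
                    stat = log2FC / 0.1,
                    p = ifelse(significant, 1e-4, 0.5),
                    padj = ifelse(significant, 1e-3, 0.7),
                    significant = significant,
                    direction = ifelse(log2FC == 0, 0L,
                                       as.integer(sign(log2FC))),
                    stringsAsFactors = FALSE)
  class(res) <- c("contrast_result", "data.frame")
  res
}

# minimal two-group count table: genes x (nA + nB) samples, groups CBR/CNI
toy_count_table <- function(counts, n_a = ncol(counts) %/% 2) {
  n <- ncol(counts)
  design <- data.frame(
    sample = paste0("s", seq_len(n)),
    genotype = rep(c("CBR", "CNI"), c(n_a, n - n_a)),
    sex = "female",
    replicate = c(seq_len(n_a), seq_len(n - n_a)),
    channel = "total", stringsAsFactors = FALSE)
  colnames(counts) <- design$sample
  count_table(counts, design)
}

# direct BH step-up oracle, independent of stats::p.adjust
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# two-sided Fisher p by exhaustive hypergeometric enumeration
fisher_oracle <- function(n11, n10, n01, n00) {
  m <- n11 + n10          # set size
  n_ <- n01 + n00         # out-of-set size
  k <- n11 + n01          # stratum size
  kk <- max(0, k - n_):min(k, m)
  probs <- stats::dhyper(kk, m, n_, k)
  obs <- stats::dhyper(n11, m, n_, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
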