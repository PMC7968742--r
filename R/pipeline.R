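#' Configuration for an end-to-end synthetic run
#'
#' @param out_dir Output directory for the report bundle.
#' @param sim A [sim_config()] describing the synthetic experiment.
#' @param p_ambiguous Per-read probability of ambiguous alignment used when
#'   passing F1 allele counts through competitive-assignment simulation;
#'   set to `NULL` to use the true allele counts directly.
#' @param fdr FDR level for all contrast families (default 0.05).
#' @param filter_min_scaled,filter_min_samples Abundance filter thresholds
#'   (defaults: > 10 scaled counts in >= 3 samples).
#' @param enrich_p,enrich_lor Dual enrichment rule thresholds (defaults
#'   p < 0.05 and |log2 OR| > 0.5).
#' @param hemizygous_x Apply the X-male scheme (default `TRUE`); F1 males are
#'   assumed to carry the C. nigoni X.
#' @param do_cluster Run co-expression clustering (default `FALSE`).
#' @param k Cluster count when clustering (default 15).
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, sim = sim_config(), p_ambiguous = 0.05,
                       fdr = 0.05, filter_min_scaled = 10,
                       filter_min_samples = 3, enrich_p = 0.05,
                       enrich_lor = 0.5, hemizygous_x = TRUE,
                       do_cluster = FALSE, k = 15) {
  stopifnot(fdr > 0, filter_min_scaled > 0, filter_min_samples > 0,
            enrich_p > 0, enrich_lor > 0)
  structure(as.list(environment()), class = "run_config")
}

# tiny rolling hash for provenance headers (no external digest dependency)
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Simulate a gene annotation for synthetic genes
#'
#' Places genes uniformly over six chromosomes (I-V and X) with sequential
#' 2-kb loci and labels arm/center domains by chromosome thirds (outer thirds
#' are arms).
#'
#' @param gene_ids Character vector of gene ids.
#' @param seed Integer seed.
#' @return `data.frame`: `gene`, `chrom`, `start`, `end`, `strand`, `domain`.
#' @export
simulate_annotation <- function(gene_ids, seed = 1L) {
  set.seed(seed)
  chroms <- c("I", "II", "III", "IV", "V", "X")
  chrom <- sample(chroms, length(gene_ids), replace = TRUE)
  ord <- stats::ave(seq_along(gene_ids), chrom, FUN = seq_along)
  n_per <- stats::ave(seq_along(gene_ids), chrom, FUN = length)
  start <- (ord - 1L) * 2000L
  end <- start + 1500L
  third <- (ord - 0.5) / n_per
  domain <- ifelse(third < 1 / 3 | third > 2 / 3, "arm", "center")
  data.frame(gene = gene_ids, chrom = chrom, start = start, end = end,
             strand = sample(c("+", "-"), length(gene_ids), replace = TRUE),
             domain = domain, stringsAsFactors = FALSE)
}

#' Classify regulation for one sex context of a count table
#'
#' Convenience driver: filters, fits the joint parental/allelic model
#' ([regulatory_contrasts()]), the three inheritance contrasts (on F1 totals
#' summed from the allele channels), and returns the per-gene calls.
#'
#' @param ct A `count_table` with parental totals and F1 allele channels.
#' @param sex Sex context.
#' @param alpha FDR level.
#' @param dispersion Dispersion method passed to the engine.
#' @param min_scaled,min_samples Abundance filter thresholds.
#' @return List: `cis_trans` (from [call_cis_trans()]), `inheritance` (from
#'   [call_inheritance()]), `contrasts` (the underlying `contrast_result`s),
#'   `genes` (ids kept by the filter).
#' @export
classify_regulation <- function(ct, sex = "female", alpha = 0.05,
                                dispersion = "trend", min_scaled = 10,
                                min_samples = 3) {
  sel <- ct$design$sex == sex
  sub <- subset_count_table(ct, samples = sel)
  sub <- with_f1_totals(sub)
  sub <- filter_genes(sub, min_scaled = min_scaled, min_samples = min_samples)
  reg <- regulatory_contrasts(sub, sex = sex, dispersion = dispersion,
                              alpha = alpha)
  d <- sub$design
  tot <- d$channel == "total"
  grp <- ifelse(d$genotype == "F1", "F1", d$genotype)
  f1_cbr <- de_pairwise(sub, tot, grp[tot], "F1", "CBR",
                        dispersion = dispersion, alpha = alpha)
  f1_cni <- de_pairwise(sub, tot, grp[tot], "F1", "CNI",
                        dispersion = dispersion, alpha = alpha)
  cni_cbr <- de_pairwise(sub, tot, grp[tot], "CNI", "CBR",
                         dispersion = dispersion, alpha = alpha)
  list(cis_trans = call_cis_trans(reg$P, reg$A, reg$T),
       inheritance = call_inheritance(f1_cbr, f1_cni, cni_cbr),
       contrasts = list(P = reg$P, A = reg$A, T = reg$T,
                        f1_vs_cbr = f1_cbr, f1_vs_cni = f1_cni,
                        cni_vs_cbr = cni_cbr),
       genes = rownames(sub$counts))
}

#' Category count summary tables
#'
#' Tabulates gene counts and proportions by category and any further strata
#' (chromosome, sex context), the numeric equivalent of stacked category
#' barplots.
#'
#' @param calls `data.frame` with at least a `category` column; optional
#'   grouping columns named in `by`.
#' @param by Character vector of additional grouping columns present in
#'   `calls`.
#' @return `data.frame` of `category`, grouping columns, `n` and `prop`
#'   (proportion within the grouping stratum).
#' @export
summarize_categories <- function(calls, by = character(0)) {
  if (nrow(calls) == 0L)
    return(data.frame(category = character(0), n = integer(0),
                      prop = numeric(0)))
  stopifnot("category" %in% names(calls), all(by %in% names(calls)))
  f <- calls[, c("category", by), drop = FALSE]
  tab <- as.data.frame(table(f), stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "n"
  if (length(by) > 0) {
    strat <- interaction(tab[, by, drop = FALSE], drop = FALSE)
    tot <- stats::ave(tab$n, strat, FUN = sum)
  } else tot <- sum(tab$n)
  tab$prop <- ifelse(tot > 0, tab$n / tot, 0)
  tab
}

#' Run the full synthetic pipeline
#'
#' Executes simulate -> (competitive-assignment noise) -> filter/contrasts ->
#' classification -> enrichment (-> clustering), writing per-stage TSVs and a
#' structured log into `config$out_dir`. Every output carries a header with
#' the config hash and seed; the run is deterministic given the config.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the main per-stage objects (`truth`,
#'   `counts`, `calls` per sex, `summary`, `enrichment`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- paste0("hybridex config=", config_hash(unclass(config)),
                " seed=", config$sim$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  log_lines <- c(hdr, paste0("R=", as.character(getRversion())))
  truth <- stage("simulate", generate_truth(config$sim))
  ct <- stage("simulate", simulate_counts(truth, config$sim))
  annot <- simulate_annotation(truth$gene_id, seed = config$sim$seed + 2L)
  write_tsv_with_header(truth, file.path(config$out_dir, "truth.tsv"), hdr)
  write_count_table(ct, file.path(config$out_dir, "counts.tsv"),
                    file.path(config$out_dir, "design.tsv"), header = hdr)
  write_tsv_with_header(annot, file.path(config$out_dir, "annotation.tsv"), hdr)
  if (!is.null(config$p_ambiguous)) {
    ct <- stage("assign", {
      d <- ct$design
      for (sx in unique(d$sex)) {
        pa <- which(d$genotype == "F1" & d$channel == "allele_CBR" & d$sex == sx)
        for (i in pa) {
          j <- which(d$genotype == "F1" & d$channel == "allele_CNI" &
                     d$sex == sx & d$replicate == d$replicate[i])
          cm <- compmap_from_true_counts(ct$counts[, i], ct$counts[, j],
                                         config$p_ambiguous,
                                         seed = config$sim$seed + 100L + i)
          ct$counts[, i] <- cm$c_a
          ct$counts[, j] <- cm$c_b
        }
      }
      ct
    })
    log_lines <- c(log_lines, paste0("assign p_ambiguous=", config$p_ambiguous))
  }
  calls <- list(); summaries <- list(); enrich <- list()
  for (sx in config$sim$sexes) {
    cl <- stage("classify",
                classify_regulation(ct, sex = sx, alpha = config$fdr,
                                    min_scaled = config$filter_min_scaled,
                                    min_samples = config$filter_min_samples))
    an <- annot[match(cl$cis_trans$gene, annot$gene), ]
    ctab <- cbind(cl$cis_trans, chrom = an$chrom, domain = an$domain,
                  sex = sx, inheritance = cl$inheritance$category,
                  d = cl$inheritance$d)
    if (config$hemizygous_x && sx == "male") {
      xi <- which(ctab$chrom == "X")
      ctab$x_male_category <- "not_applicable"
      if (length(xi) > 0)
        ctab$x_male_category[xi] <-
          call_x_male(cl$contrasts$P[xi, , drop = FALSE],
                      cl$inheritance[xi, , drop = FALSE])
    } else ctab$x_male_category <- "not_applicable"
    calls[[sx]] <- ctab
    write_tsv_with_header(ctab,
                          file.path(config$out_dir,
                                    paste0("classification_", sx, ".tsv")), hdr)
    summaries[[sx]] <- summarize_categories(ctab, by = "chrom")
    er <- stage("enrich", {
      do.call(rbind, lapply(unique(ctab$category), function(cat)
        do.call(rbind, lapply(unique(ctab$chrom), function(ch)
          fisher_enrichment(ctab$category == cat, ctab$chrom == ch,
                            p_cut = config$enrich_p,
                            lor_cut = config$enrich_lor,
                            set_label = cat, stratum_label = ch)))))
    })
    er$sex <- sx
    enrich[[sx]] <- er
    write_tsv_with_header(er, file.path(config$out_dir,
                                        paste0("enrichment_", sx, ".tsv")), hdr)
    log_lines <- c(log_lines,
                   paste0("classify sex=", sx, " genes_in=", nrow(truth),
                          " genes_kept=", length(cl$genes)))
  }
  summary_tab <- do.call(rbind, lapply(names(summaries), function(sx)
    cbind(summaries[[sx]], sex = sx)))
  write_tsv_with_header(summary_tab,
                        file.path(config$out_dir, "category_summary.tsv"), hdr)
  cluster_model <- NULL
  if (config$do_cluster) {
    cluster_model <- stage("cluster", {
      Z <- zscore(transform_counts(ct))
      kmeans_fit(Z, config$k, seed = config$sim$seed)
    })
    write_tsv_with_header(
      data.frame(gene = names(cluster_model$assignments),
                 cluster = cluster_model$assignments),
      file.path(config$out_dir, "clusters.tsv"), hdr)
  }
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(list(truth = truth, counts = ct, annotation = annot,
                 calls = calls, summary = summary_tab, enrichment = enrich,
                 cluster = cluster_model))
}
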