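#' Per-category error rates of the cis/trans classifier under simulation
#'
#' Validates the classification pipeline on synthetic data with known
#' regulatory ground truth. Two reference modes are available:
#'
#' * `reference = "true_counts"` — the expected call for each gene is the one
#'   the identical statistical pipeline makes on the *true* allele counts;
#'   the observed call comes from counts passed through competitive
#'   read-assignment simulation (ambiguity + proportional redistribution) at
#'   `p_ambiguous`. The error rates then isolate misclassification induced by
#'   allele assignment, the quantity the read-assignment method is judged on.
#' * `reference = "truth"` — calls are compared against the generative
#'   category itself, so the rates additionally absorb the statistical power
#'   of the contrasts at the simulated depth and replication.
#'
#' Type-1 (false positive) rate for category k is the fraction of genes not
#' expected in k that are called k; type-2 (false negative) is the fraction
#' of genes expected in k that are not called k. Rates are percentages.
#'
#' @param config A [sim_config()]; its seed drives all randomness.
#' @param p_ambiguous Per-read ambiguity probability for the competitive
#'   assignment step (default 0.05).
#' @param reference `"true_counts"` (default) or `"truth"`.
#' @param sex Sex context to classify.
#' @param alpha FDR level.
#' @return List: `rates` (`data.frame` of `category`, `type1`, `type2`,
#'   `n_expected`), `max_rate` (worst rate over categories, in %),
#'   `n_genes` (genes classified), `confusion` (expected x observed table).
#' @export
classifier_error_rates <- function(config, p_ambiguous = 0.05,
                                   reference = c("true_counts", "truth"),
                                   sex = "female", alpha = 0.05) {
  reference <- match.arg(reference)
  truth <- generate_truth(config)
  ct_true <- simulate_counts(truth, config)
  ct_obs <- ct_true
  d <- ct_obs$design
  for (sx in unique(d$sex)) {
    pa <- which(d$genotype == "F1" & d$channel == "allele_CBR" & d$sex == sx)
    for (i in pa) {
      j <- which(d$genotype == "F1" & d$channel == "allele_CNI" &
                 d$sex == sx & d$replicate == d$replicate[i])
      cm <- compmap_from_true_counts(ct_true$counts[, i], ct_true$counts[, j],
                                     p_ambiguous,
                                     seed = config$seed + 100L + i)
      ct_obs$counts[, i] <- cm$c_a
      ct_obs$counts[, j] <- cm$c_b
    }
  }
  obs <- classify_regulation(ct_obs, sex = sex, alpha = alpha)$cis_trans
  expected <- if (reference == "true_counts") {
    exp_calls <- classify_regulation(ct_true, sex = sex, alpha = alpha)$cis_trans
    common <- intersect(exp_calls$gene, obs$gene)
    stats::setNames(exp_calls$category[match(common, exp_calls$gene)], common)
  } else {
    common <- obs$gene
    ecat <- truth$category[match(common, truth$gene_id)]
    # generator category names map onto call names except the x-compensatory label
    ecat[ecat == "cis_x_trans"] <- "cis_x_trans_compensatory"
    stats::setNames(ecat, common)
  }
  common <- names(expected)
  ocat <- obs$category[match(common, obs$gene)]
  cats <- setdiff(unique(c(expected, ocat)), "ambiguous")
  cats <- intersect(CIS_TRANS_CATEGORIES, cats)
  rates <- do.call(rbind, lapply(cats, function(k) {
    in_exp <- expected == k
    in_obs <- ocat == k
    data.frame(category = k,
               type1 = 100 * if (sum(!in_exp) > 0)
                 sum(in_obs & !in_exp) / sum(!in_exp) else 0,
               type2 = 100 * if (sum(in_exp) > 0)
                 sum(!in_obs & in_exp) / sum(in_exp) else 0,
               n_expected = sum(in_exp), stringsAsFactors = FALSE)
  }))
  list(rates = rates, max_rate = max(c(rates$type1, rates$type2)),
       n_genes = length(common),
       confusion = table(expected = expected, observed = ocat))
}

#' Mean estimation error of the cis and trans estimators per category
#'
#' Runs the joint parental/allelic model on a fresh simulation and reports,
#' per regulatory category, the mean of the estimated allelic ratio `A` minus
#' the true cis effect `c` and of the estimated trans effect `T` minus the
#' true `t`.
#'
#' @param config A [sim_config()] (high depth / low dispersion recommended
#'   for estimator-consistency checks).
#' @param sex Sex context.
#' @return `data.frame`: `category`, `bias_A`, `bias_T`, `n`.
#' @export
estimator_recovery <- function(config, sex = "female") {
  truth <- generate_truth(config)
  ct <- simulate_counts(truth, config)
  cl <- classify_regulation(ct, sex = sex)
  m <- match(cl$cis_trans$gene, truth$gene_id)
  df <- data.frame(category = truth$category[m],
                   errA = cl$cis_trans$A - truth$c[m],
                   errT = cl$cis_trans$T - truth$t[m])
  out <- do.call(rbind, lapply(split(df, df$category), function(s)
    data.frame(category = s$category[1], bias_A = mean(s$errA),
               bias_T = mean(s$errT), n = nrow(s))))
  rownames(out) <- NULL
  out
}
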