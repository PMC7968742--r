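#' Call sex-biased expression from a male-vs-female contrast
#'
#' @param male_vs_female A `contrast_result` with `log2FC` oriented
#'   male/female.
#' @return Character vector per gene: `"male"`, `"female"` or `"neutral"`.
#' @export
call_sex_bias <- function(male_vs_female) {
  r <- male_vs_female
  ifelse(r$significant & r$direction > 0, "male",
         ifelse(r$significant & r$direction < 0, "female", "neutral"))
}

#' Species-by-sex expression group labels
#'
#' Combines three contrasts for the same genes into a three-letter label:
#' first letter `N`/`B` for significantly higher expression in C. nigoni /
#' C. briggsae else `C` (conserved between species); second letter `M`/`F`
#' for significant male/female bias else `N`; third letter `I` if the
#' species-by-sex interaction is significant else `N`. E.g. `"B-M-I"`.
#'
#' @param species,sex,interaction `contrast_result`s aligned by gene;
#'   `species` oriented CNI/CBR, `sex` oriented male/female.
#' @return Character vector of hyphenated labels.
#' @export
call_species_sex_group <- function(species, sex, interaction) {
  stopifnot(nrow(species) == nrow(sex), nrow(sex) == nrow(interaction))
  l1 <- ifelse(species$significant & species$direction > 0, "N",
               ifelse(species$significant & species$direction < 0, "B", "C"))
  l2 <- ifelse(sex$significant & sex$direction > 0, "M",
               ifelse(sex$significant & sex$direction < 0, "F", "N"))
  l3 <- ifelse(interaction$significant, "I", "N")
  paste(l1, l2, l3, sep = "-")
}

INHERITANCE_CATEGORIES <- c("no_change", "additive", "dominant_CBR",
                            "dominant_CNI", "overdominant", "underdominant",
                            "ambiguous")

#' Classify mode of expression inheritance in F1 hybrids
#'
#' Rules over three contrasts (F1 vs each parent, parent vs parent):
#' * `no_change` — F1 differs from neither parent;
#' * `additive` — all three contrasts significant with the F1 point estimate
#'   strictly between the parents (one F1-vs-parent fold change positive, the
#'   other negative);
#' * `dominant_CBR` / `dominant_CNI` — F1 matches one parent (non-significant)
#'   while differing from the other, with the parents differing;
#' * `overdominant` / `underdominant` — F1 significantly above / below both
#'   parents (transgressive misexpression);
#' * `ambiguous` — any remaining pattern.
#'
#' @param f1_vs_cbr,f1_vs_cni `contrast_result`s with `log2FC` oriented
#'   F1/parent.
#' @param cni_vs_cbr `contrast_result` between the parents.
#' @return `data.frame` with `gene`, `category` and the Euclidean
#'   misexpression distance `d` (see [expression_distance()]).
#' @export
call_inheritance <- function(f1_vs_cbr, f1_vs_cni, cni_vs_cbr) {
  stopifnot(nrow(f1_vs_cbr) == nrow(f1_vs_cni),
            nrow(f1_vs_cni) == nrow(cni_vs_cbr))
  s1 <- f1_vs_cbr$significant; d1 <- f1_vs_cbr$log2FC
  s2 <- f1_vs_cni$significant; d2 <- f1_vs_cni$log2FC
  sp <- cni_vs_cbr$significant
  cat <- rep("ambiguous", length(s1))
  cat[!s1 & !s2] <- "no_change"
  over <- s1 & s2 & d1 > 0 & d2 > 0
  under <- s1 & s2 & d1 < 0 & d2 < 0
  cat[over] <- "overdominant"
  cat[under] <- "underdominant"
  between <- s1 & s2 & sp & ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0))
  cat[between] <- "additive"
  cat[!s1 & s2 & sp] <- "dominant_CBR"
  cat[s1 & !s2 & sp] <- "dominant_CNI"
  data.frame(gene = f1_vs_cbr$gene, category = cat,
             d = expression_distance(d1, d2), stringsAsFactors = FALSE)
}

#' Euclidean misexpression distance
#'
#' Treats the two F1-vs-parent log2 fold changes as a point in expression
#' space and returns its distance from the origin (0, 0), the point of fully
#' conserved hybrid expression: `d = sqrt(delta_cbr^2 + delta_cni^2)`.
#'
#' @param delta_cbr,delta_cni Log2 fold changes of F1 vs each parent.
#' @return Non-negative numeric vector.
#' @export
expression_distance <- function(delta_cbr, delta_cni) {
  stopifnot(all(is.finite(delta_cbr) | is.na(delta_cbr)),
            all(is.finite(delta_cni) | is.na(delta_cni)))
  sqrt(delta_cbr^2 + delta_cni^2)
}

CIS_TRANS_CATEGORIES <- c("conserved", "cis_only", "trans_only",
                          "cis_plus_trans", "cis_x_trans_compensatory",
                          "compensatory", "ambiguous")

#' Classify cis/trans regulatory divergence
#'
#' Applies the standard significance-pattern rules to the three regulatory
#' contrasts per gene — parental divergence `P`, allele-specific expression
#' `A` (the cis estimator) and the trans effect `T = P - A`:
#' * `conserved` — none significant;
#' * `cis_only` — A and P significant, T not;
#' * `trans_only` — T and P significant, A not;
#' * `cis_plus_trans` — A and T significant in the same direction;
#' * `cis_x_trans_compensatory` — A and T significant in opposite directions
#'   with P still significant;
#' * `compensatory` — A and T significant in opposite directions with P
#'   non-significant (divergence invisible between species, exposed in the
#'   hybrid);
#' * `ambiguous` — any remaining pattern (e.g. significant ASE without
#'   significant divergence).
#'
#' @param P,A,T_ `contrast_result`s aligned by gene (`T_` named to avoid the
#'   base `T`).
#' @return `data.frame` with `gene`, `P`, `A`, `T` (log2 estimates) and
#'   `category`.
#' @export
call_cis_trans <- function(P, A, T_) {
  stopifnot(nrow(P) == nrow(A), nrow(A) == nrow(T_))
  sP <- P$significant; sA <- A$significant; sT <- T_$significant
  dirA <- A$direction; dirT <- T_$direction
  cat <- rep("ambiguous", length(sP))
  cat[!sP & !sA & !sT] <- "conserved"
  cat[sA & !sT & sP] <- "cis_only"
  cat[!sA & sT & sP] <- "trans_only"
  both <- sA & sT
  cat[both & dirA == dirT] <- "cis_plus_trans"
  cat[both & dirA != dirT & sP] <- "cis_x_trans_compensatory"
  cat[both & dirA != dirT & !sP] <- "compensatory"
  data.frame(gene = P$gene, P = P$log2FC, A = A$log2FC, T = T_$log2FC,
             category = cat, stringsAsFactors = FALSE)
}

X_MALE_CATEGORIES <- c("cis_only_star", "trans_only_star",
                       "compensatory_cis_trans", "conserved", "other",
                       "not_applicable")

#' Regulatory divergence scheme for hemizygous-X genes in males
#'
#' X0 males carry a single, maternally inherited X (here the C. nigoni X), so
#' allelic contrasts are impossible for X-linked genes in males. Divergence
#' type is instead inferred from parental divergence plus the F1 dominance
#' pattern, assuming the bulk of the trans environment is autosomal:
#' * P significant with C. nigoni-dominant F1 expression → `cis_only_star`
#'   (expression follows the X allele present);
#' * P significant with C. briggsae-dominant expression → `trans_only_star`
#'   (deviation from the carried allele implies trans regulation, assuming
#'   recessive C. nigoni trans regulators);
#' * P non-significant but F1 over-/under-expressed → `compensatory_cis_trans`;
#' * P non-significant with unchanged F1 expression → `conserved`;
#' * any other significant-divergence pattern → `other`.
#'
#' @param P `contrast_result` of parental divergence for X-linked genes.
#' @param inheritance Output of [call_inheritance()] for the same genes
#'   (male context).
#' @param x_linked Logical vector; must be all `TRUE` (autosomal genes are an
#'   error — they have a proper allelic contrast).
#' @return Character vector of categories.
#' @export
call_x_male <- function(P, inheritance, x_linked = rep(TRUE, nrow(P))) {
  stopifnot(nrow(P) == nrow(inheritance))
  if (!all(x_linked)) stop("call_x_male applies only to X-linked genes")
  inh <- inheritance$category
  sP <- P$significant
  out <- rep("other", length(sP))
  out[!sP & inh == "no_change"] <- "conserved"
  out[!sP & inh %in% c("overdominant", "underdominant")] <- "compensatory_cis_trans"
  out[sP & inh == "dominant_CNI"] <- "cis_only_star"
  out[sP & inh == "dominant_CBR"] <- "trans_only_star"
  # no significant divergence anywhere and F1 unchanged -> conserved already;
  # non-significant P with dominance/additive patterns remain "other"
  out
}

#' Flag masculinized genes in a sperm-producing hermaphrodite
#'
#' Hermaphrodites produce some sperm, so genuinely male-biased genes can be
#' upregulated in them relative to a sperm-less female reference. Flags
#' genes that are male-biased in both datasets AND significantly higher in
#' hermaphrodites than in the reference, so they can be excluded from
#' female-context comparisons and analyzed separately.
#'
#' @param bias_main Character vector of sex-bias calls (from
#'   [call_sex_bias()]) in the main dataset, named by gene.
#' @param bias_reference Same for the sperm-less reference dataset.
#' @param cross_dataset `contrast_result` of hermaphrodite vs reference
#'   expression (positive log2FC = higher in hermaphrodite).
#' @return Character vector of flagged gene ids.
#' @export
reconcile_hermaphrodite <- function(bias_main, bias_reference, cross_dataset) {
  if (nrow(cross_dataset) == 0L) return(character(0))
  genes <- cross_dataset$gene
  mb_main <- genes %in% names(bias_main)[bias_main == "male"]
  mb_ref <- genes %in% names(bias_reference)[bias_reference == "male"]
  up <- cross_dataset$significant & cross_dataset$direction > 0
  genes[mb_main & mb_ref & up]
}
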