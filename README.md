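# hybridex

Dissecting *cis*- and *trans*-regulatory divergence between two nematode
species (*Caenorhabditis briggsae* and *C. nigoni*) from the transcriptomes
of their F1 hybrids — as a tested, reusable R analysis pipeline that runs
end to end on synthetic data with known regulatory ground truth.

## The problem and who this is for

When two species diverge, gene-expression differences accumulate through
*cis*-regulatory changes (promoter/enhancer variants acting on the linked
allele) and *trans* changes (diffusible regulators acting on both alleles).
F1 hybrids separate the two: within one hybrid nucleus both parental alleles
share a single trans environment, so allele-specific expression (ASE)
isolates *cis* effects. With

- `P` = log2 expression ratio between the parent species (C. nigoni / C. briggsae),
- `A` = log2 allelic ratio within F1 hybrids (the ASE, the *cis* estimator),
- `T = P − A` (the *trans* estimator),

the significance pattern of (P, A, T) classifies each gene as conserved,
*cis*-only, *trans*-only, *cis* + *trans* (reinforcing), *cis* × *trans*
(compensatory, parents still diverged), compensatory (effects cancel —
parents identical, hybrids misexpress), or ambiguous. Around this core the
package implements the full analysis a hybrid-transcriptome study needs:

- **Competitive allele assignment** (`count_features`): each F1 read aligned
  to both parental references is assigned by alignment score (AS tag), then
  mismatch count (nM), with ambiguous reads redistributed per feature in
  proportion to assigned reads.
- **NB Wald contrasts** (`fit_contrast`, `regulatory_contrasts`,
  `species_sex_fit`): per-gene negative-binomial GLMs with median-of-ratios
  size factors, pooled trended dispersion, Wald tests, Benjamini–Hochberg
  FDR at 5%.
- **Classification** (`call_cis_trans`, `call_inheritance`, `call_x_male`,
  `call_sex_bias`, `call_species_sex_group`): regulatory categories;
  expression inheritance (additive / dominant / over- and underdominant)
  with the Euclidean misexpression distance `d = sqrt(Δ²_F1/Cbr + Δ²_F1/Cni)`;
  and a dedicated scheme for X-linked genes in X0 males, where hemizygosity
  makes allelic contrasts impossible.
- **Genomic context** (`fisher_enrichment`, `assign_domains`): Fisher exact
  enrichment by chromosome, arm/center domain or gene set with the dual rule
  (p < 0.05 **and** |log2 OR| > 0.5).
- **Molecular evolution** (`kaks`, `enc`, `ks_correct`,
  `upstream_conservation`): Ka/Ks by codon-table counting with Jukes–Cantor
  correction, Wright's effective number of codons, the ENC-anchored Ks′
  correction (`Ks′ = Ks + b·(60 − ENC)` from the OLS fit `Ks ~ ENC`), and
  upstream conservation as the fraction of identical 5-bp windows in 500-bp
  flanks.
- **Co-expression modules** (`kmeans_fit`, `elbow_curve`): Z-scored
  log-expression profiles clustered by K-means (k-means++ seeding, best of
  25 restarts).
- **Synthetic data with ground truth** (`sim_config`, `generate_truth`,
  `simulate_counts`, `simulate_read_alignments`, `simulate_ortholog_pair`,
  `simulate_upstream_alignments`): every input type the pipeline consumes,
  generated with known cis/trans effects, read origins, substitution ledgers
  and window mismatch rates.

## Worked example

```r
library(hybridex)

cfg   <- sim_config(n_genes = 2000, seed = 20260927)  # six categories, 3 reps
truth <- generate_truth(cfg)
ct    <- simulate_counts(truth, cfg)

calls <- classify_regulation(ct, sex = "female")
table(calls$cis_trans$category)
```

```
               ambiguous                 cis_only           cis_plus_trans
                     263                      401                      196
cis_x_trans_compensatory             compensatory                conserved
                      56                      357                      457
              trans_only
                     270
```

The 2,000 simulated genes (331 cis-only, 343 cis+trans, 346 cis×trans,
302 compensatory, 343 conserved, 335 trans-only in truth) are recovered with
the expected structure: genes whose opposing cis and trans effects nearly
cancel between species are statistically indistinguishable from purely
compensatory genes, which is why the `cis_x_trans_compensatory` call is
rarer than its generative truth and `compensatory` correspondingly richer.
At high depth the estimators are unbiased — `estimator_recovery()` at mean
depth 10⁴ and dispersion 0.01 shows per-category mean bias of A and T below
0.04 log2 units — and on all-conserved simulations the raw-p rejection
rates of the P/A/T families are 0.053 / 0.051 / 0.049 at nominal 0.05.

The numbered scripts under `analysis/` run the whole study on synthetic
data — simulation, read-level allele assignment (assigned-vs-true count
correlation 0.998 at 10% ambiguous reads), differential expression,
classification, enrichment, molecular evolution, co-expression and
validation — writing their tables under `results/`.

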