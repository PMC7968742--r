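---
title: "Models and methods behind hybridex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hybridex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridex)
```

# The estimation framework

Expression divergence between two species is the sum of *cis* effects
(linked regulatory sequence, allele-autonomous) and *trans* effects
(diffusible regulators acting on both alleles). In an F1 hybrid both
parental alleles share one trans environment, so the allelic log2 ratio
estimates the cis component alone. hybridex works with three per-gene
quantities:

- `P` — parental log2 ratio (C. nigoni / C. briggsae), estimating `c + t`;
- `A` — allelic log2 ratio within F1 hybrids, estimating `c`;
- `T = P − A`, estimating `t`.

All three are contrasts of one negative-binomial cell-means model per gene
over four groups: the two parental totals and the two F1 allele channels.
Because they share one fit, `T = P − A` holds exactly at the estimate level,
and a single per-gene dispersion is shared across the four groups (the
allele channels of one library are modelled as independent observations;
the pairing is recorded in the design sheet but not modelled).

## The NB Wald engine

Each gene is fitted by iteratively reweighted least squares for the NB GLM
with log link, log size factors as offsets, and fixed dispersion
(`variance = m + phi * m^2`). Wald statistics of contrast combinations are
referred to the standard normal, and each contrast family is
Benjamini–Hochberg adjusted across genes with significance at
`padj < 0.05`. Fractional counts produced by ambiguous-read redistribution
are accepted directly: the NB score equations are evaluated at continuous
`y`, which is the natural continuous extension of the likelihood.

Size factors are median-of-ratios: per sample, the median over
all-positive genes of the count over the gene's geometric mean, normalized
to geometric mean one. Genes are kept when more than 10 scaled counts occur
in at least 3 samples (strict inequality on 10).

**Dispersion.** With three replicates, per-gene method-of-moments
dispersions are extremely noisy and produce badly calibrated Wald tests.
The default estimator therefore pools moments within bins of mean
abundance, `phi_bin = sum(s² − m) / sum(m²)`, and interpolates the binned
values back to genes ("trended"). This averages the sampling noise of
small-replicate variance estimates while retaining any mean–dispersion
trend; `"common"` and raw `"gene"` estimators are available. On
all-conserved simulations the raw-p rejection rate of each contrast family
sits within three standard errors of the nominal 0.05
(`analysis/08_validation.R` prints 0.053/0.051/0.049 for P/A/T at
n = 4000), which is what the classifier's conserved category relies on.

## Classification rules

`call_cis_trans` maps the (P, A, T) significance pattern to categories:
conserved (none), cis-only (A and P, not T), trans-only (T and P, not A),
cis + trans (A and T, same direction), cis × trans compensatory (A and T,
opposite directions, P still significant), compensatory (A and T opposite,
P not), ambiguous otherwise. Three readings were genuinely open and were
fixed as follows:

- cis-only requires significant `P`: a gene with significant ASE but no
  significant divergence anywhere else is *ambiguous*, not cis-only.
- `call_inheritance`'s "no change" is defined purely by the two
  F1-vs-parent contrasts, even when the parents differ from each other —
  such genes match the written rule and are not demoted to ambiguous.
- "Additive" requires all three contrasts significant *and* the F1 point
  estimate strictly between the parental estimates (one F1-vs-parent fold
  change positive, the other negative); boundary equality falls to
  ambiguous. Whether intermediacy should be a statistical test rather than
  a point-estimate condition is unknowable from the rule as stated; the
  point estimate is used.

For X-linked genes in X0 males the allelic contrast does not exist (one
maternally inherited X). `call_x_male` instead combines parental divergence
with the F1 dominance pattern, assuming a mostly autosomal trans
environment: C. nigoni-dominant expression of a diverged gene implies
cis-type divergence (the expression follows the one X allele present),
C. briggsae-dominant expression implies trans-type regulation (with the
caveat that this sees only the recessive-regulator subset), unchanged
parents with transgressive hybrids imply compensatory cis–trans change, and
everything else with significant divergence is lumped into "other".
Dominance direction is taken from the F1-vs-parent point estimates.

# The synthetic experiment

The generator is the package's study design, not a test dial. Defaults:
2,000 genes in six regulatory categories with equal weights; absolute cis
and trans effects uniform on [0.5, 2] log2 units with random signs subject
to the category constraints (compensatory means `t = −c` exactly);
baseline depth log-uniform on 100–1000 mean counts; NB dispersion 0.05;
three replicate libraries per condition; log-normal library-size
multipliers (sd 0.1) so normalization is actually exercised. Counts follow
the additive mean model: parental C. briggsae at `mu`, parental C. nigoni
at `mu + c + t`, F1 allele channels at `mu + h·t` and `mu + c + h·t`. The
trans-dominance weight `h` defaults to 0.5 (additive trans background); the
mean-model identities `E[P] = c + t`, `E[A] = c`, `E[T] = t` hold for any
`h`, which the tests verify by Monte Carlo at low dispersion. Two-sex
designs add a per-gene sex effect (and optionally a species-by-sex
interaction on parental C. nigoni males); by default 60% of genes are
sex-biased in two-sex runs, matching the scale of sex-biased expression
such experiments observe.

Read-level simulation emits alignment-score pairs, not nucleotides:
non-ambiguous reads score strictly better against their true reference
(or tie on score with fewer mismatches), ambiguous reads tie on both. The
default ambiguity rate of 5% reflects high interspecific divergence — at
roughly 20% synonymous-site divergence and 25% synonymous sites, a 100-bp
coding read carries about five diagnostic differences
(`expected_coding_differences(0.2, 0.25, 100)`), so fully ambiguous reads
are the exception. What the generator does **not** emulate: sequencing
error profiles, mapping bias between references, isoform structure,
correlated dispersion across genes, or the shared-library pairing of the
two allele channels. Passing tests therefore demonstrate correctness of
the algorithms under a clean generative model, not robustness to
alignment artefacts on real libraries.

At scale, competitive assignment is simulated at the count level
(binomial ambiguity split plus proportional redistribution), which has the
same outcome distribution as materializing every read; the equivalence of
the two paths is itself under test.

## Validation design

The classifier's headline validation asks: how much misclassification does
competitive read assignment introduce? Expected calls come from the
identical statistical pipeline on the *true* allele counts; observed calls
from counts passed through assignment simulation. Per-category type-1 and
type-2 rates are then disagreement rates attributable to assignment alone,
and stay under 5% at the default conditions (`classifier_error_rates`,
also recomputed by `scripts/acceptance.R`). Rates against the generative
truth are reported separately (`analysis/08_validation.R`): they absorb
statistical power and are necessarily large near the 0.5-log2 lower edge
of the effect distribution at three replicates — a gene with
`|c| = 0.5` at median depth carries a Wald z of roughly 2 per contrast, so
conjunction rules miss it often. A further subtlety is intrinsic to the
taxonomy: a cis × trans gene whose opposing effects nearly cancel has
`P ≈ 0` and is statistically a compensatory gene; no classifier can
separate the two near that boundary.

# Molecular-evolution choices

`kaks` uses deterministic codon-table counting: synonymous site fractions
per codon from its degeneracy (averaged over both sequences), substitutions
along minimal mutational paths averaged over orderings (paths through stop
codons excluded when avoidable; changes creating stops count as
nonsynonymous), and Jukes–Cantor correction `d = −3/4·log(1 − 4p/3)` with
saturation flagged at `p ≥ 3/4`. This estimator was chosen because every
quantity is desk-verifiable against the simulator's substitution ledger by
hand-countable oracles; it sits behind a plain interface so a
likelihood-based codon model can be swapped in. Consequently all validation
uses ledgered simulations, never literature genome-wide values.

`enc` implements Wright's statistic with the small-sample homozygosity
`F = (nΣp² − 1)/(n − 1)` (a singleton family falls back to `Σp² = 1`),
family classes 2/9/1/5/3 under the standard code, missing families imputed
by the mean of their degeneracy class (the lone three-fold family, if
missing, by the mean of the two- and four-fold class means), and the result
clamped to [20, 61]. The `ks_correct` anchor is ENC = 60 — kept as
conventionally printed even though Wright's maximum is 61; the correction
`Ks′ = Ks + b(60 − ENC)` only shifts all values by a constant under a
different anchor, so downstream correlations are unaffected. Constant ENC
input leaves Ks untouched (the slope is taken as zero).

Upstream conservation partitions the first 500 alignment columns into 100
five-column windows; a window with any gap column counts as non-identical
(gap treatment in such scores is rarely stated; the conservative reading
was chosen and is configurable by pre-filtering the alignment).

# Numerical and algorithmic details

- IRLS starts from the least-squares fit to log counts, converges at
  1e-10 on coefficients, caps at 50 iterations; rank-deficient designs and
  non-estimable contrasts error out; all-zero genes get `p = 1` and are
  flagged rather than dropped.
- Redistribution with no assigned reads on either side splits ambiguous
  reads equally (logged per feature).
- Fisher enrichment: two-sided p by summing hypergeometric probabilities
  no larger than the observed table's; the Haldane–Anscombe +0.5 applies to
  the odds ratio only, and only when a cell is zero. Enrichment p-values
  are deliberately not multiplicity-corrected — the dual rule
  (p < 0.05 and |log2 OR| > 0.5) is the filter, matching common practice
  for descriptive chromosome-level scans.
- K-means uses k-means++ seeding with Lloyd iterations, best of 25
  restarts, deterministic given the seed; the elbow curve is emitted for
  every run so the default `k = 15` can be re-chosen per dataset.
- BED intervals are 0-based half-open throughout; flank extraction is
  strand-aware and truncates (with a flag) at chromosome edges; domain
  assignment uses gene midpoints with left-closed boundary intervals.
- Problem sizes in tests and the acceptance script (2,000-gene
  classification runs, 4,000-gene calibration, 1,200-gene recovery at
  depth 10⁴) were chosen so each check carries enough Monte-Carlo precision
  for its tolerance while a full suite run stays in the minutes range on a
  single core.

# Known limitations

- The dispersion estimator is a pooled-moments trend, not an empirical
  Bayes shrinkage; per-gene dispersion variation within an abundance bin is
  flattened. The engine interface accepts numeric dispersions, so an
  external estimator can be substituted.
- Reads mapped to only one reference are assigned to that side — the
  behaviour most read-assignment workflows leave unstated; at high
  divergence this slightly favours the better-assembled reference.
- A read overlapping several features counts once per feature (union
  counting), so overlapping annotations double-count; collapse the BED
  beforehand if that matters.
- The hemizygous-X scheme can misattribute genes whose trans regulators are
  X-linked or C. nigoni-dominant; its trans-only* category is an
  acknowledged underestimate of trans regulation.
- `transform_counts` uses `log2(scaled + 1)`, not a variance-stabilizing
  shrinkage transform; at very low counts cluster profiles are noisier
  than they would be under a regularized transform. The transform is a
  plain function argument away from being replaced.
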