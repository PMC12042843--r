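---
title: "Methods: TRA calling, tonic interferon scoring and transcriptomic diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TRA calling, tonic interferon scoring and transcriptomic diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airetonic)
options(airetonic.log_level = "quiet")
```

# Scope and model

`airetonic` implements the statistical layer used to study how the
transcriptional regulator Aire shapes thymic self-antigen expression and
tonic type 1 interferon (T1 IFN) signaling, and how the loss of that
signaling propagates to peripheral immune cells.  The package covers seven
connected analyses: tissue-restricted antigen (TRA) calling on ranked
tissue-group expression, bulk and pseudobulk differential expression (DE)
with the definition of Aire-dependent genes, Fisher odds-ratio enrichment
of interferon-stimulated gene (ISG) sets, pre-ranked GSEA with gene-set
downsampling, a per-cell-type "IFN score" for tonic-sensitive ISGs,
Hill-number transcriptomic diversity, and a cross-species gene-module
comparison.  All stages run on synthetic data with planted ground truth,
so every downstream claim the package makes can be scored against a known
answer.

# The dynamic-step TRA caller

A gene is tissue-restricted when it is expressed in only a few tissue
groups.  Tissue samples are first reduced to `n_groups` (default 11)
groups by average-linkage hierarchical clustering on correlation distance
(1 − Pearson over genes), so that over-sampled similar tissues do not
dominate; group expression is the arithmetic mean of member samples on
linear scale.  For each gene the group values are ranked descending and,
for j = 1..`j_max`, the rule asks whether the j-th highest group value
exceeds a threshold `T` evaluated at the expression level `E` of the
(j+1)-th group.  The smallest such j is `j_star`; the gene is a TRA when
`j_star >= 1`.

The threshold's printed rendering is typographically ambiguous, so both
algebraic parses ship behind the `form` flag:

* `gap` (default): `T = E + E/250 + 50` — a genuinely expression-dependent
  step: a gene must exceed the next group by a margin that grows with
  that group's expression.  We default to this form because a nearly
  constant threshold would contradict the "dynamic step" character of the
  method.
* `saturating`: `T = E/(250 + E) + 50` — effectively constant (50–51).

Both forms satisfy `T >= 50` and are monotone in `E`; neither is asserted
to be the historical original.  `j_max` defaults to 5, covering the 1–3
expressing groups typical of TRA definitions with headroom; whether the
rule requires all top-j groups or just the j-th to clear the threshold is
moot because the groups are sorted descending, which makes the two
readings equivalent.

```{r tra-example}
panel <- make_tissue_panel(n_genes = 500, n_tra = 20, seed = 1)
groups <- reduce_to_groups(panel$expr, n_groups = 11)
calls <- call_tra(groups, j_max = 5, form = "gap")
table(called = calls$is_tra,
      planted = calls$gene %in% panel$truth$planted_tra$gene)
```

# Differential expression and Aire-dependent genes

Bulk comparisons use a per-gene Welch two-sample t test on log2-scale
values with Benjamini–Hochberg adjustment; the original analyses ran in a
closed array-analysis console whose test is unstated, so Welch + BH is
the package's own, explicitly documented choice, and the validation
surface is parameter recovery on synthetic data rather than replication
of any particular gene list.  Aire-dependent genes are defined as the
genes downregulated in the Aire knockout: signed LFC < −1 at FDR < 0.05
(strict inequalities).  Published figure legends mix a magnitude
convention ("LFC > 1" for downregulated genes) with a signed one ("LFC
less than −1"); the package standardizes on the signed convention
everywhere.

Single-cell contrasts first sum counts to (animal, cell type) pseudobulk
strata — summation is exact and conservation-tested — with strata under
`min_cells` (default 10) dropped, then normalize as
`log2(1 + 1e4 × count/stratum total)` before the same Welch test.  Holm's
step-down adjustment is used whenever a small family of populations is
tested together.

# Enrichment: Fisher tables, downsampled GSEA, module scores

Enrichment of a gene set among downregulated genes is a 2×2 table over
the population's *tested* universe (an explicit choice; the alternative —
a common detected-genes universe — is not used, and results carry the
universe size so the choice is auditable).  The reported odds ratio is the
sample cross-product `ad/bc` (the convention of the figure software the
analyses mirrored), with a Haldane–Anscombe +0.5 correction and a flag
when any cell is zero; the p value is the one-sided hypergeometric tail,
because every use in this pipeline is an enrichment claim.

Pre-ranked GSEA uses the classic weighted running sum (weight 1): set
members add `|s|^p` (normalized), non-members subtract `1/(N − |set|)`;
the enrichment score (ES) is the signed maximum deviation.  The null
permutes gene labels (the input is a pre-ranked list, so phenotype
permutation is unavailable), NES divides ES by the mean |null ES| of
matching sign, and the permutation p carries the standard +1 correction.
When several sets of different sizes are compared, `downsample_sets()`
first reduces all sets to the smallest size by seeded sampling without
replacement, so NES differences are not driven by set size.

Per-cell module scores follow the standard single-cell convention: genes
are placed in 24 equal-frequency bins by mean expression, each set gene
draws 100 control genes from its own bin, and the score is the mean
set-gene expression minus the mean control expression per cell.

# Tonic-sensitivity and the IFN score

ISGs are split into tonic-sensitive and tonic-insensitive classes using a
baseline (unstimulated) interferon-receptor-knockout reference contrast:
tonic-sensitive means LFC < −1 at FDR < 0.05 in that reference.  The
package generates a synthetic reference with planted labels
(`make_tonic_reference()`); no external dataset is bundled.  A reference
covering less than half the ISG universe is rejected as unreliable, and
ISGs absent from the reference are flagged unclassified and excluded.

The IFN score for a cell type standardizes each tonic-sensitive gene in a
knockout sample against the control-group mean and SD (n−1 denominator)
and sums the z values:

score(sample) = Σ_g (x_g − mean_ctrl,g) / sd_ctrl,g.

Zero scores mean knockout expression sits at control means; −1 is exactly
one control SD below for a single gene; the score is linear, so ten genes
at −2 SD give −20.  Genes with zero control SD are dropped (an epsilon
floor would let a constant gene dominate the sum).  Expression entering
the score is the per-animal, per-cell-type mean of log-normalized
single-cell values: the underlying description does not fix cell- versus
animal-level aggregation, and animal-level aggregation avoids
pseudoreplication across cells of one animal.  Under the null the score
has mean 0 and variance close to the number of genes (slightly above,
because the control mean and SD are estimated).

# Transcriptomic diversity

Diversity of a cell population is the Hill number of order q = 0 — gene
richness — as a function of the number of UMIs considered.  Below the
observed depth N, the expected richness of an m-UMI subsample has the
closed hypergeometric form `E[S_m] = Σ_g (1 − C(N − n_g, m)/C(N, m))`,
evaluated in log space; it equals S_obs exactly at m = N.  Beyond N the
curve is anchored to the Chao1 asymptote
(`S_obs + f1²/(2 f2)`, or the bias-corrected form when f2 = 0) through the
standard exponential approach; with no singletons the extrapolation is
flat at S_obs and flagged.  The API carries `q` for future orders but
rejects q ≠ 0.

Standard errors come from a multinomial bootstrap over an estimated
complete abundance distribution: observed relative abundances are shrunk
by the coverage estimate `Chat = 1 − f1/N` and the remaining mass is
split equally across the estimated number of unseen genes.  Populations
are compared at a common depth m* (default 2× the smallest population's
N, the usual extrapolation guidance) with a Wald-type Z test whose SEs
are recovered from the 95% CI half-widths — deliberately mirroring the
CI-derived-SE chain — and Holm adjustment across populations.  One
boundary subtlety is documented rather than hidden: at exactly m = N of a
smaller sample its curve equals S_obs while a supersample is still
subsampled there, so curve dominance after adding cells holds on the
interior of the grid, not at that boundary point.

# Cross-species modules

Rat and mouse KO-vs-control DE tables are combined over a strictly
one-to-one ortholog map into a gene × dataset LFC matrix; a gene is kept
when present in the rat table and at least one mouse dataset, and missing
entries stay NA (absent, never zero) except inside K-means, where columns
are z-scaled and NAs imputed as 0 for clustering only.  K-means (k = 4,
fixed by the study design rather than selected by criterion; best of 50
seeded starts) assigns modules, renumbered by descending size, and each
module is tested for TRA/ISG enrichment through the same Fisher machinery.
Dataset-level structure is inspected by PCA on z-scaled genes with a fixed
sign convention, and population relationships by average-linkage
clustering on correlation distance with plain bootstrap proportions as
node support (multiscale approximately-unbiased bootstrap is out of
scope; the supports are labeled BP).  Relative ISG expression between two
datasets is compared by Spearman correlation, exact by full permutation
enumeration for n ≤ 9 and by the t approximation above that.

# The synthetic cohort

The generators (`make_tissue_panel`, `make_mtec_bulk`, `make_sc_counts`,
`make_cross_species`, `make_tonic_reference`) are pure functions of their
parameters and a seed, and their defaults define the package's standard
study conditions:

* tissue panel: 2,000 genes, 33 samples in 11 true groups, 50 planted
  TRAs expressing at 1,000 linear units in 1–3 groups over a background
  of 10 (a 100-fold contrast), group-level noise SD 1;
* bulk mTECs: log2 scale, baselines Uniform(6, 12) (keeps shifted KO
  means positive without truncation distortion), 100 planted
  Aire-dependent genes at LFC −4, noise SD 0.25, 4 KO vs 3–4 control
  replicates, matching the microarray-style regime of a small purified
  mTEC cohort;
* single cells: negative-binomial counts with a single global dispersion
  (0.1) — the minimal noise structure that exercises pseudobulk DE and
  the IFN score — log-normal library sizes around 5,000 UMIs, three cell
  types, three animals per genotype, and tonic-sensitive ISGs
  downregulated 2^−2-fold in knockout cells;
* cross-species: four modules over 1,000 orthologs — conserved
  (downregulated everywhere), rat-specific, mouse-specific and null —
  with TRA membership planted at 50% inside the conserved module versus
  10% outside.

What the generators deliberately do not emulate: doublets, ambient RNA,
batch effects, cell-to-cell correlation beyond module structure, or
platform-specific probe behavior.  Tests passing on this cohort therefore
demonstrate that the algorithms are implemented correctly and recover
planted signal at realistic effect sizes — not that any particular
biological dataset would yield the same numbers.

# Numerical choices and degenerate inputs

Ties in group ranking break deterministically by group label; ties in
expression bins by first-occurrence rank.  Equal-mean zero-variance genes
get p = 1 in the Welch test (zero-variance with unequal means gives an
infinite t, hence p = 0).  Zero-variance samples make correlation
distance undefined and are reported by name.  The rarefaction binomials
are computed via `lchoose` to avoid overflow at large N, and terms with
`N − n_g < m` contribute exactly 1.  Permutation p values are never 0 by
construction.  All stochastic stages derive their seed from
(global seed, stage name), so stages are independently reproducible and
rerunning a configuration reproduces deterministic outputs byte for byte.

Problem sizes in the shipped tests (hundreds to a few thousand genes,
tens to hundreds of cells per stratum, 10²–10⁴ permutations/bootstrap
replicates) are the package's chosen standard conditions for
demonstrating the statistical contracts; all scale linearly if increased.

# Known limitations

The Welch + BH bulk test is a documented stand-in for an unstated
console test; the IFN score's aggregation level and normalization are
explicit choices where the source description is silent; bootstrap node
supports are plain proportions, not multiscale-corrected; and the
diversity machinery intentionally supports only order 0.  The gene-set
universe for per-population enrichment is each population's tested genes,
flagged in the output so a shared-universe reanalysis remains possible.
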