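---
title: "Models and methods behind coralfront"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind coralfront}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coralfront)
```

## The scientific question

Coral chimeras are single colonies formed by the fusion of two or more
genetically distinct conspecific individuals. Compared with genetically
homogeneous colonies, chimeras of *Stylophora pistillata* survive better in
the field, and one candidate mechanism is *frontloading*: stress-responsive
genes held constitutively at an elevated baseline, so the colony is
prepared for an environmental insult before it arrives, at the cost of a
smaller induced response. The complementary axis is *transcriptomic
plasticity* — how far the expression profile moves when the environment
changes, for example when a colony acclimated at 10 m depth is translocated
to 2 m for 48 h and suddenly sees higher light and temperature variability.

`coralfront` implements the count-level statistical pipeline for this
comparison: negative-binomial differential expression with a mother-colony
covariate, the frontloading/higher-plasticity classification, rank-based GO
enrichment with adaptive category clustering and delta-rank comparison,
fit-and-project discriminant analysis (DAPC) as a plasticity measure,
chimerism validation from microsatellites and multiallelic MNP calls,
microbiome diversity, and the field survival/logger statistics. A
synthetic-data module generates every input with known ground truth, so
each stage is testable without the original sequencing reads.

## Differential expression

Counts for gene $g$ in sample $j$ are modelled as
$K_{gj} \sim \mathrm{NB}(\mu_{gj}, \alpha_g)$ with
$\mathrm{Var} = \mu + \alpha \mu^2$ and

$$\log \mu_{gj} = \log s_j + x_j^\top \beta_g,
\qquad x_j : \texttt{\~{} treatment + mother\_colony}.$$

* **Size factors** $s_j$ use the median-of-ratios convention: the median,
  over genes with all-positive counts, of the count divided by the gene's
  geometric mean. Genes containing a zero never enter the reference.
* **Contrasts.** The four biological contrasts (entity within each depth,
  depth within each entity) are run as separate two-factor fits on the
  stratum's samples, with the mother colony always retained — colonies
  descend from a handful of mothers, and that shared origin is a genuine
  batch structure. A rank-deficient design (mother confounded with
  treatment) is refused with the aliased columns named.
* **Dispersion.** Per gene, a Poisson-then-NB two-pass fit provides fitted
  means and hat values $h_j$; the raw estimate is the leverage-corrected
  method of moments
  $\hat\alpha_g = \sum_j [(y_j - \hat\mu_j)^2 - (1 - h_j)\hat\mu_j] \,/\,
  \sum_j (1 - h_j) \hat\mu_j^2$. The leverage correction matters here: with
  seven mothers and a treatment factor, the design spends most of the ten
  samples in a stratum, and an uncorrected estimator is badly biased
  toward zero. Raw estimates stay unclamped when the mean-dispersion trend
  $a_0 + a_1/\mu$ is fitted through their binned means (clamping at zero
  first would bias the trend upward near the Poisson limit), and the final
  value is $(1-w)\,\hat\alpha_g + w\,\mathrm{trend}$, floored at $10^{-8}$.
  The default weight $w = 0.85$ is empirical-Bayes-style moderation: with
  roughly two residual degrees of freedom per gene, the per-gene estimate
  deserves little weight against a trend pooled from two thousand genes
  (the equivalent of a prior worth about eleven degrees of freedom). When
  the expression range is too narrow to anchor the $1/\mu$ term, or the
  unconstrained fit leaves the positive quadrant, the trend falls back to
  the constant mean.
* **Testing.** With the dispersion plugged in, each gene is refit by IRLS
  and the Wald statistic on the contrast coefficient gives a two-sided
  normal p-value; Benjamini–Hochberg step-up adjustment is applied within
  each contrast. Fold changes are reported in log2 units and
  `log2fc > 0` always means higher in the first-named level.

This is deliberately a *simplified* NB engine, not a port of any published
implementation: no outlier filtering, no independent filtering, no fold
change shrinkage. The downstream conclusions rest on contrasts and FDR
thresholds, not on those refinements.

For ordination and the plasticity analysis, counts are transformed as
$\log_2(k/s_j + 1)$ — monotone, variance-damping and dependency-free — and
the mother-colony effect is removed by per-gene linear modelling
(`limma::removeBatchEffect` stands behind `remove_batch_effect()`), leaving
retained design effects untouched.

## Frontloading classification

Starting from the genes that respond to translocation in non-chimeras
(FDR < $\alpha$, default 0.05), each gene is looked up in two further
contrasts:

| category | basal contrast (chimera vs non-chimera at 10 m) | chimera response (2 m vs 10 m) |
|---|---|---|
| FRONTLOADED | significantly **higher** | not amplified |
| HIGHER_PLASTICITY | not higher | significant, **larger** and same-direction |
| FRONTLOADED_AND_HIGHER_PLASTICITY | both conditions | both conditions |
| UNCLASSIFIED | neither | neither (including opposite-direction amplification) |

The three conditions — basal significance, magnitude ordering
(|chimera| > |non-chimera|), and sign concordance — are individually
switchable flags, because the qualitative definitions ("higher basal
expression", "over- or under-expressed higher") do not pin down a unique
statistical rule. The defaults require all three; an amplified response in
the *opposite* direction is not higher plasticity but a qualitatively
different behaviour, hence UNCLASSIFIED. Genes that respond identically in
both entities (the generator's RESPONSIVE_ONLY archetype) split between
HIGHER_PLASTICITY and UNCLASSIFIED purely by estimation noise in the
magnitude comparison; that is a property of any rule of this shape, which
is why recovery guarantees are stated only for the planted categories and
for the false-classification rate of true null genes.

## GO enrichment

The enrichment engine reimplements the adaptive-clustering, rank-based
approach:

1. **Index.** Gene-to-term annotations are restricted to the analysis
   universe, optionally closed over `is_a` parent links, and filtered:
   categories with fewer than `smallest = 10` genes or more than
   `largest = 0.1` of the universe are dropped.
2. **Clustering.** Near-duplicate categories are merged by complete-linkage
   clustering of the dissimilarity
   $d(A,B) = 1 - |A \cap B| / \min(|A|,|B|)$ cut at
   `cut_height = 0.5` (Jaccard available behind a flag). Overlap over the
   smaller set is the choice that makes a subset of a large term merge into
   it; merged unions are re-checked against the `largest` filter so a
   merged mega-category cannot sneak past it. The order is fixed:
   filter, cluster, re-filter.
3. **Test.** Genes are ranked by the continuous measure (log2 fold change;
   midranks for ties) and each category's members are compared with
   non-members by the Mann–Whitney test; the *delta-rank* (mean member rank
   minus mean non-member rank) is the effect size. For binary gene sets the
   Fisher exact test is computed by two-sided hypergeometric summation.
   BH adjustment runs across categories. Two analyses are compared by the
   Pearson correlation of delta-ranks over shared categories, matched by
   member-set identity with a name fallback.

Because the test is rank-based, results are invariant under any monotone
transform of the measure — asserted in the tests by re-running on
exponentiated measures. The reported `n_strong` count (members with
|log2FC| above 2) is a display statistic for figure labels, never a test
input.

## DAPC plasticity

The plasticity measure fits the model on one entity and projects the other:

1. centre the non-chimera samples' adjusted log counts and reduce by SVD,
   keeping the smallest number of PCs explaining ≥ 80 % of variance,
   capped at $n_{\mathrm{train}} - 3$;
2. fit a linear discriminant (pooled within-group covariance) on the PC
   scores with the two depths as groups — two groups give one axis;
3. project the chimera samples with the stored centring, loadings and
   coefficients.

Per entity the summary is the **shift** (absolute difference of mean
coordinates, stressed minus control), the **overlap** (symmetric
range-overlap fraction of the two coordinate clouds), and the
**diversity** (pooled within-condition coordinate variance). A reduced
chimera shift relative to non-chimeras is the reduced-plasticity pattern.
The axis sign is fixed by making the largest-magnitude discriminant
loading positive, so results are deterministic; at full PC rank the
coordinates equal plain LDA up to that sign, which the tests assert
against an independent LDA implementation.

## Chimerism validation

Two independent routes:

* **Microsatellites.** Fusion partners are siblings (same mother, unknown
  sperm donors), so two alleles at a locus prove nothing; *more than two*
  distinct alleles at any locus prove two co-occurring genomes. Duplicate
  allele entries are collapsed before counting.
* **MNPs from RNA-seq variant calls.** An MNP record is one whose REF spans
  at least two bases with all ALT alleles the same length (a short
  haplotype of SNPs). The per-sample statistic is the fraction of MNP
  records whose distinct-allele count (from the genotype field when
  present, else REF plus all ALTs) exceeds a threshold. The source
  material states the threshold inconsistently ("more than 2" in one
  place, "more than 3" in another), so it is a required, logged parameter;
  the default is more than 2 distinct alleles, consistent with the
  microsatellite rule. Groups are compared by the Mann–Whitney test on the
  per-sample fractions — exact p by the null distribution of U when
  $n_1 n_2 \le 400$ and the data are tie-free, otherwise the tie-corrected
  normal approximation with continuity correction; the exact mode refuses
  ties rather than approximating silently.

## Microbiome and field statistics

The OTU stage filters (total relative abundance below 1 %, singletons),
then computes observed richness, bias-corrected Chao1
($S + F_1(F_1-1)/(2(F_2+1))$, finite when doubletons are absent), Shannon
entropy (natural log by default, base-2 behind a flag), Bray–Curtis
dissimilarity on raw counts (scale-sensitive by construction; no
rarefaction by default, seeded subsampling offered), and classical-scaling
PCoA, dropping negative-eigenvalue axes with a logged count. Group
differences in the alpha indices use one-way ANOVA across the four
entity-by-depth cells with BH across the three indices; a two-factor
decomposition sits behind a flag. (The reported per-index p-values are what
"MANOVA" denotes in this literature; a joint multivariate test of three
highly correlated indices would answer a different question.)

Field statistics are exact binomial (Clopper–Pearson) survival intervals
via Beta quantiles, and Pearson chi-square 2×2 tests per census time —
independent per timepoint, matching how paired survival percentages are
reported; no longitudinal model is attempted. The Yates correction is off
by default and exposed as a flag. Logger series are summarized per depth:
temperature min/mean/max and coefficient of variation (sample sd over mean
on the raw °C scale; Kelvin behind a flag, since CV on an interval scale
is convention-dependent), mean light, and the maximum light among records
whose local clock time falls in the 10:00–16:00 diurnal window, endpoints
inclusive.

## The synthetic-data generator

The generator is the package's study-conditions encoding, not a tuning
knob. The `paper_like` preset fixes 2000 genes, five colonies per
entity-by-depth cell, seven mother colonies assigned cyclically over the
ordered sample list (so every mother spans entities and depths and the
covariate stays estimable), NB dispersion 0.1, a log2 response of 2, a
basal frontloading shift of 2, a plasticity gain of 1, and
60/60/60/200 genes planted as FRONTLOADED / HIGHER_PLASTICITY / both /
RESPONSIVE_ONLY. Baseline log-means are drawn from
$\mathcal{N}(\log 100, 1)$ and the mother effect is an additive
$\mathcal{N}(0, 0.5)$ intercept on the natural-log scale, drawn
independently per gene and mother — the simplest structure that makes the
batch covariate genuinely necessary. Neither value is dictated by the
study design, so they were fixed once at magnitudes a sequencing
practitioner would call moderate (a 2.7-fold typical mother effect) and
documented here. Each responsive gene's direction is drawn up or down with
equal probability: real stress responses mix over- and under-expression,
and an all-up response set would additionally violate the mostly-unchanged
assumption behind median-of-ratios normalization. Effects are additive on
the natural-log mean scale; log2 inputs are converted internally.

The `frontload_heavy` preset (no higher-plasticity or combined genes)
suppresses the extra chimera response so chimeras respond only through the
shared RESPONSIVE_ONLY genes — the configuration under which the DAPC
projection should, and does, show the smaller chimera shift.

The MNP generator plants an additive multiallelic excess (default 0.3) on
a base rate of 0.2, with 11 chimera and 9 non-chimera samples — the
per-group sizes for the group comparison are not stated in the source
material, so the preset uses the validated-chimera versus remainder split
and flags it as a choice. The OTU generator is Dirichlet-multinomial with
a compositional group tilt; the logger generator is a diel sinusoid plus
Gaussian noise with a truncated-sinusoid light curve; survivors follow a
binomial chain, which enforces monotone counts.

What the generator does *not* emulate: library-size heterogeneity beyond
the batch effect, gene-gene correlation, gene-specific dispersion spread,
linkage between variant loci, phylogenetic structure among OTUs, or
sensor drift. Passing recovery tests therefore demonstrates the
pipeline's correctness under the stated model, not robustness to every
failure mode of real data.

## Numerical choices and degenerate inputs

* All randomness flows through per-call integer seeds; the same inputs and
  seed reproduce byte-identical outputs, asserted in the tests.
* Wald p-values for genes whose IRLS fit collapses are set to 1 rather
  than dropped; all-zero genes are removed before testing with a logged
  count; all-zero dispersion genes receive the floor and a flag.
* The exact Fisher p sums hypergeometric densities no larger than the
  observed one (with the customary $1+10^{-7}$ slack) and is capped at 1.
* BH adjustment is the plain step-up with monotone enforcement, returned
  in input order; it is checked against the stock implementation on random
  vectors.
* PCoA warns through its eigenvalue report, not through the underlying
  scaling routine; identical samples produce identical coordinates.
* The tests run the full suite — including the null-calibration,
  recovery, coverage and power simulations — at the preset sizes above
  (2000 genes, 50 mixed replicates, 100 projection and power replicates,
  1000 enrichment universes), which completes in a few minutes on a single
  core; these sizes are the package's chosen Monte-Carlo budget and are
  stated here so that reruns are comparable.

## Known limitations

* The NB engine's normal-reference Wald test is mildly anticonservative in
  the extreme tail at these sample sizes; the empirical FDR at q = 0.05
  stays within 1.5× nominal under the preset, but single-gene p-values
  below about $10^{-4}$ should not be over-read.
* The classification rule conditions on point significance in three
  contrasts and does not propagate estimation uncertainty into category
  membership; borderline genes flip categories under resampling.
* Delta-rank matching across analyses assumes category member sets are
  comparable; after aggressive clustering, matching falls back to display
  names.
* The microbiome stage tests alpha indices per index; it does not model
  compositionality or perform differential-abundance testing (out of
  scope).
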