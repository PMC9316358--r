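# coralfront

Statistical pipeline for asking whether chimeric corals **frontload**
stress-response genes — hold them constitutively at an elevated baseline —
and whether chimerism trades transcriptomic **plasticity** for robustness.
It is written for researchers analysing count-level multi-omic data from a
two-entity (chimera vs non-chimera), two-environment (10-m depth vs a 48-h
translocation to 2 m) design in *Stylophora pistillata* or comparable
systems, and for anyone who wants the component methods (rank-based GO
enrichment with adaptive clustering, fit-and-project DAPC, multiallelic MNP
chimerism testing) as reusable, tested functions.

## What it computes

* **Differential expression**: per-gene negative-binomial log-linear models
  `~ treatment + mother_colony`, median-of-ratios size factors,
  leverage-corrected moment dispersion estimates shrunk to a mean trend, a
  Wald test on the contrast coefficient, and Benjamini–Hochberg FDR. Four
  contrasts: entity within each depth, depth within each entity.
* **Frontloading classification**: genes responding in non-chimeras
  (FDR < 0.05) are split into FRONTLOADED (higher basal expression in
  chimeras, `basal` FDR < α and log2FC > 0), HIGHER_PLASTICITY (a
  significant chimera response, larger in magnitude and same-signed), both,
  or UNCLASSIFIED.
* **GO enrichment**: Mann–Whitney rank test on log2 fold changes per GO
  category (delta-rank = mean member rank − mean non-member rank), Fisher
  exact mode for binary sets, category filtering
  (`smallest = 10`, `largest = 0.1`) and complete-linkage merging of
  near-duplicate categories at dissimilarity
  `1 − |A∩B|/min(|A|,|B|)` cut at 0.5; delta-rank correlation between
  analyses.
* **DAPC plasticity**: PCA + one-axis linear discriminant fit on
  non-chimera samples (10 m vs 2 m), chimeras projected onto the axis;
  per-entity shift, range overlap and coordinate diversity.
* **Chimerism validation**: the more-than-two-alleles microsatellite rule,
  and per-sample fractions of multiallelic MNP records from VCF variant
  calls compared by an exact/normal Mann–Whitney U test.
* **Microbiome**: OTU filtering, observed/Chao1/Shannon alpha diversity,
  Bray–Curtis, PCoA, per-index ANOVA.
* **Field statistics**: Clopper–Pearson survival intervals, 2×2 chi-square
  per census, and HOBO-logger summaries (temperature CV, mean light,
  diurnal-window maxima).
* **Synthetic data**: generators for every input — NB counts with planted
  frontloading archetypes and mother-colony batch effects, GO maps with
  planted terms, per-sample VCFs with elevated chimera multiallelism,
  Dirichlet-multinomial OTU tables, diel logger series, survival counts —
  with ground truth returned alongside.

## Worked example

```r
library(coralfront)

ps  <- sim_preset("paper_like", seed = 42)   # 2000 genes, 5 colonies/cell, 7 mothers
sim <- simulate_counts(ps$design, ps$params)

resp  <- de_contrast(sim$counts, sim$metadata, "depth",  "nonchimera")
basal <- de_contrast(sim$counts, sim$metadata, "entity", "10m")
chim  <- de_contrast(sim$counts, sim$metadata, "depth",  "chimera")

sum(resp$fdr < 0.05)
#> [1] 388

cls <- classify_frontloading(resp, basal, chim)
table(cls$category)
#>                       FRONTLOADED FRONTLOADED_AND_HIGHER_PLASTICITY
#>                                55                                58
#>                 HIGHER_PLASTICITY                      UNCLASSIFIED
#>                               150                               125

adj <- remove_batch_effect(normalized_log_counts(sim$counts),
                           sim$metadata$mother_colony)
dapc_plasticity(adj, sim$metadata)$metrics
#>       entity shift overlap diversity
#> 1    chimera  24.3       0      43.4
#> 2 nonchimera  30.9       0      18.7
```

Reading the output: 388 genes respond to the simulated translocation in
non-chimeras (380 were planted). Of the 55 genes called FRONTLOADED, all
carry a planted constitutive elevation; the 150 HIGHER_PLASTICITY calls
contain the 60 planted amplified responders plus equal-responders that win
the magnitude comparison by noise — an inherent property of any
magnitude-ordering rule, quantified in the tests. The DAPC shift is
smaller and the coordinate diversity larger in chimeras than in
non-chimeras: the reduced-plasticity, increased-diversity pattern the
projection analysis is designed to detect.

The whole analysis graph also runs as one call:

```r
report <- run_pipeline(pipeline_config(preset = "paper_like", seed = 1,
                                       out_dir = "run1"))
```

which writes per-contrast DE tables, the classification, enrichment
results, DAPC coordinates, MNP summaries and a JSON + text run report into
`run1/`.

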