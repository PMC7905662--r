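# glycoStrat

Glycolysis-associated lncRNA scoring and patient stratification for bulk
RNA-Seq cohorts.

Tumor glycolysis is a hallmark metabolic program, and a subset of long
noncoding RNAs (lncRNAs) tracks it closely enough to stratify patients into
clinically distinct groups. glycoStrat packages that analysis strategy as a
tested, reusable pipeline for anyone who wants to apply it to a count
matrix of their own or to study its operating characteristics:

1. **Score** per-sample glycolytic activity by single-sample gene set
   enrichment (ssGSEA) of a glycolysis gene set — the integrated difference
   of the weighted in-set and unweighted out-of-set rank ECDFs,
   $\mathrm{ES} = \sum_i [P^w_{\mathrm{in}}(i) - P_{\mathrm{out}}(i)]$.
2. **Select** glycolysis-associated lncRNAs by Pearson correlation with the
   score, keeping $|r| > 0.3$ at Benjamini–Hochberg FDR $< 0.05$.
3. **Stratify** patients by consensus clustering: 1000 iterations of PAM on
   a 95% feature resample of the selected lncRNAs, cluster number guided by
   the consensus-CDF delta area, labels canonicalized so cluster 3 is the
   high-glycolysis group.
4. **Characterize** clusters: Kaplan–Meier/log-rank survival,
   Kruskal–Wallis + Dunn score comparisons, Fisher-exact mutation
   enrichment, Welch/NB differential expression, preranked GSEA with
   permutation NES/FDR, aREA regulon activity with an ANOVA effect-size
   screen, ssGSEA immune infiltration with Ward grouping, and an immune
   checkpoint screen.
5. **Transfer** cluster labels to external expression data with a lasso
   multinomial genomic classifier (10-fold CV, minimum-deviance lambda,
   KKT-verified solutions) after pooled-reference quantile normalization.
6. **Quantify linkage** of lncRNA, glycolysis score $x$ and gene expression
   $y$ by the first-order partial correlation
   $r_{xy\cdot z} = (r_{xy} - r_{xz} r_{yz}) / \sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}$,
   comparing raw and adjusted coefficient distributions with a
   Kolmogorov–Smirnov test, plus a covariate-adjusted regression screen
   against copy-number and methylation.

A negative-binomial synthetic cohort generator with planted ground truth
(latent glycolytic activity per cluster, signed lncRNA correlations,
cluster-dependent survival, an enriched mutation, active regulons, immune
blocks, compartment-biased localization) makes every stage testable for
parameter recovery at desk scale. See `vignette("glycoStrat-methods")` for
the models, assumptions and design decisions.

## Worked example

```r
library(glycoStrat)

cohort <- generateCohort(cohortConfig(seed = 5))
cohort
#> class: GlycoCohort
#> dim: 2120 150
#> ...
#> features: 2000 coding, 120 lncRNA
#> mutations: 30 features; cnv: 40; methylation: 40
#> geneSets(12): GLYCOLYSIS, DECOY_01, DECOY_02, DECOY_03
#> truth: planted, 3 clusters

res <- runPipeline(cohort, pipelineConfig(nIter = 150, gseaNperm = 1000,
                                          seed = 11))

nrow(res$selected)                     # lncRNAs passing |r| > 0.3, q < 0.05
#> [1] 40
table(res$cluster, cohortTruth(cohort)$cluster)
#>      1  2  3
#>   1 50  2  0
#>   2  0 42  0
#>   3  0  0 56
res$logrank$p                          # survival differs across clusters
#> [1] 0.000181179
res$mutationEnrichment$focusHigh$feature
#> [1] "MUT001"                         # the planted enriched mutation
sapply(res$linkage, `[[`, "p")         # KS p: conditioning on each candidate
#> LNC0021      LNC0033      ...        # lncRNA shifts the score-gene
#> 3.8e-09      4.6e-07      ...        # correlation distribution
length(signatureFeatures(res$classifier))
#> [1] 6                                # genomic classifier signature size
```

The cluster table shows near-perfect recovery of the three planted groups
(cluster 3 = highest glycolysis score by construction of the
canonicalization); the log-rank p-value reflects the planted hazard ratios
(1, 1.5, 3); the linkage p-values show the planted lncRNAs mediating the
score–gene coexpression.

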