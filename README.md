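# m6Apattern

Stratifying lung adenocarcinoma (LUAD) expression cohorts by the joint
behaviour of the 23 N6-methyladenosine (m6A) regulator genes — 8
methyltransferase "writers", 13 binding-protein "readers", 2 demethylase
"erasers" — and condensing the resulting modification patterns into a
per-patient prognostic **m6Ascore**.  The package is written for
computational biologists who want the full analysis chain as tested,
reusable functions rather than a one-off script collection:

1. **Consensus clustering** of samples on the regulator panel
   (1000 subsampling resamples, delta-area selection of the cluster
   number k) → the m6A modification patterns;
2. **ssGSEA** immune-cell-signature scores and **GSVA** pathway scores
   per sample, with moderated-t contrasts between patterns;
3. **phenotype-related DEGs** across the patterns (empirical-Bayes
   moderated t, BH-adjusted), re-clustered into geneclusters;
4. the **m6Ascore**: univariate-Cox prognostic filtering of the DEGs,
   then PCA of the z-scored signature with

   m6Ascore_i = PC1_i + PC2_i

   with the component signs anchored so that high score = protective
   direction, and the score dichotomized at the **maximally selected
   log-rank cutpoint**;
5. survival analysis implemented from first principles (Kaplan–Meier,
   log-rank, Breslow/Efron **Cox proportional hazards** by
   Newton–Raphson), tumor-mutation-burden and CNV summaries, and
   immunotherapy-response comparisons across checkpoint-blockade strata.

Because the original TCGA/GEO meta-cohort cannot be bundled, the package
includes a first-class synthetic cohort generator (`generate_cohort()`)
that plants exactly the structure the analysis is meant to detect: three
regulator-defined subtypes, a poor-prognosis subtype B, immune signatures
elevated in subtype A, TMB anti-coupled and anti-CTLA4 response coupled
to a latent prognosis score.  All tests and the reproduction script run
against this generator.

## Worked example

The numbered drivers under `analysis/` walk the whole study; each prints
its findings and writes tables under `results/tables/`.  Running

```sh
Rscript analysis/01_simulate.R
Rscript analysis/03_cluster_patterns.R
```

produces (abridged):

```
consensus CDF area and relative gain by k:
           2      3      4      5      6
area  0.4918 0.6219 0.6465 0.6666 0.6859
delta 0.2646 0.0394 0.0312 0.0289     NA
chosen k = 3
adjusted Rand index vs planted subtypes: 0.816
log-rank across clusters: chi2 = 137.3 (df 2), p = 1.54e-30
  cluster 1: n = 217, median OS = 41.7
  cluster 2: n = 125, median OS = 7.9
  cluster 3: n = 258, median OS = 62.8
```

The relative CDF-area gain collapses after k = 3 (0.26 → 0.04): three
modification patterns.  They recover the planted subtypes (ARI 0.82) and
separate survival, with the subtype-B-dominated cluster 2 showing the
shortest median OS — the poor-prognosis carcinogenic pattern.  Continuing
with `analysis/05_score.R` and `analysis/06_mutation_immuno.R`:

```
phenotype-related DEGs (union, BH p < 0.05): 233 genes
genecluster consensus on the DEG panel: chosen k = 3
prognostic filter (Wald p < 0.05): 186 genes (125 protective, 61 risk)
m6Ascore cutpoint -6.28 -> 470 HIGH / 130 LOW
HIGH vs LOW: log-rank p = 4.24e-58, HR = 0.15 [0.12, 0.20]
Spearman(m6Ascore, TMB) = -0.560, p = 8e-51
anti-CTLA4 stratum: median response 0.41 (HIGH, n=114) vs -0.98 (LOW, n=28), p = 1.34e-09
CTLA4 ligand expression by score group:
 gene     W        p direction
 CD80 43658 6.73e-14   HIGH_up
 CD86 46793 1.62e-20   HIGH_up
```

High m6Ascore marks the protective orientation: hazard ratio well below
1, lower mutation burden, better anti-CTLA4 response scores, and
up-regulated CTLA4 ligands B7-1 (CD80) / B7-2 (CD86) — each the
simulation twin of the corresponding cohort-level claim.

Everything is also callable directly:

```r
library(m6Apattern)
cohort <- generate_cohort(default_cohort_config())
report <- run_pipeline(cohort$expression, cohort$clinical,
                       cohort$gene_sets, mutations = cohort$mutations,
                       cnv = cohort$cnv, response = cohort$response)
report$consensus$chosen_k      # 3
head(report$score)             # per-sample pc1, pc2, m6ascore, group
```

## Layout

```
R/                  implementation (io, synthetic cohort, consensus
                    clustering, enrichment, diffexpr, survival, m6ascore,
                    mutation, immunotherapy, pipeline)
analysis/           numbered narrative drivers over the package
scripts/acceptance.R  end-to-end reproduction script
tests/testthat/     unit, property and acceptance tests
vignettes/          methods vignette (models, parameters, design choices)
inst/extdata/       toy immune-signature GMT (synthetic)
```
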