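#!/usr/bin/env Rscript
# Per-sample enrichment: ssGSEA immune-signature scores compared across
# the m6A clusters, and GSVA pathway activity with pairwise contrasts.

library(m6Apattern)

cohort <- generate_cohort(default_cohort_config())
asg_tab <- utils::read.delim("results/tables/m6a_cluster_assignments.tsv")
asg <- stats::setNames(asg_tab$m6a_cluster, asg_tab$sample_id)

imm <- ssgsea(cohort$expression, cohort$gene_sets$immune)
cat("mean immune ssGSEA score by cluster:\n")
print(round(t(apply(imm$scores, 1, tapply, asg[colnames(imm$scores)], mean)),
            3))
kw <- do.call(rbind, lapply(rownames(imm$scores), function(s) {
  k <- kruskal_wallis(imm$scores[s, ], asg[colnames(imm$scores)])
  data.frame(set = s, H = k$H, p = k$p)
}))
kw$adj_p <- bh_adjust(kw$p)
cat("Kruskal-Wallis across clusters (immune signatures):\n")
print(kw, row.names = FALSE, digits = 3)

gs <- gsva_scores(cohort$expression, cohort$gene_sets$pathways)
pairs <- utils::combn(sort(unique(asg)), 2, simplify = FALSE)
contrasts <- lapply(pairs, function(pr)
  score_group_contrast(gs, as.character(asg[colnames(gs$scores)]),
                       as.character(pr)))
names(contrasts) <- vapply(pairs, paste, character(1), collapse = "_vs_")
for (nm in names(contrasts)) {
  cat(sprintf("GSVA contrast %s (top rows):\n", nm))
  print(utils::head(contrasts[[nm]], 2), row.names = FALSE, digits = 3)
}

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
utils::write.table(data.frame(set = rownames(imm$scores), imm$scores,
                              check.names = FALSE),
                   "results/tables/immune_ssgsea_scores.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(kw, "results/tables/immune_kruskal.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
for (nm in names(contrasts))
  utils::write.table(contrasts[[nm]],
                     sprintf("results/tables/gsva_contrast_%s.tsv", nm),
                     sep = "\t", quote = FALSE, row.names = FALSE)
cat("enrichment tables written to results/tables/\n")
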