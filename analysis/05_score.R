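#!/usr/bin/env Rscript
# The m6Ascore chain: phenotype DEGs across the clusters, genecluster
# consensus on the DEG panel, univariate-Cox prognostic filter, PCA score,
# cutpoint dichotomization, and survival models.

library(m6Apattern)

cohort <- generate_cohort(default_cohort_config())
cl <- cohort$clinical
asg_tab <- utils::read.delim("results/tables/m6a_cluster_assignments.tsv")
asg <- stats::setNames(asg_tab$m6a_cluster, asg_tab$sample_id)

deg <- phenotype_degs(cohort$expression, asg[colnames(cohort$expression)])
cat(sprintf("phenotype-related DEGs (union, BH p < 0.05): %d genes\n",
            length(deg$genes)))

gc <- consensus_cluster(cohort$expression, deg$genes, k_range = 2:6,
                        n_resamples = 1000, seed = 2)
cat(sprintf("genecluster consensus on the DEG panel: chosen k = %d\n",
            gc$chosen_k))

pf <- prognostic_filter(cohort$expression, deg$genes, cl)
cat(sprintf("prognostic filter (Wald p < 0.05): %d genes (%d protective, %d risk)\n",
            nrow(pf), sum(pf$direction == "protective"),
            sum(pf$direction == "risk")))

score <- compute_m6ascore(cohort$expression, pf$gene,
                          pf$gene[pf$direction == "protective"])
score <- dichotomize_score(score, cl)
cat(sprintf("m6Ascore cutpoint %.2f -> %d HIGH / %d LOW\n",
            score$cutpoint[1], sum(score$group == "HIGH"),
            sum(score$group == "LOW")))
cat("mean m6Ascore by planted subtype:\n")
print(round(tapply(score$m6ascore, cohort$truth$subtype, mean), 2))

grp <- score$group[match(cl$sample_id, score$sample_id)]
lr <- logrank_test(cl$os_time, cl$os_event, grp)
hr <- cox_fit(cl$os_time, cl$os_event,
              matrix(as.numeric(grp == "HIGH"), ncol = 1), names = "HIGH")
cat(sprintf("HIGH vs LOW: log-rank p = %.3g, HR = %.2f [%.2f, %.2f]\n",
            lr$p, hr$terms$hr, hr$terms$ci_low, hr$terms$ci_high))

stage_num <- match(cl$stage, c("I", "II", "III", "IV"))
covs <- cbind(m6ascore = score$m6ascore[match(cl$sample_id, score$sample_id)],
              age = cl$age, gender = as.integer(cl$gender == "male"),
              stage = stage_num)
multi <- cox_fit(cl$os_time, cl$os_event, covs)
cat("multivariate Cox (score + age + gender + stage):\n")
print(multi$terms, digits = 3, row.names = FALSE)

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
utils::write.table(as.data.frame(score),
                   "results/tables/m6ascore.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(pf, "results/tables/prognostic_genes.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(sample_id = names(gc$assignments[[as.character(gc$chosen_k)]]),
             genecluster = gc$assignments[[as.character(gc$chosen_k)]]),
  "results/tables/genecluster_assignments.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(multi$terms, "results/tables/cox_multivariate.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("score chain tables written to results/tables/\n")
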