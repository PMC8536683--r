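#!/usr/bin/env Rscript
# Regulator-level landscape: catalog composition, somatic mutation
# frequency of the 23-gene panel, and CNV gain/loss frequencies.

library(m6Apattern)

cohort <- generate_cohort(default_cohort_config())
cat23 <- default_regulator_catalog()

cat(sprintf("regulator catalog: %d genes (%d writers, %d readers, %d erasers)\n",
            nrow(cat23), sum(cat23$category == "WRITER"),
            sum(cat23$category == "READER"), sum(cat23$category == "ERASER")))

freq <- gene_mutation_frequency(cohort$mutations, cohort$clinical$sample_id,
                                cat23$symbol)
cat(sprintf("samples with >= 1 regulator mutation: %d/%d (%.1f%%)\n",
            freq$panel_n_mutated, nrow(cohort$clinical),
            100 * freq$panel_fraction))
top <- freq$per_gene[order(-freq$per_gene$n_mutated), ][1:5, ]
cat("most frequently mutated regulators:\n")
print(top, row.names = FALSE)

cnv <- cnv_frequency(cohort$cnv)
cnv <- cnv[order(-cnv$gain_fraction), ]
cat("top amplified / deleted regulators:\n")
print(utils::head(cnv, 3), row.names = FALSE)
print(utils::head(cnv[order(-cnv$loss_fraction), ], 3), row.names = FALSE)

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
utils::write.table(freq$per_gene, "results/tables/regulator_mutation_freq.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(cnv, "results/tables/regulator_cnv_freq.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("tables written to results/tables/\n")
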