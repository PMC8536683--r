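#' Per-gene and panel-level mutation frequency
#'
#' A sample counts as mutated for a gene when it carries at least one
#' record for it; the panel-level fraction is the share of cohort samples
#' with a mutation in any listed gene.
#'
#' @param mt mutation table (`sample_id`, `gene_symbol`, `variant_class`).
#' @param cohort_samples all sample ids of the cohort (denominator).
#' @param genes genes to summarize.
#' @return list: `per_gene` data.frame (`gene`, `n_mutated`, `fraction`),
#'   `panel_n_mutated`, `panel_fraction`.
#' @export
gene_mutation_frequency <- function(mt, cohort_samples, genes) {
  if (!length(cohort_samples)) stop("cohort_samples must be nonempty")
  n <- length(unique(cohort_samples))
  sub <- mt[mt$gene_symbol %in% genes & mt$sample_id %in% cohort_samples, ,
            drop = FALSE]
  per_gene <- data.frame(gene = genes, n_mutated = 0L, fraction = 0,
                         stringsAsFactors = FALSE)
  if (nrow(sub)) {
    counts <- tapply(sub$sample_id, sub$gene_symbol,
                     function(s) length(unique(s)))
    idx <- match(names(counts), per_gene$gene)
    per_gene$n_mutated[idx] <- as.integer(counts)
    per_gene$fraction <- per_gene$n_mutated / n
  }
  panel_n <- length(unique(sub$sample_id))
  list(per_gene = per_gene, panel_n_mutated = panel_n,
       panel_fraction = panel_n / n)
}

#' Default nonsynonymous variant classes
#' @return character vector of MAF Variant_Classification values counted
#'   toward tumor mutation burden.
#' @export
default_nonsyn_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
    "Frame_Shift_Ins", "Splice_Site", "In_Frame_Del", "In_Frame_Ins",
    "Translation_Start_Site", "Nonstop_Mutation")
}

#' Per-sample tumor mutation burden
#'
#' Counts nonsynonymous records per sample (cohort samples absent from the
#' mutation table get 0) and divides by the captured exome size in Mb.
#'
#' @param mt mutation table.
#' @param cohort_samples all sample ids (rows of the result).
#' @param nonsyn_classes variant classes counted
#'   ([default_nonsyn_classes()]).
#' @param exome_mb exome size in megabases (default 38).
#' @return data.frame `sample_id`, `n_mutations`, `tmb`.
#' @export
tmb <- function(mt, cohort_samples,
                nonsyn_classes = default_nonsyn_classes(), exome_mb = 38) {
  if (exome_mb <= 0) stop("exome_mb must be positive")
  sub <- mt[mt$variant_class %in% nonsyn_classes &
              mt$sample_id %in% cohort_samples, , drop = FALSE]
  counts <- table(factor(sub$sample_id, levels = cohort_samples))
  data.frame(sample_id = cohort_samples,
             n_mutations = as.integer(counts),
             tmb = as.integer(counts) / exome_mb,
             stringsAsFactors = FALSE, row.names = cohort_samples)
}

#' Per-gene CNV gain/loss frequencies
#'
#' @param cnv integer call matrix (genes x samples, codes in -2..2).
#' @return data.frame `gene`, `gain_fraction` (calls > 0), `loss_fraction`
#'   (calls < 0).
#' @export
cnv_frequency <- function(cnv) {
  if (!all(cnv %in% -2:2)) stop("CNV calls outside {-2,...,2}")
  data.frame(gene = rownames(cnv),
             gain_fraction = rowMeans(cnv > 0),
             loss_fraction = rowMeans(cnv < 0),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Expression contrast between mutated and wild-type samples
#'
#' Wilcoxon rank-sum comparison of `expr_gene` expression between samples
#' carrying a mutation in `mut_gene` and wild-type samples.
#'
#' @param mt mutation table.
#' @param m an [expression_matrix()].
#' @param mut_gene gene defining the mutated/wild-type split.
#' @param expr_gene gene whose expression is compared (defaults to
#'   `mut_gene`).
#' @return list `W`, `p`, `direction` (`"mutant_up"` / `"mutant_down"`),
#'   `n_mutant`, `n_wildtype`.
#' @export
mutated_vs_wildtype_expression <- function(mt, m, mut_gene,
                                           expr_gene = mut_gene) {
  if (!expr_gene %in% rownames(m)) stop("expression gene not in matrix: ",
                                        expr_gene)
  mutated <- unique(mt$sample_id[mt$gene_symbol == mut_gene])
  mutated <- intersect(mutated, colnames(m))
  wild <- setdiff(colnames(m), mutated)
  if (!length(mutated)) stop("no mutated samples for gene ", mut_gene)
  if (!length(wild)) stop("no wild-type samples for gene ", mut_gene)
  a <- unclass(m)[expr_gene, mutated]
  b <- unclass(m)[expr_gene, wild]
  wt <- wilcoxon_ranksum(a, b)
  list(W = wt$W, p = wt$p,
       direction = if (stats::median(a) >= stats::median(b)) "mutant_up"
                   else "mutant_down",
       n_mutant = length(mutated), n_wildtype = length(wild))
}

#' Compare tumor mutation burden between score groups
#'
#' Reports the Wilcoxon rank-sum test on per-sample TMB between HIGH and
#' LOW m6Ascore groups plus the fraction of samples in each group carrying
#' any nonsynonymous mutation.
#'
#' @param tmb_table a [tmb()] result.
#' @param st a dichotomized score table (`group` column).
#' @return list `W`, `p`, `median_high`, `median_low`, `mutated_fraction_high`,
#'   `mutated_fraction_low`.
#' @export
tmb_by_score_group <- function(tmb_table, st) {
  common <- intersect(tmb_table$sample_id, st$sample_id)
  if (!length(common)) stop("no shared samples")
  tt <- tmb_table[match(common, tmb_table$sample_id), ]
  grp <- st$group[match(common, st$sample_id)]
  hi <- tt$tmb[grp == "HIGH"]; lo <- tt$tmb[grp == "LOW"]
  if (!length(hi) || !length(lo)) stop("a score group is empty")
  wt <- wilcoxon_ranksum(hi, lo)
  list(W = wt$W, p = wt$p,
       median_high = stats::median(hi), median_low = stats::median(lo),
       mutated_fraction_high = mean(tt$n_mutations[grp == "HIGH"] > 0),
       mutated_fraction_low = mean(tt$n_mutations[grp == "LOW"] > 0))
}
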