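#' Immunotherapy treatment strata
#' @return the four checkpoint-blockade strata labels (anti-PD-1 only,
#'   anti-CTLA4 only, both, neither).
#' @export
response_strata <- function() {
  c("CTLA4neg_PD1pos", "CTLA4pos_PD1neg", "CTLA4pos_PD1pos", "CTLA4neg_PD1neg")
}

#' Compare immunotherapy response between score groups within a stratum
#'
#' Wilcoxon rank-sum test of the response score between HIGH and LOW
#' m6Ascore groups among patients of one treatment stratum.
#'
#' @param rt response table (`sample_id`, `stratum`, `response_score`).
#' @param st dichotomized score table (`group` column).
#' @param stratum one of [response_strata()].
#' @return list `median_high`, `median_low`, `W`, `p`, `n_high`, `n_low`.
#' @export
compare_response <- function(rt, st, stratum = "CTLA4pos_PD1neg") {
  if (!stratum %in% rt$stratum) stop("stratum not present: ", stratum)
  sub <- rt[rt$stratum == stratum, , drop = FALSE]
  if (anyDuplicated(sub$sample_id)) stop("duplicate sample within stratum")
  grp <- st$group[match(sub$sample_id, st$sample_id)]
  hi <- sub$response_score[grp == "HIGH" & !is.na(grp)]
  lo <- sub$response_score[grp == "LOW" & !is.na(grp)]
  if (!length(hi) || !length(lo))
    stop("both score groups must be represented in the stratum")
  wt <- wilcoxon_ranksum(hi, lo)
  list(median_high = stats::median(hi), median_low = stats::median(lo),
       W = wt$W, p = wt$p, n_high = length(hi), n_low = length(lo))
}

#' Checkpoint-ligand expression contrast between score groups
#'
#' Wilcoxon rank-sum test per gene (default the CTLA4 ligands B7-1/CD80 and
#' B7-2/CD86) between HIGH and LOW m6Ascore groups.
#'
#' @param m an [expression_matrix()].
#' @param st dichotomized score table.
#' @param genes genes to contrast (default `c("CD80", "CD86")`).
#' @return data.frame `gene`, `W`, `p`, `direction` (`"HIGH_up"` /
#'   `"HIGH_down"` / `"flat"`).
#' @export
ligand_contrast <- function(m, st, genes = c("CD80", "CD86")) {
  missing_genes <- setdiff(genes, rownames(m))
  if (length(missing_genes))
    stop("gene(s) absent from matrix: ", paste(missing_genes, collapse = ", "))
  common <- intersect(colnames(m), st$sample_id)
  grp <- st$group[match(common, st$sample_id)]
  hi <- common[grp == "HIGH"]; lo <- common[grp == "LOW"]
  if (!length(hi) || !length(lo)) stop("a score group is empty")
  rows <- lapply(genes, function(g) {
    a <- unclass(m)[g, hi]; b <- unclass(m)[g, lo]
    if (stats::sd(c(a, b)) == 0)
      return(list(W = NA_real_, p = 1, direction = "flat"))
    wt <- wilcoxon_ranksum(a, b)
    list(W = wt$W, p = wt$p,
         direction = if (stats::median(a) >= stats::median(b)) "HIGH_up"
                     else "HIGH_down")
  })
  data.frame(gene = genes,
             W = vapply(rows, `[[`, numeric(1), "W"),
             p = vapply(rows, `[[`, numeric(1), "p"),
             direction = vapply(rows, `[[`, character(1), "direction"),
             stringsAsFactors = FALSE)
}
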