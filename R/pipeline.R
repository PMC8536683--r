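#' Default pipeline configuration
#'
#' All stage parameters in one validated list: consensus-clustering
#' controls, enrichment exponents, DEG and prognostic-filter thresholds,
#' the cutpoint minimum group proportion, and the global seed.  Unknown
#' keys passed via `...` are rejected.
#'
#' @param ... overrides of the defaults.
#' @return list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(...) {
  cfg <- list(k_range = 2:6,
              n_resamples = 1000,
              item_fraction = 0.8,
              delta_threshold = 0.1,
              ssgsea_alpha = 0.25,
              gsva_tau = 1,
              deg_threshold = 0.05,
              deg_mode = "UNION",
              prognostic_threshold = 0.05,
              minprop = 0.1,
              exome_mb = 38,
              seed = 1)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full m6A-pattern analysis
#'
#' Executes, in order: (1) consensus clustering of samples on the
#' 23-regulator panel (m6Aclusters); (2) ssGSEA immune-signature scores
#' with a per-set Kruskal-Wallis test across clusters; (3) GSVA pathway
#' scores with pairwise cluster contrasts; (4) phenotype-related DEGs
#' across the clusters; (5) consensus clustering on the DEG panel
#' (geneclusters, k chosen by the same delta-area rule); (6) univariate-Cox
#' prognostic filter, PCA m6Ascore, and cutpoint dichotomization; (7)
#' Kaplan-Meier/log-rank per grouping plus uni- and multivariate Cox of the
#' score with age/gender/stage; (8) mutation frequency, TMB-vs-score and
#' CNV summaries; (9) immunotherapy-response and CTLA4-ligand contrasts.
#' Mutation/CNV/response stages are skipped when those inputs are absent.
#'
#' @param expr an [expression_matrix()] (log2 scale; FPKM/TPM input is
#'   log2(x+1)-transformed at entry).
#' @param clinical clinical table (see [read_clinical()]).
#' @param gene_sets list with elements `immune` and `pathways` (gene-set
#'   lists) — e.g. from [read_gmt()] or the synthetic cohort.
#' @param mutations optional mutation table.
#' @param cnv optional CNV call matrix.
#' @param response optional response table.
#' @param config a [default_pipeline_config()].
#' @param regulator_panel genes to cluster on (default the 23-regulator
#'   catalog intersected with the matrix).
#' @return list of class `report_bundle` with each stage's outputs and a
#'   `provenance` element (config and seed).
#' @export
run_pipeline <- function(expr, clinical, gene_sets,
                         mutations = NULL, cnv = NULL, response = NULL,
                         config = default_pipeline_config(),
                         regulator_panel = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  expr <- log2_transform(expr)
  if (is.null(regulator_panel))
    regulator_panel <- intersect(default_regulator_catalog()$symbol,
                                 rownames(expr))
  if (length(regulator_panel) < 2) stop("regulator panel too small")
  common <- intersect(colnames(expr), clinical$sample_id)
  expr <- expression_matrix(unclass(expr)[, common, drop = FALSE],
                            rownames(expr), common, unit = "LOG2")
  clinical <- clinical[match(common, clinical$sample_id), ]

  # (1) m6A patterns on the regulator panel
  cc <- consensus_cluster(expr, regulator_panel,
                          k_range = config$k_range,
                          n_resamples = config$n_resamples,
                          item_fraction = config$item_fraction,
                          seed = config$seed,
                          delta_threshold = config$delta_threshold)
  m6a_cluster <- cc$assignments[[as.character(cc$chosen_k)]]

  # (2) immune infiltration by ssGSEA + Kruskal-Wallis across clusters
  imm <- ssgsea(expr, gene_sets$immune, alpha = config$ssgsea_alpha)
  imm_kw <- do.call(rbind, lapply(rownames(imm$scores), function(s) {
    kw <- kruskal_wallis(imm$scores[s, ], m6a_cluster)
    data.frame(set = s, H = kw$H, p = kw$p, stringsAsFactors = FALSE)
  }))
  imm_kw$adj_p <- bh_adjust(imm_kw$p)

  # (3) GSVA pathway activity with pairwise cluster contrasts
  gsva_res <- gsva_scores(expr, gene_sets$pathways, tau = config$gsva_tau)
  cl_levels <- sort(unique(m6a_cluster))
  pathway_contrasts <- lapply(utils::combn(cl_levels, 2, simplify = FALSE),
                              function(pr) score_group_contrast(
                                gsva_res, as.character(m6a_cluster),
                                as.character(pr)))
  names(pathway_contrasts) <- vapply(utils::combn(cl_levels, 2, simplify = FALSE),
                                     paste, character(1), collapse = "_vs_")

  # (4) phenotype-related DEGs
  degs <- phenotype_degs(expr, m6a_cluster,
                         p_threshold = config$deg_threshold,
                         mode = config$deg_mode)

  # (5) geneclusters on the DEG panel
  genecluster <- NULL; gc_res <- NULL
  if (length(degs$genes) >= 2) {
    gc_res <- consensus_cluster(expr, degs$genes,
                                k_range = config$k_range,
                                n_resamples = config$n_resamples,
                                item_fraction = config$item_fraction,
                                seed = config$seed + 1,
                                delta_threshold = config$delta_threshold)
    genecluster <- gc_res$assignments[[as.character(gc_res$chosen_k)]]
  }

  # (6) prognostic filter -> m6Ascore -> dichotomization
  prog <- prognostic_filter(expr, degs$genes, clinical,
                            p_threshold = config$prognostic_threshold)
  score <- compute_m6ascore(expr, prog$gene,
                            protective_genes = prog$gene[prog$direction ==
                                                           "protective"])
  score <- dichotomize_score(score, clinical, minprop = config$minprop)

  # (7) survival by cluster, genecluster and score group; Cox models
  surv <- list(
    m6a_cluster = logrank_test(clinical$os_time, clinical$os_event,
                               m6a_cluster),
    score_group = logrank_test(clinical$os_time, clinical$os_event,
                               score$group[match(clinical$sample_id,
                                                 score$sample_id)]))
  if (!is.null(genecluster))
    surv$genecluster <- logrank_test(clinical$os_time, clinical$os_event,
                                     genecluster)
  km_by_cluster <- lapply(split(seq_along(m6a_cluster), m6a_cluster),
                          function(idx) km_estimate(clinical$os_time[idx],
                                                    clinical$os_event[idx]))
  cox_uni <- cox_fit(clinical$os_time, clinical$os_event,
                     matrix(score$m6ascore[match(clinical$sample_id,
                                                 score$sample_id)],
                            ncol = 1),
                     names = "m6ascore")
  cox_multi <- NULL
  covs <- multivariate_covariates(score, clinical)
  if (!is.null(covs)) {
    idx <- attr(covs, "subset")
    cox_multi <- cox_fit(clinical$os_time[idx], clinical$os_event[idx], covs)
  }

  # (8) mutation / CNV summaries
  mut_summary <- NULL
  if (!is.null(mutations)) {
    freq <- gene_mutation_frequency(mutations, clinical$sample_id,
                                    regulator_panel)
    tmb_tab <- tmb(mutations, clinical$sample_id, exome_mb = config$exome_mb)
    rho <- correlate(score$m6ascore,
                     tmb_tab$tmb[match(score$sample_id, tmb_tab$sample_id)],
                     method = "SPEARMAN")
    mut_summary <- list(regulator_frequency = freq, tmb = tmb_tab,
                        score_tmb_spearman = rho,
                        tmb_by_group = tmb_by_score_group(tmb_tab, score))
  }
  cnv_summary <- if (!is.null(cnv)) cnv_frequency(cnv) else NULL

  # (9) immunotherapy response
  immuno <- NULL
  if (!is.null(response)) {
    immuno <- list(ctla4 = compare_response(response, score,
                                            "CTLA4pos_PD1neg"),
                   ligands = ligand_contrast(expr, score))
  }

  structure(list(m6a_cluster = m6a_cluster,
                 consensus = cc,
                 immune_scores = imm,
                 immune_kruskal = imm_kw,
                 gsva = gsva_res,
                 pathway_contrasts = pathway_contrasts,
                 degs = degs,
                 genecluster = genecluster,
                 genecluster_consensus = gc_res,
                 prognostic = prog,
                 score = score,
                 survival = surv,
                 km_by_cluster = km_by_cluster,
                 cox_univariate = cox_uni,
                 cox_multivariate = cox_multi,
                 mutation = mut_summary,
                 cnv = cnv_summary,
                 immunotherapy = immuno,
                 provenance = list(config = unclass(config),
                                   seed = config$seed,
                                   n_samples = ncol(expr))),
            class = "report_bundle")
}

# ordinal stage (I..IV -> 1..4), binary gender, age, plus the score
multivariate_covariates <- function(score, clinical) {
  if (!all(c("age", "gender", "stage") %in% colnames(clinical))) return(NULL)
  stage_num <- match(clinical$stage, c("I", "II", "III", "IV"))
  gender_num <- as.integer(clinical$gender == "male")
  ok <- !is.na(stage_num) & !is.na(gender_num) & !is.na(clinical$age)
  if (sum(ok) < 20) return(NULL)
  covs <- cbind(m6ascore = score$m6ascore[match(clinical$sample_id,
                                                score$sample_id)],
                age = clinical$age, gender = gender_num, stage = stage_num)
  covs <- covs[ok, , drop = FALSE]
  attr(covs, "subset") <- which(ok)
  covs
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf(paste0("report_bundle: %d samples, chosen k = %d, ",
                     "%d DEGs, %d signature genes\n"),
              x$provenance$n_samples, x$consensus$chosen_k,
              length(x$degs$genes), length(attr(x$score, "signature_genes"))))
  invisible(x)
}
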