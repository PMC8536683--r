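#' Default synthetic-cohort configuration
#'
#' The defaults mirror the structure the analysis assumes in a real
#' meta-cohort: three expression subtypes over the 23-gene regulator panel
#' (proportions 0.45/0.18/0.37, emulating the 646/262/522 split), a
#' poor-prognosis subtype B, immune signatures elevated in subtype A, and
#' mutation burden anti-coupled / immunotherapy response coupled to a latent
#' prognosis score.
#'
#' @param n_samples cohort size.
#' @param subtype_proportions three nonnegative numbers summing to 1 (A, B, C).
#' @param n_background_genes genes with no planted structure.
#' @param n_phenotype_genes genes carrying subtype-dependent means (the
#'   recoverable DEGs).
#' @param regulator_shift mean log2 shift of the subtype-specific regulator
#'   blocks.
#' @param phenotype_shift log2 shift of phenotype genes between subtypes.
#' @param immune_shift elevation of immune-signature genes in subtype A.
#' @param noise_sd residual log2-scale standard deviation.
#' @param hazard_log_hr named log hazard ratios per subtype.
#' @param censor_rate target censoring fraction in (0,1).
#' @param tmb_mean_by_subtype mean mutation counts per subtype.
#' @param response_shift coupling of the immunotherapy-response score to the
#'   standardized latent prognosis score.
#' @param seed integer seed; the generator is a pure function of the config.
#' @return A list of class `cohort_config`.
#' @export
default_cohort_config <- function(n_samples = 600,
                                  subtype_proportions = c(A = 0.45, B = 0.18, C = 0.37),
                                  n_background_genes = 300,
                                  n_phenotype_genes = 100,
                                  regulator_shift = 1.2,
                                  phenotype_shift = 1.0,
                                  immune_shift = 1.0,
                                  noise_sd = 1.0,
                                  hazard_log_hr = c(A = -0.5, B = 0.8, C = -0.3),
                                  censor_rate = 0.5,
                                  tmb_mean_by_subtype = c(A = 40, B = 120, C = 60),
                                  response_shift = 1.0,
                                  seed = 42) {
  cfg <- list(n_samples = n_samples,
              subtype_proportions = subtype_proportions,
              n_background_genes = n_background_genes,
              n_phenotype_genes = n_phenotype_genes,
              regulator_shift = regulator_shift,
              phenotype_shift = phenotype_shift,
              immune_shift = immune_shift,
              noise_sd = noise_sd,
              hazard_log_hr = hazard_log_hr,
              censor_rate = censor_rate,
              tmb_mean_by_subtype = tmb_mean_by_subtype,
              response_shift = response_shift,
              seed = seed)
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    if (n_samples < 30) stop("n_samples must be >= 30")
    if (abs(sum(subtype_proportions) - 1) > 1e-9)
      stop("subtype proportions must sum to 1")
    if (any(subtype_proportions < 0)) stop("subtype proportions must be nonnegative")
    if (noise_sd <= 0) stop("noise_sd must be positive")
    if (censor_rate <= 0 || censor_rate >= 1) stop("censor_rate must be in (0,1)")
    if (!all(c("A", "B", "C") %in% names(hazard_log_hr)))
      stop("hazard_log_hr needs entries A, B, C")
    if (any(tmb_mean_by_subtype <= 0)) stop("tmb means must be positive")
    shifted <- c(regulator_shift, phenotype_shift, immune_shift) != 0
    if (any(shifted) && any(round(subtype_proportions * n_samples) == 0))
      stop("a subtype with zero expected samples while its shift is nonzero")
  })
  invisible(cfg)
}

# Regulator blocks planted per subtype (log2 mean shift applies to the
# block's subtype only).
regulator_blocks <- function() {
  list(A = c("METTL14", "RBM15", "YTHDC1", "YTHDC2", "FMR1", "HNRNPA2B1"),
       B = c("IGFBP1", "IGFBP3"),
       C = c("RBM15B", "YTHDF2", "IGFBP2", "FTO", "ALKBH5"))
}

# Deterministic subtype counts from proportions (largest-remainder rounding).
subtype_counts <- function(n, prop) {
  raw <- prop * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(prop))
}

# Censoring horizon: C ~ U(0, c) with c solved so the expected censoring
# fraction given the drawn event times equals the target rate.
solve_censor_horizon <- function(event_times, rate) {
  f <- function(cc) mean(pmin(event_times / cc, 1)) - rate
  upper <- max(event_times) * 2
  # expected rate decreases in c; f(upper) may still exceed 0 if rate tiny
  while (f(upper) > 0) upper <- upper * 2
  stats::uniroot(f, c(1e-8, upper), tol = 1e-10)$root
}

#' Generate a synthetic cohort
#'
#' Produces an expression matrix (23 regulators + background + phenotype +
#' immune-signature genes + CD80/CD86), clinical survival data, ground-truth
#' subtype labels and latent prognosis scores, a mutation table, a CNV call
#' matrix, per-sample immunotherapy-response scores with treatment strata,
#' and toy gene-set collections.  All randomness derives from `config$seed`;
#' the same config yields an identical cohort.
#'
#' Planted structure: subtype-specific regulator blocks (A up in METTL14,
#' RBM15, YTHDC1, YTHDC2, FMR1, HNRNPA2B1; B in IGFBP1/IGFBP3; C in RBM15B,
#' YTHDF2, IGFBP2, FTO, ALKBH5); phenotype genes split into a protective set
#' (up in A/C and in samples with high latent score) and a risk set (up in
#' B); immune signatures and the CTLA4 ligands CD80/CD86 elevated in subtype
#' A and with the latent score; exponential survival with log-hazard =
#' hazard_log_hr[subtype] - latent; negative-binomial mutation counts (size
#' 2) with mean tmb_mean_by_subtype[subtype] * exp(-0.5 * latent); response
#' score = response_shift * standardized(latent) + N(0,1).
#'
#' @param config a [default_cohort_config()] list.
#' @return A list of class `synthetic_cohort` with elements `expression`,
#'   `clinical`, `truth`, `mutations`, `cnv`, `response`, `gene_sets`,
#'   `config`.
#' @export
generate_cohort <- function(config = default_cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))

  counts <- subtype_counts(n, config$subtype_proportions)
  subtype <- sample(rep(names(counts), counts))
  names(subtype) <- sample_ids

  # latent prognosis score: high = good prognosis; subtype B pulled down
  latent <- stats::rnorm(n, 0, 0.5) - 1.0 * (subtype == "B")

  catalog <- default_regulator_catalog()
  regulators <- catalog$symbol
  bg_genes <- sprintf("BG%04d", seq_len(config$n_background_genes))
  ph_genes <- sprintf("PHEN%04d", seq_len(config$n_phenotype_genes))
  immune_sets <- list(
    ACT_CD8_T  = sprintf("IMM_CD8_%02d", 1:10),
    ACT_B_CELL = sprintf("IMM_B_%02d", 1:10),
    NK_CELL    = sprintf("IMM_NK_%02d", 1:10),
    MACROPHAGE = sprintf("IMM_MAC_%02d", 1:10),
    ACT_DC     = sprintf("IMM_DC_%02d", 1:10),
    TFH_CELL   = sprintf("IMM_TFH_%02d", 1:10))
  class(immune_sets) <- "gene_sets"
  imm_genes <- unlist(immune_sets, use.names = FALSE)
  ligands <- c("CD80", "CD86")
  genes <- c(regulators, bg_genes, ph_genes, imm_genes, ligands)

  base <- stats::runif(length(genes), 4, 8)
  names(base) <- genes
  mu <- matrix(base, nrow = length(genes), ncol = n,
               dimnames = list(genes, sample_ids))

  blocks <- regulator_blocks()
  for (st in names(blocks))
    mu[blocks[[st]], subtype == st] <- mu[blocks[[st]], subtype == st] +
      config$regulator_shift

  # phenotype genes: first half protective (up in A/C), second half risk (up in B)
  half <- config$n_phenotype_genes %/% 2
  prot <- ph_genes[seq_len(half)]
  risk <- ph_genes[setdiff(seq_along(ph_genes), seq_len(half))]
  mu[prot, subtype != "B"] <- mu[prot, subtype != "B"] + config$phenotype_shift
  mu[risk, subtype == "B"] <- mu[risk, subtype == "B"] + config$phenotype_shift
  # continuous coupling so the PCA score tracks the latent prognosis score
  mu[prot, ] <- mu[prot, ] + 0.5 * rep(latent, each = length(prot))
  mu[risk, ] <- mu[risk, ] - 0.5 * rep(latent, each = length(risk))

  mu[imm_genes, subtype == "A"] <- mu[imm_genes, subtype == "A"] + config$immune_shift
  mu[imm_genes, ] <- mu[imm_genes, ] + 0.3 * rep(latent, each = length(imm_genes))
  mu[ligands, subtype == "A"] <- mu[ligands, subtype == "A"] + config$immune_shift
  mu[ligands, ] <- mu[ligands, ] + 0.4 * rep(latent, each = length(ligands))

  # toy pathway sets over background genes, nudged per subtype so GSVA
  # contrasts have signal
  pathway_sets <- list(
    PATH_IMMUNE_ACT = bg_genes[1:15],
    PATH_ONCOGENIC  = bg_genes[16:30],
    PATH_METABOLISM = bg_genes[31:45],
    PATH_NEUTRAL    = bg_genes[46:60])
  class(pathway_sets) <- "gene_sets"
  mu[pathway_sets$PATH_IMMUNE_ACT, subtype == "A"] <-
    mu[pathway_sets$PATH_IMMUNE_ACT, subtype == "A"] + 0.6
  mu[pathway_sets$PATH_ONCOGENIC, subtype == "B"] <-
    mu[pathway_sets$PATH_ONCOGENIC, subtype == "B"] + 0.6
  mu[pathway_sets$PATH_METABOLISM, subtype == "C"] <-
    mu[pathway_sets$PATH_METABOLISM, subtype == "C"] + 0.6

  values <- mu + matrix(stats::rnorm(length(mu), 0, config$noise_sd),
                        nrow = nrow(mu))
  expr <- expression_matrix(values, genes, sample_ids, unit = "LOG2")

  # survival: exponential with log-hazard = hazard_log_hr[subtype] - latent
  lh <- config$hazard_log_hr[subtype]
  base_rate <- 1 / 60  # baseline median ~41.6 months
  event_t <- stats::rexp(n, rate = base_rate * exp(lh - latent))
  horizon <- solve_censor_horizon(event_t, config$censor_rate)
  cens_t <- stats::runif(n, 0, horizon)
  os_time <- pmin(event_t, cens_t)
  os_event <- as.integer(event_t <= cens_t)
  clinical <- data.frame(
    sample_id = sample_ids,
    os_time = os_time,
    os_event = os_event,
    age = round(stats::rnorm(n, 65, 9)),
    gender = sample(c("female", "male"), n, replace = TRUE),
    stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                   prob = c(0.5, 0.22, 0.2, 0.08)),
    stringsAsFactors = FALSE, row.names = sample_ids)

  # mutations: NB counts, mean inversely coupled to latent; ZC3H13 the most
  # frequently hit regulator
  mut_mean <- config$tmb_mean_by_subtype[subtype] * exp(-0.5 * latent)
  n_mut <- stats::rnbinom(n, size = 2, mu = mut_mean)
  gene_pool <- c(regulators, bg_genes)
  pool_w <- c(stats::setNames(rep(1, length(regulators)), regulators),
              stats::setNames(rep(4, length(bg_genes)), bg_genes))
  pool_w["ZC3H13"] <- 8
  classes <- c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
               "Frame_Shift_Ins", "Splice_Site", "Silent")
  class_w <- c(0.55, 0.1, 0.08, 0.08, 0.04, 0.15)
  mutations <- data.frame(
    sample_id = rep(sample_ids, n_mut),
    gene_symbol = sample(gene_pool, sum(n_mut), replace = TRUE,
                         prob = pool_w / sum(pool_w)),
    variant_class = sample(classes, sum(n_mut), replace = TRUE, prob = class_w),
    stringsAsFactors = FALSE)

  # CNV: regulators biased toward amplification or deletion, background neutral
  amp_bias <- c("YTHDF1", "VIRMA", "FMR1", "METTL3", "HNRNPC", "RBMX",
                "YTHDF3", "HNRNPA2B1", "LRPPRC", "IGFBP1", "IGFBP3", "FTO",
                "YTHDC1")
  cnv_genes <- regulators
  cnv <- matrix(0L, length(cnv_genes), n, dimnames = list(cnv_genes, sample_ids))
  for (g in cnv_genes) {
    p_gain <- if (g %in% amp_bias) 0.25 else 0.08
    p_loss <- if (g %in% amp_bias) 0.08 else 0.25
    cnv[g, ] <- sample(c(-2L, -1L, 0L, 1L, 2L), n, replace = TRUE,
                       prob = c(p_loss / 3, 2 * p_loss / 3,
                                1 - p_gain - p_loss,
                                2 * p_gain / 3, p_gain / 3))
  }

  strata <- sample(c("CTLA4neg_PD1pos", "CTLA4pos_PD1neg",
                     "CTLA4pos_PD1pos", "CTLA4neg_PD1neg"),
                   n, replace = TRUE)
  response <- data.frame(
    sample_id = sample_ids,
    stratum = strata,
    response_score = config$response_shift *
      as.vector(scale(latent)) + stats::rnorm(n),
    stringsAsFactors = FALSE, row.names = sample_ids)

  truth <- data.frame(sample_id = sample_ids,
                      subtype = subtype,
                      latent_score = latent,
                      stringsAsFactors = FALSE, row.names = sample_ids)

  out <- list(expression = expr,
              clinical = clinical,
              truth = truth,
              mutations = mutations,
              cnv = cnv,
              response = response,
              gene_sets = list(immune = immune_sets, pathways = pathway_sets),
              phenotype_genes = list(protective = prot, risk = risk),
              config = config)
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples, %d genes, subtypes %s\n",
              ncol(x$expression), nrow(x$expression),
              paste(sprintf("%s=%d", names(table(x$truth$subtype)),
                            table(x$truth$subtype)), collapse = " ")))
  invisible(x)
}

#' Write a synthetic cohort to a directory of standard files
#'
#' Emits expression.tsv, clinical.tsv, mutations.maf.tsv, cnv.tsv,
#' response.tsv, truth.tsv, sets.gmt (immune + pathway collections) and
#' config.json.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if absent).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  maf <- data.frame(Tumor_Sample_Barcode = cohort$mutations$sample_id,
                    Hugo_Symbol = cohort$mutations$gene_symbol,
                    Variant_Classification = cohort$mutations$variant_class)
  utils::write.table(maf, file.path(dir, "mutations.maf.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = rownames(cohort$cnv), cohort$cnv,
                                check.names = FALSE),
                     file.path(dir, "cnv.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$response, file.path(dir, "response.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  allsets <- c(unclass(cohort$gene_sets$immune),
               unclass(cohort$gene_sets$pathways))
  class(allsets) <- "gene_sets"
  write_gmt(allsets, file.path(dir, "sets.gmt"))
  jsonlite::write_json(unclass(cohort$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
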