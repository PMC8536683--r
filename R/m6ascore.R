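#' Univariate-Cox prognostic gene filter
#'
#' Fits a univariate Cox model per gene on the z-scored expression values
#' and keeps genes whose Wald p-value falls below `p_threshold`, reporting
#' the direction of effect (risk when beta > 0, protective when beta < 0).
#'
#' @param m an [expression_matrix()].
#' @param genes candidate genes (subset of `rownames(m)`).
#' @param clinical clinical table with `sample_id`, `os_time`, `os_event`;
#'   samples are matched by id to the matrix columns.
#' @param p_threshold Wald p cutoff (default 0.05, uncorrected).
#' @return data.frame `gene`, `beta`, `p`, `direction` for the surviving
#'   genes, with the full per-gene table as attribute `all`.
#' @export
prognostic_filter <- function(m, genes, clinical, p_threshold = 0.05) {
  missing_genes <- setdiff(genes, rownames(m))
  if (length(missing_genes))
    stop("gene(s) absent from matrix: ", paste(missing_genes, collapse = ", "))
  common <- intersect(colnames(m), clinical$sample_id)
  if (length(common) < 10) stop("too few samples shared with clinical table")
  cl <- clinical[match(common, clinical$sample_id), ]
  x <- unclass(m)[genes, common, drop = FALSE]
  res <- lapply(genes, function(g) {
    v <- x[g, ]
    if (stats::sd(v) == 0) return(c(NA_real_, NA_real_))
    fit <- cox_fit(cl$os_time, cl$os_event,
                   matrix(as.vector(scale(v)), ncol = 1), names = g)
    c(fit$terms$beta[1], fit$terms$p[1])
  })
  tab <- data.frame(gene = genes,
                    beta = vapply(res, `[[`, numeric(1), 1L),
                    p = vapply(res, `[[`, numeric(1), 2L),
                    stringsAsFactors = FALSE)
  tab$direction <- ifelse(tab$beta > 0, "risk", "protective")
  keep <- !is.na(tab$p) & tab$p < p_threshold
  if (!any(keep))
    stop("no gene passed the prognostic filter; consider a larger p_threshold")
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all") <- tab
  out
}

#' Compute the m6Ascore from a phenotype-gene signature
#'
#' Each signature gene is z-scored across samples; principal components are
#' obtained from the SVD of the samples x genes matrix (correlation-PCA);
#' the per-sample score is PC1 + PC2.  Sign orientation is deterministic:
#' each component's loading vector is flipped, when needed, so that the sum
#' of loadings over protective genes (univariate Cox beta < 0) is positive
#' -- anchoring "high score" to good prognosis; if that sum is zero the
#' largest-|loading| gene is made positive.
#'
#' @param m an [expression_matrix()].
#' @param signature_genes at least 2 genes present in the matrix.
#' @param protective_genes optional subset of `signature_genes` used as the
#'   orientation anchor (typically from [prognostic_filter()]'s direction
#'   column).
#' @return data.frame of class `score_table`: `sample_id`, `pc1`, `pc2`,
#'   `m6ascore`, plus attributes `loadings`, `orientation_sign`,
#'   `signature_genes`.
#' @export
compute_m6ascore <- function(m, signature_genes, protective_genes = NULL) {
  missing_genes <- setdiff(signature_genes, rownames(m))
  if (length(missing_genes))
    stop("signature gene(s) absent: ", paste(missing_genes, collapse = ", "))
  if (length(signature_genes) < 2) stop("need at least 2 signature genes")
  if (ncol(m) < 3) stop("need at least 3 samples")
  x <- unclass(m)[signature_genes, , drop = FALSE]
  sdv <- apply(x, 1L, stats::sd)
  if (sum(sdv > 0) < 2) stop("fewer than 2 nonconstant signature genes")
  x <- x[sdv > 0, , drop = FALSE]
  genes <- rownames(x)
  z <- t(scale(t(x)))                      # gene-wise z-score
  sv <- svd(t(z))                          # samples x genes
  loadings <- sv$v[, 1:2, drop = FALSE]
  scores <- sv$u[, 1:2, drop = FALSE] %*% diag(sv$d[1:2], 2)
  rownames(loadings) <- genes

  anchor <- intersect(protective_genes %||% character(0), genes)
  sign_flip <- vapply(1:2, function(k) {
    s <- if (length(anchor)) sum(loadings[anchor, k]) else 0
    if (s > 0) 1 else if (s < 0) -1
    else sign(loadings[which.max(abs(loadings[, k])), k])
  }, numeric(1))
  loadings <- sweep(loadings, 2L, sign_flip, "*")
  scores <- sweep(scores, 2L, sign_flip, "*")

  out <- data.frame(sample_id = colnames(m),
                    pc1 = scores[, 1], pc2 = scores[, 2],
                    m6ascore = scores[, 1] + scores[, 2],
                    stringsAsFactors = FALSE, row.names = colnames(m))
  attr(out, "loadings") <- loadings
  attr(out, "orientation_sign") <- sign_flip
  attr(out, "signature_genes") <- genes
  class(out) <- c("score_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dichotomize the m6Ascore at the maximally selected log-rank cutpoint
#'
#' @param st a [compute_m6ascore()] table.
#' @param clinical clinical table matched by `sample_id`.
#' @param minprop minimum group proportion passed to [surv_cutpoint()].
#' @return The score table with `group` (`"HIGH"` iff score > cutpoint) and
#'   `cutpoint` columns added; cutpoint details in attribute `cutpoint_result`.
#' @export
dichotomize_score <- function(st, clinical, minprop = 0.1) {
  common <- intersect(st$sample_id, clinical$sample_id)
  if (!length(common)) stop("no samples shared with clinical table")
  st2 <- st[match(common, st$sample_id), ]
  cl <- clinical[match(common, clinical$sample_id), ]
  cp <- surv_cutpoint(st2$m6ascore, cl$os_time, cl$os_event, minprop = minprop)
  st2$group <- ifelse(st2$m6ascore > cp$cutpoint, "HIGH", "LOW")
  st2$cutpoint <- cp$cutpoint
  attr(st2, "cutpoint_result") <- cp
  attr(st2, "loadings") <- attr(st, "loadings")
  attr(st2, "orientation_sign") <- attr(st, "orientation_sign")
  attr(st2, "signature_genes") <- attr(st, "signature_genes")
  class(st2) <- c("score_table", "data.frame")
  st2
}

#' Correlate the m6Ascore with per-set enrichment scores
#'
#' Spearman correlation of the score against each gene set's per-sample
#' enrichment, BH-adjusted across sets.
#'
#' @param st a score table.
#' @param es an `enrichment_scores` object.
#' @return data.frame `set`, `rho`, `p`, `adj_p`.
#' @export
score_immune_correlation <- function(st, es) {
  common <- intersect(st$sample_id, colnames(es$scores))
  if (length(common) < 4) stop("need at least 4 shared samples")
  sc <- st$m6ascore[match(common, st$sample_id)]
  rows <- lapply(rownames(es$scores), function(s) {
    v <- es$scores[s, common]
    if (all(is.na(v))) return(c(NA_real_, NA_real_))
    r <- correlate(sc, v, method = "SPEARMAN")
    c(r$statistic, r$p)
  })
  out <- data.frame(set = rownames(es$scores),
                    rho = vapply(rows, `[[`, numeric(1), 1L),
                    p = vapply(rows, `[[`, numeric(1), 2L),
                    stringsAsFactors = FALSE)
  out$adj_p <- bh_adjust(out$p)
  out
}
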