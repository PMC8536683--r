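#' Single-sample gene-set enrichment (ssGSEA)
#'
#' For each sample, genes are ranked by expression (descending, average
#' ranks for ties) and the enrichment score of a set is the sum, over all
#' positions of the ranked list, of the difference between the weighted
#' in-set empirical CDF (weights |rank value|^alpha) and the uniform
#' out-of-set ECDF.  Scores are rank-based, hence invariant to any strictly
#' monotone transform of a sample's expression vector.
#'
#' @param m an [expression_matrix()].
#' @param sets named list of gene symbol vectors (`gene_sets`).
#' @param alpha rank-weight exponent (default 0.25, the conventional value).
#' @param normalize divide all scores by the global score range (default TRUE).
#' @return A list of class `enrichment_scores` with `scores` (sets x
#'   samples), `method = "SSGSEA"`, `normalized`.
#' @export
ssgsea <- function(m, sets, alpha = 0.25, normalize = TRUE) {
  if (alpha < 0) stop("alpha must be >= 0")
  x <- unclass(m)
  n_genes <- nrow(x)
  present <- lapply(sets, intersect, rownames(x))
  empty <- names(sets)[lengths(present) == 0L]
  if (length(empty))
    warning("gene set(s) with no member in the matrix, scores set NA: ",
            paste(empty, collapse = ", "))
  scores <- matrix(NA_real_, length(sets), ncol(x),
                   dimnames = list(names(sets), colnames(x)))
  for (j in seq_len(ncol(x))) {
    # rank value: higher expression -> larger rank
    rk <- rank(x[, j], ties.method = "average")
    ord <- order(rk, decreasing = TRUE)        # walk from top-ranked down
    rk_ord <- rk[ord]
    genes_ord <- rownames(x)[ord]
    for (s in seq_along(sets)) {
      memb <- genes_ord %in% present[[s]]
      n_in <- sum(memb)
      if (n_in == 0L) next
      w <- abs(rk_ord)^alpha * memb
      p_in <- cumsum(w) / sum(w)
      p_out <- cumsum(!memb) / (n_genes - n_in)
      scores[s, j] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- range(scores, na.rm = TRUE)
    if (diff(rng) > 0) scores <- scores / diff(rng)
  }
  structure(list(scores = scores, method = "SSGSEA", normalized = normalize),
            class = "enrichment_scores")
}

#' GSVA-style per-sample pathway scores
#'
#' Per gene, the expression ECDF across samples is estimated with a
#' Gaussian kernel (bandwidth = gene sd / 4, floored at 1e-8 for constant
#' genes).  Within each sample the kernel CDF values are converted to ranks
#' and the symmetric rank statistic r = |rank - n_genes/2| drives a KS-like
#' random walk down the CDF-ordered gene list with in-set weight |r|^tau.
#' With `mx_diff` the score is the sum of the maximum positive and maximum
#' negative walk deviations, otherwise the maximum absolute deviation; all
#' scores lie in [-1, 1].
#'
#' @param m an [expression_matrix()] with at least 3 samples.
#' @param sets named list of gene symbol vectors.
#' @param tau rank-weight exponent (default 1).
#' @param mx_diff use max-positive + max-negative deviation (default TRUE).
#' @return An `enrichment_scores` list with `method = "GSVA"`.
#' @export
gsva_scores <- function(m, sets, tau = 1, mx_diff = TRUE) {
  x <- unclass(m)
  n <- ncol(x)
  if (n < 3) stop("GSVA needs at least 3 samples")
  if (tau <= 0) stop("tau must be positive")
  n_genes <- nrow(x)
  # kernel CDF per gene across samples
  z <- matrix(NA_real_, n_genes, n, dimnames = dimnames(x))
  for (i in seq_len(n_genes)) {
    h <- stats::sd(x[i, ]) / 4
    if (h < 1e-8) {
      h <- 1e-8
      warning("constant gene '", rownames(x)[i], "': bandwidth floored")
    }
    z[i, ] <- rowMeans(stats::pnorm(outer(x[i, ], x[i, ], "-") / h))
  }
  scores <- matrix(NA_real_, length(sets), n,
                   dimnames = list(names(sets), colnames(x)))
  present <- lapply(sets, intersect, rownames(x))
  for (j in seq_len(n)) {
    ord <- order(z[, j], decreasing = TRUE)
    rk <- rank(z[, j], ties.method = "average")
    r_stat <- abs(rk - n_genes / 2)[ord]
    genes_ord <- rownames(x)[ord]
    for (s in seq_along(sets)) {
      memb <- genes_ord %in% present[[s]]
      n_in <- sum(memb)
      if (n_in == 0L) { scores[s, j] <- NA_real_; next }
      if (n_in == n_genes) {
        warning("set '", names(sets)[s],
                "' covers every gene; score degenerate, returned 0")
        scores[s, j] <- 0
        next
      }
      w <- r_stat^tau * memb
      walk <- cumsum(w / sum(w) - (!memb) / (n_genes - n_in))
      scores[s, j] <- if (mx_diff) max(c(walk, 0)) + min(c(walk, 0))
                      else walk[which.max(abs(walk))]
    }
  }
  structure(list(scores = scores, method = "GSVA", normalized = FALSE),
            class = "enrichment_scores")
}

#' @export
print.enrichment_scores <- function(x, ...) {
  cat(sprintf("enrichment_scores [%s]: %d sets x %d samples\n",
              x$method, nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Pathway-score contrast between two groups
#'
#' Moderated-t comparison of per-sample gene-set scores between two groups,
#' reported in the standard limma-style table: logFC (difference of group
#' means), AveExpr, moderated t, raw and BH-adjusted p.
#'
#' @param es an `enrichment_scores` object.
#' @param groups per-sample labels aligned to `colnames(es$scores)`.
#' @param pair character vector of two group labels, contrast `pair[1] - pair[2]`.
#' @return data.frame with columns `set`, `logFC`, `AveExpr`, `t`, `p`,
#'   `adj_p`, sorted by `adj_p`.
#' @export
score_group_contrast <- function(es, groups, pair) {
  if (length(pair) != 2) stop("pair must name exactly two groups")
  if (!all(pair %in% groups))
    stop("unknown group label(s): ",
         paste(setdiff(pair, unique(groups)), collapse = ", "))
  keep <- groups %in% pair
  sc <- es$scores[, keep, drop = FALSE]
  ok_rows <- stats::complete.cases(sc)
  if (!all(ok_rows))
    warning(sum(!ok_rows), " set(s) with missing scores dropped from contrast")
  sc <- sc[ok_rows, , drop = FALSE]
  g <- groups[keep]
  scm <- expression_matrix(sc, rownames(sc), colnames(sc), unit = "LOG2")
  tab <- moderated_ttest(scm, g, pair)
  data.frame(set = tab$gene, logFC = tab$logFC, AveExpr = tab$AveExpr,
             t = tab$t, p = tab$p, adj_p = tab$adj_p,
             stringsAsFactors = FALSE)[order(tab$adj_p), ]
}
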