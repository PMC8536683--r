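#' Empirical-Bayes moderated two-sample t-test per gene
#'
#' Per gene the pooled two-group residual variance s_g^2 (d_g degrees of
#' freedom) is shrunk toward a common prior: s~_g^2 = (d0 s0^2 + d_g s_g^2)
#' / (d0 + d_g), with the prior (d0, s0^2) estimated by moment-matching of
#' log s_g^2 against a scaled F distribution (trigamma inversion).  The
#' moderated t = logFC / (s~_g sqrt(1/n1 + 1/n2)) is referred to a t
#' distribution on d0 + d_g df.  Setting `d0 = Inf` (or when the observed
#' variances are underdispersed relative to chi-square sampling noise)
#' recovers the ordinary pooled-variance t-test.
#'
#' @param m an [expression_matrix()].
#' @param groups per-sample labels aligned to columns of `m`.
#' @param pair two group labels; logFC is `mean(pair[1]) - mean(pair[2])`.
#' @param d0 optional override of the prior degrees of freedom.
#' @return data.frame: `gene`, `logFC`, `AveExpr`, `t`, `p`, `adj_p`,
#'   `comparison`, plus attributes `d0` and `s0_sq`.
#' @export
moderated_ttest <- function(m, groups, pair, d0 = NULL) {
  if (length(pair) != 2) stop("pair must name exactly two groups")
  i1 <- which(groups == pair[1]); i2 <- which(groups == pair[2])
  if (length(i1) < 2 || length(i2) < 2)
    stop("both groups need at least 2 samples")
  x <- unclass(m)
  x1 <- x[, i1, drop = FALSE]; x2 <- x[, i2, drop = FALSE]
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  logfc <- m1 - m2
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  dg <- n1 + n2 - 2
  s2 <- ss / dg

  if (is.null(d0)) {
    prior <- fit_f_prior(s2, dg)
    d0 <- prior$d0; s0_sq <- prior$s0_sq
  } else {
    s0_sq <- if (is.finite(d0)) mean(s2) else NA_real_
  }
  s2_tilde <- if (is.finite(d0)) (d0 * s0_sq + dg * s2) / (d0 + dg) else s2
  df_total <- if (is.finite(d0)) d0 + dg else dg
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, logfc / se, 0)
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  p[se == 0 & logfc == 0] <- 1
  out <- data.frame(gene = rownames(x), logFC = logfc,
                    AveExpr = rowMeans(x[, c(i1, i2), drop = FALSE]),
                    t = tstat, p = p, adj_p = bh_adjust(p),
                    comparison = paste(pair, collapse = "_vs_"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  out
}

# Moment-match log(s^2) to log of a scaled F: var(log s2) - trigamma(dg/2)
# = trigamma(d0/2); invert trigamma by Newton.  Underdispersion -> d0 = Inf
# (ordinary t) with a warning.
fit_f_prior <- function(s2, dg) {
  ok <- s2 > 0
  if (sum(ok) < 2) return(list(d0 = Inf, s0_sq = mean(s2)))
  e <- log(s2[ok]) - digamma(dg / 2) + log(dg / 2)
  excess <- stats::var(e) - trigamma(dg / 2)
  if (!is.finite(excess) || excess <= 0) {
    warning("variances underdispersed; falling back to ordinary t (d0 = Inf)")
    return(list(d0 = Inf, s0_sq = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Phenotype-related differentially expressed genes across clusters
#'
#' Runs [moderated_ttest()] for every cluster pair and keeps genes
#' significant (adjusted or raw p below `p_threshold`) in at least one pair
#' (`mode = "UNION"`) or in all pairs (`mode = "INTERSECT"`).
#'
#' @param m an [expression_matrix()].
#' @param cluster_labels per-sample cluster labels.
#' @param p_threshold significance threshold (default 0.05).
#' @param mode `"UNION"` (default) or `"INTERSECT"`.
#' @param use_adjusted filter on BH-adjusted p (default) or raw p.
#' @return list: `genes` (character vector), `tables` (per-pair DEG tables).
#' @export
phenotype_degs <- function(m, cluster_labels, p_threshold = 0.05,
                           mode = c("UNION", "INTERSECT"),
                           use_adjusted = TRUE) {
  mode <- match.arg(mode)
  cl <- sort(unique(as.character(cluster_labels)))
  if (length(cl) < 2) stop("need at least 2 clusters")
  pairs <- utils::combn(cl, 2, simplify = FALSE)
  tables <- lapply(pairs, function(p2)
    moderated_ttest(m, as.character(cluster_labels), p2))
  names(tables) <- vapply(pairs, paste, character(1), collapse = "_vs_")
  sig_sets <- lapply(tables, function(tb) {
    pv <- if (use_adjusted) tb$adj_p else tb$p
    tb$gene[pv < p_threshold]
  })
  genes <- if (mode == "UNION") Reduce(union, sig_sets)
           else Reduce(intersect, sig_sets)
  if (!length(genes)) warning("no gene passed the DEG filter")
  list(genes = genes, tables = tables)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, monotone-enforced and capped at 1.
#'
#' @param p vector of p-values in [0, 1].
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Kruskal-Wallis rank-sum test (wrapper)
#' @param values numeric vector.
#' @param groups group labels (>= 2 nonempty groups).
#' @return list `H` (tie-corrected statistic) and `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  if (length(unique(groups)) < 2) stop("need at least 2 groups")
  kt <- stats::kruskal.test(values, factor(groups))
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' One-way ANOVA (wrapper)
#' @inheritParams kruskal_wallis
#' @return list `F` and `p`.
#' @export
one_way_anova <- function(values, groups) {
  if (length(unique(groups)) < 2) stop("need at least 2 groups")
  fit <- stats::oneway.test(values ~ factor(groups), var.equal = TRUE)
  list(F = unname(fit$statistic), p = fit$p.value)
}

#' Wilcoxon rank-sum test (wrapper)
#' @param a,b numeric vectors.
#' @return list `W` and `p`.
#' @export
wilcoxon_ranksum <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  wt <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  list(W = unname(wt$statistic), p = wt$p.value)
}

#' Spearman or distance correlation
#'
#' Spearman rho with the t-approximation p-value; distance correlation via
#' the double-centered pairwise-distance formula with a seeded permutation
#' p-value.
#'
#' @param x,y numeric vectors, length >= 4.
#' @param method `"SPEARMAN"` or `"DISTANCE"`.
#' @param n_perm permutations for the distance-correlation p (default 999).
#' @param seed permutation seed.
#' @return list `statistic` and `p` (`NA` statistic for constant input).
#' @export
correlate <- function(x, y, method = c("SPEARMAN", "DISTANCE"),
                      n_perm = 999, seed = 1) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4) stop("need at least 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(statistic = NA_real_, p = NA_real_))
  if (method == "SPEARMAN") {
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    rho <- unname(ct$estimate)
    n <- length(x)
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- if (abs(rho) == 1) 0 else 2 * stats::pt(-abs(tstat), df = n - 2)
    return(list(statistic = rho, p = p))
  }
  dc_obs <- distance_correlation(x, y)
  set.seed(seed)
  perm <- replicate(n_perm, distance_correlation(x, sample(y)))
  p <- (1 + sum(perm >= dc_obs)) / (n_perm + 1)
  list(statistic = dc_obs, p = p)
}

distance_correlation <- function(x, y) {
  dcenter <- function(v) {
    d <- as.matrix(stats::dist(v))
    d - outer(rowMeans(d), colMeans(d), "+") + mean(d)
  }
  A <- dcenter(x); B <- dcenter(y)
  dcov2 <- mean(A * B)
  dvar_x <- mean(A * A); dvar_y <- mean(B * B)
  if (dvar_x <= 0 || dvar_y <= 0) return(NA_real_)
  sqrt(max(dcov2, 0)) / (dvar_x * dvar_y)^(1 / 4)
}
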