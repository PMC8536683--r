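#' Resampling-based consensus clustering with delta-area k selection
#'
#' Samples are repeatedly subsampled without replacement, the gene-wise
#' z-scored submatrix is partitioned by the inner clusterer, and
#' co-assignment frequencies are accumulated into a consensus matrix per k.
#' The default inner clusterer is average-linkage hierarchical clustering
#' on 1 - Pearson correlation: because it isolates outlying samples
#' consistently across resamples, the consensus CDF saturates once the true
#' cluster number is reached, which keeps the delta-area criterion sharp
#' (a centroid-splitting inner such as k-means keeps inflating the CDF
#' area beyond the true k by splitting real clusters differently in every
#' resample).  k-means and PAM remain available.
#'
#' Final assignments come from average-linkage hierarchical clustering of
#' 1 - consensus; with `polish = TRUE` (default) they are then refined by a
#' single k-means convergence in the standardized expression space started
#' from the consensus-cluster centroids, which recovers boundary samples
#' that average linkage chains to the wrong branch without affecting the
#' stability curve.
#'
#' The number of clusters is chosen by the relative change in the area
#' under the consensus CDF: the smallest k for which moving to k + 1
#' increases the area by less than `delta_threshold` (parsimony; ties break
#' toward smaller k), else the k with the largest area.
#'
#' @param m an [expression_matrix()].
#' @param panel genes to cluster on (subset of `rownames(m)`).
#' @param k_range candidate cluster numbers, e.g. `2:6`.
#' @param n_resamples number of subsampling iterations (default 1000).
#' @param item_fraction fraction of samples drawn per iteration.
#' @param seed integer seed; the whole procedure is deterministic given it.
#' @param inner `"hclust"` (default), `"kmeans"` or `"pam"`.
#' @param delta_threshold relative CDF-area gain below which adding a
#'   cluster is considered uninformative (default 0.1).
#' @param polish refine final labels by centroid reassignment (default TRUE).
#' @return A list of class `consensus_result`: `k_range`, `consensus` (per-k
#'   sample x sample matrices), `assignments` (per-k integer labels),
#'   `cdf_area`, `delta_area`, `chosen_k`.
#' @export
consensus_cluster <- function(m, panel, k_range = 2:6, n_resamples = 1000,
                              item_fraction = 0.8, seed = 1,
                              inner = c("hclust", "kmeans", "pam"),
                              delta_threshold = 0.1, polish = TRUE) {
  inner <- match.arg(inner)
  missing_genes <- setdiff(panel, rownames(m))
  if (length(missing_genes))
    stop("panel gene(s) absent from matrix: ",
         paste(missing_genes, collapse = ", "))
  if (item_fraction <= 0 || item_fraction > 1)
    stop("item_fraction must be in (0, 1]")
  n <- ncol(m)
  n_sub <- ceiling(item_fraction * n)
  if (max(k_range) >= n_sub) stop("k must be smaller than the subsample size")
  if (min(k_range) < 2) stop("k_range must start at 2 or above")

  # gene standardization on the full cohort (not per resample)
  x <- unclass(m)[panel, , drop = FALSE]
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, stats::sd)
  sdv[sdv == 0] <- 1
  z <- t((x - mu) / sdv)               # samples x genes

  set.seed(seed)
  draws <- replicate(n_resamples, sample.int(n, n_sub), simplify = FALSE)

  sample_ids <- colnames(m)
  consensus <- list()
  assignments <- list()
  co_sampled <- matrix(0, n, n)
  for (d in draws) co_sampled[d, d] <- co_sampled[d, d] + 1

  if (any(co_sampled == 0))
    warning("some sample pairs were never co-sampled; their consensus is 0")

  # the hierarchical inner tree does not depend on k: build once per draw
  trees <- if (inner == "hclust") {
    lapply(draws, function(d) {
      cm <- suppressWarnings(stats::cor(t(z[d, , drop = FALSE])))
      cm[!is.finite(cm)] <- 0
      stats::hclust(stats::as.dist(1 - cm), method = "average")
    })
  } else NULL

  for (k in k_range) {
    co_assigned <- matrix(0, n, n)
    for (i in seq_along(draws)) {
      d <- draws[[i]]
      cl <- switch(inner,
        hclust = stats::cutree(trees[[i]], k = k),
        kmeans = stats::kmeans(z[d, , drop = FALSE], centers = k,
                               nstart = 10, iter.max = 50)$cluster,
        pam = pam_medoids(z[d, , drop = FALSE], k))
      for (g in seq_len(k)) {
        idx <- d[cl == g]
        co_assigned[idx, idx] <- co_assigned[idx, idx] + 1
      }
    }
    cons <- ifelse(co_sampled > 0, co_assigned / pmax(co_sampled, 1), 0)
    diag(cons) <- 1
    dimnames(cons) <- list(sample_ids, sample_ids)
    hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
    asg <- stats::cutree(hc, k = k)
    if (polish) asg <- polish_labels(z, asg, k)
    assignments[[as.character(k)]] <- stats::setNames(asg, sample_ids)
    consensus[[as.character(k)]] <- cons
  }

  cdf_area <- vapply(consensus, consensus_cdf_area, numeric(1))
  names(cdf_area) <- as.character(k_range)
  # delta_area[k] = relative gain in CDF area going from k to k+1
  delta_area <- stats::setNames(rep(NA_real_, length(k_range)),
                                as.character(k_range))
  if (length(k_range) > 1) {
    gain <- diff(cdf_area) / cdf_area[-length(cdf_area)]
    delta_area[seq_along(gain)] <- gain
  }
  below <- which(!is.na(delta_area) & delta_area < delta_threshold)
  chosen_k <- if (length(below)) k_range[min(below)] else k_range[which.max(cdf_area)]

  structure(list(k_range = k_range, consensus = consensus,
                 assignments = assignments, cdf_area = cdf_area,
                 delta_area = delta_area, chosen_k = chosen_k),
            class = "consensus_result")
}

# area under the empirical CDF of the off-diagonal consensus entries,
# integrated over [0, 1]
consensus_cdf_area <- function(cons) {
  v <- cons[upper.tri(cons)]
  sv <- sort(v)
  # integral of ECDF step function: sum over steps of F(x_i) * (x_{i+1}-x_i)
  xs <- c(sv, 1)
  Fs <- seq_along(sv) / length(sv)
  sum(Fs * diff(xs))
}

# one k-means convergence in standardized expression space from the
# consensus-cluster centroids; falls back to the input labels if any
# cluster is empty or centroids coincide
polish_labels <- function(z, asg, k) {
  if (length(unique(asg)) < k) return(asg)
  cents <- t(vapply(sort(unique(asg)),
                    function(g) colMeans(z[asg == g, , drop = FALSE]),
                    numeric(ncol(z))))
  if (anyDuplicated(cents)) return(asg)
  out <- tryCatch(stats::kmeans(z, centers = cents, iter.max = 50)$cluster,
                  error = function(e) asg)
  out
}

# minimal PAM: BUILD + swap phase on Euclidean distances, deterministic
pam_medoids <- function(z, k) {
  dmat <- as.matrix(stats::dist(z))
  n <- nrow(dmat)
  med <- integer(0)
  for (i in seq_len(k)) {
    cost <- vapply(seq_len(n), function(cand) {
      if (cand %in% med) return(Inf)
      sum(do.call(pmin, c(lapply(med, function(m0) dmat[, m0]),
                          list(dmat[, cand]))))
    }, numeric(1))
    med <- c(med, which.min(cost))
  }
  repeat {
    assign_cost <- sum(apply(dmat[, med, drop = FALSE], 1L, min))
    best <- assign_cost; swap <- NULL
    for (mi in seq_along(med)) for (cand in setdiff(seq_len(n), med)) {
      trial <- med; trial[mi] <- cand
      cost <- sum(apply(dmat[, trial, drop = FALSE], 1L, min))
      if (cost < best - 1e-12) { best <- cost; swap <- c(mi, cand) }
    }
    if (is.null(swap)) break
    med[swap[1]] <- swap[2]
  }
  apply(dmat[, med, drop = FALSE], 1L, which.min)
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: k in {%s}, chosen k = %d\n",
              paste(x$k_range, collapse = ","), x$chosen_k))
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same samples;
#' 1 for identical partitions (up to renaming), about 0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return ARI in [-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  tab <- table(a, b)
  n <- length(a)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(tab)
  row_c <- sum_comb(rowSums(tab))
  col_c <- sum_comb(colSums(tab))
  expected <- row_c * col_c / choose(n, 2)
  max_idx <- (row_c + col_c) / 2
  if (max_idx == expected) return(0)
  (idx - expected) / (max_idx - expected)
}
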