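# programmatic fixtures shared across test files

small_cohort <- function(seed = 42, n = 150, ...) {
  generate_cohort(default_cohort_config(n_samples = n, seed = seed, ...))
}

# two well-separated groups on 6 genes (marker profile: half the genes up,
# half down in group 1, shift 6 sd)
blob_matrix <- function(n_per = 20, shift = 6, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per
  vals <- matrix(rnorm(6 * n), 6, n)
  vals[1:3, seq_len(n_per)] <- vals[1:3, seq_len(n_per)] + shift
  vals[4:6, seq_len(n_per)] <- vals[4:6, seq_len(n_per)] - shift
  expression_matrix(vals, paste0("g", 1:6), paste0("s", seq_len(n)),
                    unit = "LOG2")
}

write_tsv_fixture <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# brute-force ssGSEA walk, term by term (independent of the package path)
ssgsea_bruteforce <- function(expr_vec, set_genes, alpha) {
  genes <- names(expr_vec)
  rk <- rank(expr_vec, ties.method = "average")
  ord <- order(rk, decreasing = TRUE)
  es <- 0; p_in <- 0; p_out <- 0
  in_set <- genes[ord] %in% set_genes
  w_total <- sum(abs(rk[ord][in_set])^alpha)
  n_out <- sum(!in_set)
  for (i in seq_along(ord)) {
    if (in_set[i]) p_in <- p_in + abs(rk[ord][i])^alpha / w_total
    else p_out <- p_out + 1 / n_out
    es <- es + (p_in - p_out)
  }
  unname(es)
}

# pair-counting ARI oracle
ari_bruteforce <- function(a, b) {
  n <- length(a)
  s00 <- s11 <- s01 <- s10 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (sa && !sb) s10 <- s10 + 1
    else if (!sa && sb) s01 <- s01 + 1
    else s00 <- s00 + 1
  }
  tot <- choose(n, 2)
  expected <- (s11 + s10) * (s11 + s01) / tot
  maxi <- ((s11 + s10) + (s11 + s01)) / 2
  if (maxi == expected) return(0)
  (s11 - expected) / (maxi - expected)
}

# sorted-definition Benjamini-Hochberg oracle
bh_bruteforce <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  sorted <- p[ord] * n / seq_len(n)
  for (i in seq_len(n)) adj[i] <- min(sorted[i:n], 1)
  out <- numeric(n)
  out[ord] <- adj
  out
}
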