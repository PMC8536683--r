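test_that("PCA coordinates match an independent eigendecomposition", {
  set.seed(1)
  vals <- matrix(rnorm(15 * 12), 15, 12,
                 dimnames = list(paste0("g", 1:15), paste0("s", 1:12)))
  m <- expression_matrix(vals, unit = "LOG2")
  st <- compute_m6ascore(m, rownames(vals))
  # oracle: eigendecomposition of the gene-gene scatter of the z-scored
  # data; sample coordinates are projections onto the top eigenvectors
  z <- t(scale(t(vals)))                       # genes x samples, z-scored
  eg <- eigen(tcrossprod(z), symmetric = TRUE)
  proj <- t(z) %*% eg$vectors[, 1:2]
  for (k in 1:2) {
    a <- st[[c("pc1", "pc2")[k]]]
    expect_equal(abs(a), abs(unname(proj[, k])), tolerance = 1e-8)
  }
  expect_equal(sum(st$m6ascore), 0, tolerance = 1e-8)
  expect_equal(st$m6ascore, st$pc1 + st$pc2)
})

test_that("a rank-1 expression pattern loads entirely on PC1", {
  factor_s <- c(-2, -1, 0, 1, 2, 0)
  load_g <- c(1, 2, 3, 4, 5)
  vals <- outer(load_g, factor_s) + 5
  dimnames(vals) <- list(paste0("g", 1:5), paste0("s", 1:6))
  m <- expression_matrix(vals, unit = "LOG2")
  st <- compute_m6ascore(m, rownames(vals))
  expect_equal(st$pc2, rep(0, 6), tolerance = 1e-8)
  expect_equal(abs(cor(st$m6ascore, factor_s)), 1, tolerance = 1e-8)
})

test_that("score is invariant to gene and sample order and duplicates", {
  set.seed(2)
  vals <- matrix(rnorm(8 * 10), 8, 10,
                 dimnames = list(paste0("g", 1:8), paste0("s", 1:10)))
  m <- expression_matrix(vals, unit = "LOG2")
  st <- compute_m6ascore(m, rownames(vals))
  st_rep <- compute_m6ascore(m, rownames(vals))
  expect_identical(st, st_rep)   # fully deterministic
  gperm <- sample(8)
  st_g <- compute_m6ascore(m, rownames(vals)[gperm])
  expect_equal(st_g$m6ascore, st$m6ascore, tolerance = 1e-8)
  sperm <- sample(10)
  mp <- expression_matrix(vals[, sperm], rownames(vals),
                          colnames(vals)[sperm], unit = "LOG2")
  st_s <- compute_m6ascore(mp, rownames(vals))
  expect_equal(st_s$m6ascore[match(st$sample_id, st_s$sample_id)],
               st$m6ascore, tolerance = 1e-8)
  # duplicating every sample keeps duplicate pairs equal
  md <- expression_matrix(vals[, rep(1:10, 2)], rownames(vals),
                          c(paste0("s", 1:10), paste0("d", 1:10)),
                          unit = "LOG2")
  st_d <- compute_m6ascore(md, rownames(vals))
  expect_equal(st_d$m6ascore[1:10], st_d$m6ascore[11:20], tolerance = 1e-8)
  expect_error(compute_m6ascore(m, c("g1", "nope")), "nope")
})

test_that("prognostic filter recovers planted genes, keeps all at p=1", {
  co <- small_cohort(n = 200)
  planted <- c(co$phenotype_genes$protective, co$phenotype_genes$risk)
  pf <- prognostic_filter(co$expression, planted, co$clinical)
  expect_gte(mean(planted %in% pf$gene), 0.8)
  # protective genes carry negative Cox beta by construction
  prot_dir <- pf$direction[pf$gene %in% co$phenotype_genes$protective]
  expect_gt(mean(prot_dir == "protective"), 0.8)
  pf_all <- prognostic_filter(co$expression, planted, co$clinical,
                              p_threshold = 1.0)
  expect_setequal(pf_all$gene, planted)
})

test_that("orientation anchors high score to the protective direction", {
  co <- small_cohort(n = 200)
  planted <- c(co$phenotype_genes$protective, co$phenotype_genes$risk)
  pf <- prognostic_filter(co$expression, planted, co$clinical)
  st <- compute_m6ascore(co$expression, pf$gene,
                         protective_genes = pf$gene[pf$direction ==
                                                      "protective"])
  mean_by <- tapply(st$m6ascore, co$truth$subtype, mean)
  expect_lt(mean_by["B"], mean_by["A"])
  expect_lt(mean_by["B"], mean_by["C"])
  # and the score tracks the latent prognosis score positively
  expect_gt(cor(st$m6ascore, co$truth$latent_score), 0.3)
})

test_that("dichotomization respects minprop and errors on constant score", {
  co <- small_cohort(n = 150)
  planted <- c(co$phenotype_genes$protective, co$phenotype_genes$risk)
  pf <- prognostic_filter(co$expression, planted, co$clinical)
  st <- compute_m6ascore(co$expression, pf$gene,
                         pf$gene[pf$direction == "protective"])
  grp <- dichotomize_score(st, co$clinical, minprop = 0.1)
  expect_true(all(grp$group %in% c("HIGH", "LOW")))
  expect_gte(min(table(grp$group)), 0.1 * nrow(grp))
  expect_true(all((grp$m6ascore > grp$cutpoint) == (grp$group == "HIGH")))
  st_const <- st
  st_const$m6ascore <- rep(1, nrow(st_const))
  expect_error(dichotomize_score(st_const, co$clinical), "constant")
})

test_that("score-immune correlation finds the planted positive association", {
  co <- small_cohort(n = 150)
  planted <- c(co$phenotype_genes$protective, co$phenotype_genes$risk)
  pf <- prognostic_filter(co$expression, planted, co$clinical)
  st <- compute_m6ascore(co$expression, pf$gene,
                         pf$gene[pf$direction == "protective"])
  es <- ssgsea(co$expression, co$gene_sets$immune)
  tab <- score_immune_correlation(st, es)
  expect_true(all(tab$rho > 0))
  # score correlated with itself as a fake set
  fake <- structure(list(scores = matrix(st$m6ascore, 1,
                                         dimnames = list("self",
                                                         st$sample_id)),
                         method = "SSGSEA", normalized = FALSE),
                    class = "enrichment_scores")
  expect_equal(score_immune_correlation(st, fake)$rho, 1)
})
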