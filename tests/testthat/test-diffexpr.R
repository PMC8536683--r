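test_that("moderated t handles degenerate genes and the d0 = Inf limit", {
  set.seed(1)
  vals <- matrix(rnorm(200), 20, 10,
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  vals[1, ] <- 5  # identical in both groups
  m <- expression_matrix(vals, unit = "LOG2")
  grp <- rep(c("a", "b"), each = 5)
  tab <- moderated_ttest(m, grp, c("a", "b"))
  expect_equal(tab$logFC[1], 0)
  expect_equal(tab$t[1], 0)
  expect_equal(tab$p[1], 1)
  expect_true(all(tab$adj_p >= tab$p - 1e-12))

  # d0 = Inf must reproduce the ordinary pooled-variance t-test
  tab_inf <- moderated_ttest(m, grp, c("a", "b"), d0 = Inf)
  ordinary <- apply(vals[-1, ], 1, function(v)
    stats::t.test(v[1:5], v[6:10], var.equal = TRUE)$statistic)
  expect_equal(tab_inf$t[-1], unname(ordinary), tolerance = 1e-10)
  expect_error(moderated_ttest(m, grp, c("a", "missing")), "2 samples")
})

test_that("moderated t agrees with the limma empirical-Bayes pipeline", {
  skip_if_not_installed("limma")
  set.seed(2)
  vals <- matrix(rnorm(100 * 12), 100, 12,
                 dimnames = list(paste0("g", 1:100), paste0("s", 1:12)))
  vals[1:10, 1:6] <- vals[1:10, 1:6] + 1
  m <- expression_matrix(vals, unit = "LOG2")
  grp <- rep(c("a", "b"), each = 6)
  tab <- moderated_ttest(m, grp, c("a", "b"))
  design <- cbind(1, grp == "a")
  fit <- limma::eBayes(limma::lmFit(vals, design))
  expect_equal(attr(tab, "d0"), fit$df.prior, tolerance = 1e-4)
  expect_equal(attr(tab, "s0_sq"), fit$s2.prior, tolerance = 1e-4)
  expect_equal(tab$t, fit$t[, 2], tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(tab$p, fit$p.value[, 2], tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("moderated t is monotone in |logFC| at fixed variance", {
  n <- 6
  v0 <- rep(c(-1, 1), n / 2)           # same within-group variance per gene
  shift <- c(0.2, 0.5, 1.5)
  vals <- t(vapply(shift, function(s) c(v0 + s, v0), numeric(2 * n)))
  dimnames(vals) <- list(c("lo", "mid", "hi"), paste0("s", 1:(2 * n)))
  m <- expression_matrix(vals, unit = "LOG2")
  tab <- suppressWarnings(
    moderated_ttest(m, rep(c("a", "b"), each = n), c("a", "b")))
  expect_equal(tab$logFC, shift)
  expect_true(all(diff(tab$t[order(abs(tab$logFC))]) > 0))
})

test_that("phenotype DEGs recover planted genes; INTERSECT within UNION", {
  co <- small_cohort(n = 150)
  deg_u <- phenotype_degs(co$expression, co$truth$subtype, mode = "UNION")
  planted <- c(co$phenotype_genes$protective, co$phenotype_genes$risk)
  recall <- mean(planted %in% deg_u$genes)
  expect_gte(recall, 0.9)
  deg_i <- phenotype_degs(co$expression, co$truth$subtype, mode = "INTERSECT")
  expect_true(all(deg_i$genes %in% deg_u$genes))
  expect_warning(
    empty <- phenotype_degs(co$expression, co$truth$subtype, p_threshold = 0),
    "no gene")
  expect_length(empty$genes, 0)
})

test_that("BH adjustment matches the sorted step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.73), 0.73)
  set.seed(3)
  p <- runif(50)
  expect_equal(bh_adjust(p), bh_bruteforce(p), tolerance = 1e-12)
  # order invariance
  ord <- sample(50)
  expect_equal(bh_adjust(p[ord]), bh_adjust(p)[ord])
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("rank tests match direct formula evaluation", {
  # identical groups: no separation
  kw0 <- kruskal_wallis(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(kw0$H, 0, tolerance = 1e-12)
  expect_equal(kw0$p, 1)
  # hand-ranked oracle, no ties: H = 12/(N(N+1)) * sum n_i Rbar_i^2 - 3(N+1)
  v <- 1:9; g <- rep(c("a", "b", "c"), each = 3)
  rk <- rank(v)
  rbar <- tapply(rk, g, mean)
  H_hand <- 12 / (9 * 10) * sum(3 * rbar^2) - 3 * 10
  expect_equal(kruskal_wallis(v, g)$H, unname(H_hand), tolerance = 1e-12)
  # KW is invariant to monotone transforms
  expect_equal(kruskal_wallis(exp(v), g)$H, kruskal_wallis(v, g)$H)
  # two-group ANOVA F equals squared pooled t
  set.seed(4)
  a <- rnorm(8); b <- rnorm(8) + 1
  Fv <- one_way_anova(c(a, b), rep(c("a", "b"), each = 8))$F
  tv <- stats::t.test(a, b, var.equal = TRUE)$statistic
  expect_equal(Fv, unname(tv^2), tolerance = 1e-10)
  expect_error(kruskal_wallis(1:4, rep("a", 4)), "2 groups")
})

test_that("Spearman and distance correlation separate where they should", {
  x <- c(-2, -1, 0, 1, 2)
  expect_equal(correlate(x, x, "SPEARMAN")$statistic, 1)
  quad <- correlate(x, x^2, "SPEARMAN")
  expect_equal(quad$statistic, 0)
  dc <- correlate(x, x^2, "DISTANCE", n_perm = 199, seed = 1)
  expect_gt(dc$statistic, 0.4)
  # dCor statistic against a direct double-centered computation
  set.seed(5)
  a <- rnorm(12); b <- rnorm(12)
  dmat <- function(v) as.matrix(dist(v))
  ctr <- function(d) d - outer(rowMeans(d), colMeans(d), "+") + mean(d)
  A <- ctr(dmat(a)); B <- ctr(dmat(b))
  expected <- sqrt(max(mean(A * B), 0)) / (mean(A * A) * mean(B * B))^0.25
  expect_equal(correlate(a, b, "DISTANCE", n_perm = 9)$statistic, expected,
               tolerance = 1e-12)
  expect_true(is.na(correlate(rep(1, 5), 1:5, "SPEARMAN")$statistic))
})
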