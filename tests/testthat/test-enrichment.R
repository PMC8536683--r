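test_that("ssGSEA ranks a top-gene set above a bottom-gene set", {
  set.seed(1)
  vals <- matrix(rnorm(40), 20, 2,
                 dimnames = list(paste0("g", 1:20), c("s1", "s2")))
  m <- expression_matrix(vals, unit = "LOG2")
  ord <- order(vals[, 1], decreasing = TRUE)
  sets <- list(top = rownames(vals)[ord[1:5]],
               bottom = rownames(vals)[ord[16:20]])
  es <- ssgsea(m, sets, normalize = FALSE)
  expect_gt(es$scores["top", "s1"], es$scores["bottom", "s1"])
})

test_that("ssGSEA equals the term-by-term brute-force walk", {
  set.seed(2)
  v <- rnorm(10)
  names(v) <- paste0("g", 1:10)
  m <- expression_matrix(matrix(v, 10, 1,
                                dimnames = list(names(v), "s1")),
                         unit = "LOG2")
  for (alpha in c(0, 0.25, 1)) {
    sets <- list(S = c("g2", "g5", "g9"))
    es <- ssgsea(m, sets, alpha = alpha, normalize = FALSE)
    expect_equal(es$scores["S", "s1"],
                 ssgsea_bruteforce(v, sets$S, alpha),
                 tolerance = 1e-8)
  }
})

test_that("ssGSEA is rank-based: monotone transforms change nothing", {
  set.seed(3)
  vals <- matrix(rexp(60), 20, 3,
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:3)))
  m <- expression_matrix(vals, unit = "LOG2")
  sets <- list(A = paste0("g", c(1, 4, 7)), B = paste0("g", c(2, 8, 15, 19)))
  es1 <- ssgsea(m, sets, normalize = FALSE)
  m2 <- expression_matrix(log1p(vals) * 3 + 1, rownames(vals),
                          colnames(vals), unit = "LOG2")
  es2 <- ssgsea(m2, sets, normalize = FALSE)
  expect_equal(es1$scores, es2$scores, tolerance = 1e-10)
  # identical expression vectors get identical scores
  m3 <- expression_matrix(vals[, c(1, 1, 2)], rownames(vals),
                          c("a", "b", "c"), unit = "LOG2")
  es3 <- ssgsea(m3, sets, normalize = FALSE)
  expect_equal(es3$scores[, "a"], es3$scores[, "b"])
})

test_that("a set and its complement anticorrelate across samples", {
  co <- small_cohort(n = 60)
  genes <- rownames(co$expression)
  set.seed(4)
  s <- sample(genes, 40)
  sets <- list(set = s, comp = setdiff(genes, s))
  es <- ssgsea(co$expression, sets, normalize = FALSE)
  rho <- correlate(es$scores["set", ], es$scores["comp", ],
                   method = "SPEARMAN")$statistic
  expect_lt(rho, 0)
})

test_that("GSVA scores are bounded and detect a planted group shift", {
  co <- small_cohort(n = 60)
  es <- gsva_scores(co$expression, co$gene_sets$pathways)
  expect_true(all(es$scores >= -1 & es$scores <= 1))
  in_a <- co$truth$subtype == "A"
  expect_gt(mean(es$scores["PATH_IMMUNE_ACT", in_a]),
            mean(es$scores["PATH_IMMUNE_ACT", !in_a]))
  # sample-order invariance
  perm <- sample(ncol(co$expression))
  mp <- expression_matrix(unclass(co$expression)[, perm],
                          rownames(co$expression),
                          colnames(co$expression)[perm], unit = "LOG2")
  esp <- gsva_scores(mp, co$gene_sets$pathways["PATH_NEUTRAL"])
  expect_equal(esp$scores[, colnames(es$scores)],
               es$scores["PATH_NEUTRAL", ], tolerance = 1e-10)
})

test_that("a set covering every gene degenerates to score 0", {
  set.seed(5)
  vals <- matrix(rnorm(30), 10, 3,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:3)))
  m <- expression_matrix(vals, unit = "LOG2")
  expect_warning(es <- gsva_scores(m, list(all = rownames(vals))),
                 "every gene")
  expect_equal(unname(es$scores["all", ]), rep(0, 3))
})

test_that("group contrast reports the limma-style columns and null logFC", {
  co <- small_cohort(n = 80)
  es <- ssgsea(co$expression, co$gene_sets$immune)
  grp <- co$truth$subtype
  tab <- score_group_contrast(es, grp, c("A", "B"))
  expect_named(tab, c("set", "logFC", "AveExpr", "t", "p", "adj_p"))
  # immune sets are planted up in subtype A
  expect_true(all(tab$logFC > 0))
  # same samples in both "groups" gives logFC 0
  dup <- list(scores = cbind(es$scores, es$scores), method = "SSGSEA",
              normalized = TRUE)
  colnames(dup$scores) <- c(paste0(colnames(es$scores), "_x"),
                            paste0(colnames(es$scores), "_y"))
  class(dup) <- "enrichment_scores"
  g2 <- rep(c("p", "q"), each = ncol(es$scores))
  tab2 <- score_group_contrast(dup, g2, c("p", "q"))
  expect_equal(tab2$logFC, rep(0, nrow(tab2)))
  expect_error(score_group_contrast(es, grp, c("A", "Z")), "unknown group")
})

test_that("a planted pathway shift ranks first by adjusted p", {
  hits <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    sc <- matrix(rnorm(20 * 200, 0, 0.1), 20, 200,
                 dimnames = list(paste0("set", 1:20), paste0("s", 1:200)))
    grp <- rep(c("a", "b"), each = 100)
    sc["set7", grp == "a"] <- sc["set7", grp == "a"] + 0.15
    es <- structure(list(scores = sc, method = "GSVA", normalized = FALSE),
                    class = "enrichment_scores")
    tab <- score_group_contrast(es, grp, c("a", "b"))
    tab$set[1] == "set7"
  }, logical(1))
  expect_gte(sum(hits), 9)
})
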