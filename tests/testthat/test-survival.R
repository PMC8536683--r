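test_that("KM estimator matches hand-computed product-limit tables", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  # mixed fixture: times 1,2+,3,4,5+,6 -> S = 5/6, 5/8, 5/12, 0
  km2 <- km_estimate(c(1, 2, 3, 4, 5, 6), c(1, 0, 1, 1, 0, 1))
  expect_equal(km2$times, c(1, 3, 4, 6))
  expect_equal(km2$survival, c(5 / 6, 5 / 8, 5 / 12, 0))
  expect_equal(median_survival(km2), 4)
  # all censored: flat curve, undefined median
  km3 <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_length(km3$times, 0)
  expect_true(is.na(median_survival(km3)))
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(1)
  t <- rexp(40)
  km <- km_estimate(t, rep(1, 40))
  emp <- vapply(km$times, function(tt) mean(t > tt), numeric(1))
  expect_equal(km$survival, emp, tolerance = 1e-12)
})

test_that("log-rank test matches survival::survdiff and is symmetric", {
  skip_if_not_installed("survival")
  set.seed(2)
  t <- rexp(60, rate = c(1, 2))
  e <- rbinom(60, 1, 0.8)
  g <- rep(c("a", "b"), 30)
  lr <- logrank_test(t, e, g)
  sd <- survival::survdiff(survival::Surv(t, e) ~ g)
  expect_equal(lr$chi2, sd$chisq, tolerance = 1e-8)
  expect_equal(lr$df, 1)
  # swapping labels leaves chi2 unchanged
  g2 <- ifelse(g == "a", "b", "a")
  expect_equal(logrank_test(t, e, g2)$chi2, lr$chi2, tolerance = 1e-12)
  # identical duplicated groups: no difference
  lr0 <- logrank_test(rep(t, 2), rep(e, 2), rep(c("x", "y"), each = 60))
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)
  # three-group case against survdiff
  g3 <- rep(c("a", "b", "c"), 20)
  lr3 <- logrank_test(t, e, g3)
  sd3 <- survival::survdiff(survival::Surv(t, e) ~ g3)
  expect_equal(lr3$chi2, sd3$chisq, tolerance = 1e-8)
  expect_equal(lr3$df, 2)
  expect_error(logrank_test(t, e, rep("a", 60)), "2 groups")
})

test_that("log-rank is invariant to monotone time transforms", {
  set.seed(3)
  t <- rexp(50); e <- rbinom(50, 1, 0.7); g <- rep(c("a", "b"), 25)
  expect_equal(logrank_test(t, e, g)$chi2,
               logrank_test(sqrt(t) + 2, e, g)$chi2, tolerance = 1e-10)
})

test_that("Cox fit agrees with survival::coxph (Breslow and Efron)", {
  skip_if_not_installed("survival")
  set.seed(4)
  n <- 200
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
  t <- rexp(n, exp(0.6 * x1 - 0.5 * x2) / 10)
  e <- as.numeric(t < rexp(n, 1 / 15))
  t <- pmin(t, 30)
  t_tied <- round(t, 1)  # induce ties
  X <- cbind(x1 = x1, x2 = x2)
  for (tie in c("breslow", "efron")) {
    fit <- cox_fit(t_tied, e, X, ties = tie)
    ref <- survival::coxph(survival::Surv(t_tied, e) ~ x1 + x2,
                           ties = tie)
    expect_equal(fit$terms$beta, unname(coef(ref)), tolerance = 1e-6)
    expect_equal(fit$terms$se, unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-4)
    expect_true(fit$converged)
  }
  expect_error(cox_fit(t, e, cbind(x1, x1)), "rank-deficient")
  expect_error(cox_fit(t, e, matrix(1, n, 1)), "constant")
})

test_that("Cox recovers a planted log-hazard ratio and is null-calibrated", {
  set.seed(5)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, 0.1 * exp(0.7 * x))
  cens <- runif(n, 0, quantile(t_ev, 0.9) * 1.2)
  t <- pmin(t_ev, cens); e <- as.numeric(t_ev <= cens)
  fit <- cox_fit(t, e, matrix(x, ncol = 1), names = "grp")
  expect_lt(abs(fit$terms$beta[1] - 0.7), 0.15)
  expect_equal(fit$terms$hr[1], exp(fit$terms$beta[1]))
  expect_true(fit$terms$ci_low[1] <= fit$terms$hr[1] &
                fit$terms$hr[1] <= fit$terms$ci_high[1])
  # independent covariate: small beta
  z <- rnorm(500)
  tz <- rexp(500, 0.1); ez <- rbinom(500, 1, 0.7)
  fit0 <- cox_fit(tz, ez, matrix(z, ncol = 1))
  expect_lt(abs(fit0$terms$beta[1]), 0.2)
})

test_that("surv_cutpoint equals the exhaustive per-candidate scan", {
  set.seed(6)
  for (rep in 1:5) {
    n <- 50
    score <- rnorm(n)
    t <- rexp(n, exp(score)); e <- rbinom(n, 1, 0.7)
    if (sum(e) == 0) e[1] <- 1
    cp <- surv_cutpoint(score, t, e, minprop = 0.1)
    # brute force: every feasible midpoint, direct log-rank each
    sv <- sort(unique(score))
    cand <- (sv[-1] + sv[-length(sv)]) / 2
    nlow <- vapply(cand, function(cc) sum(score <= cc), numeric(1))
    cand <- cand[pmin(nlow, n - nlow) >= 0.1 * n]
    zs <- vapply(cand, function(cc) logrank_z(t, e, score > cc), numeric(1))
    best <- which(abs(zs) == max(abs(zs)))[1]
    expect_equal(cp$cutpoint, cand[best], tolerance = 1e-12)
    expect_equal(cp$statistic, zs[best], tolerance = 1e-8)
    expect_equal(cp$scanned$statistic,
                 vapply(cp$scanned$candidate,
                        function(cc) logrank_z(t, e, score > cc), numeric(1)),
                 tolerance = 1e-8)
  }
})

test_that("cutpoint respects minprop and finds a planted hazard split", {
  # minprop 0.49 with 10 distinct values: only the median split remains
  score <- 1:10
  t <- rexp(10); e <- rep(1, 10)
  cp <- surv_cutpoint(score, t, e, minprop = 0.49)
  expect_equal(nrow(cp$scanned), 1)
  expect_equal(cp$cutpoint, 5.5)
  expect_error(surv_cutpoint(rep(1, 10), t, e), "constant")

  # planted two-population hazard structure: the chosen split must agree
  # with the planted one for nearly all samples (the log-rank statistic
  # plateaus around the boundary, so the exact cutpoint may sit a few
  # samples off the gap)
  hits <- vapply(1:10, function(s) {
    set.seed(300 + s)
    n <- 200
    grp <- rep(0:1, each = n / 2)
    score <- grp * 2 + runif(n)  # low half scores in [0,1], high in [2,3]
    t_ev <- rexp(n, 0.1 * exp(-log(4) * grp))  # high score -> HR 1/4
    cens <- runif(n, 0, 40)
    t <- pmin(t_ev, cens); e <- as.numeric(t_ev <= cens)
    cp <- surv_cutpoint(score, t, e)
    mean((score > cp$cutpoint) == (grp == 1)) >= 0.9
  }, logical(1))
  expect_gte(sum(hits), 9)
})
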