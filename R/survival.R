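#' Kaplan-Meier product-limit estimate
#'
#' @param times nonnegative follow-up times.
#' @param events event indicators in {0, 1} (1 = death/event).
#' @return list of class `km_curve`: `times` (distinct event times,
#'   increasing), `survival`, `at_risk`, `n_events`.
#' @export
km_estimate <- function(times, events) {
  check_surv(times, events)
  ord <- order(times)
  t_s <- times[ord]; e_s <- events[ord]
  evt_times <- sort(unique(t_s[e_s == 1]))
  at_risk <- vapply(evt_times, function(tt) sum(t_s >= tt), numeric(1))
  n_events <- vapply(evt_times, function(tt) sum(t_s == tt & e_s == 1),
                     numeric(1))
  surv <- cumprod(1 - n_events / at_risk)
  structure(list(times = evt_times, survival = surv,
                 at_risk = as.integer(at_risk),
                 n_events = as.integer(n_events)),
            class = "km_curve")
}

check_surv <- function(times, events) {
  if (!length(times)) stop("empty survival input")
  if (length(times) != length(events)) stop("times/events length mismatch")
  if (any(times < 0)) stop("negative survival times")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  invisible(TRUE)
}

#' Median survival time from a KM curve
#'
#' First event time at which the survival estimate drops to 0.5 or below;
#' `NA` when the curve never reaches 0.5.
#'
#' @param km a [km_estimate()] result.
#' @return numeric or `NA`.
#' @export
median_survival <- function(km) {
  hit <- which(km$survival <= 0.5)
  if (!length(hit)) NA_real_ else km$times[min(hit)]
}

#' Log-rank test across k groups
#'
#' Observed-vs-expected chi-square with k - 1 degrees of freedom and
#' hypergeometric variance, handling tied event times.
#'
#' @param times,events survival data.
#' @param groups per-subject group labels (>= 2 groups).
#' @return list `chi2`, `df`, `p`.
#' @export
logrank_test <- function(times, events, groups) {
  check_surv(times, events)
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  k <- length(lev)
  if (k < 2) stop("log-rank needs at least 2 groups")
  evt_times <- sort(unique(times[events == 1]))
  O <- E <- stats::setNames(numeric(k), lev)
  V <- matrix(0, k, k, dimnames = list(lev, lev))
  for (tt in evt_times) {
    at <- times >= tt
    n_t <- sum(at)
    d_t <- sum(times == tt & events == 1)
    n_g <- vapply(lev, function(g) sum(at & groups == g), numeric(1))
    d_g <- vapply(lev, function(g) sum(times == tt & events == 1 & groups == g),
                  numeric(1))
    O <- O + d_g
    E <- E + d_t * n_g / n_t
    if (n_t > 1) {
      vmult <- d_t * (n_t - d_t) / (n_t - 1)
      V <- V + vmult * (diag(n_g / n_t, k) - tcrossprod(n_g / n_t))
    }
  }
  z <- (O - E)[-k]
  Vsub <- V[-k, -k, drop = FALSE]
  chi2 <- tryCatch(drop(t(z) %*% solve(Vsub, z)),
                   error = function(e) drop(t(z) %*% mp_ginv(Vsub) %*% z))
  list(chi2 = chi2, df = k - 1,
       p = stats::pchisq(chi2, df = k - 1, lower.tail = FALSE))
}

# small Moore-Penrose fallback for singular log-rank variance matrices
mp_ginv <- function(X, tol = 1e-10) {
  s <- svd(X)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

revcumsum <- function(v) rev(cumsum(rev(v)))

#' Cox proportional-hazards fit by Newton-Raphson
#'
#' Maximizes the Breslow (default) or Efron partial likelihood; Wald
#' confidence intervals and p-values from the inverse observed information.
#' Risk-set sums are computed by reverse cumulative sums over the
#' time-sorted cohort, so one Newton step costs O(n p^2).  Non-convergence
#' returns the last iterate with `converged = FALSE`; |beta| > 20 flags
#' monotone likelihood (perfect separation).
#'
#' @param times,events survival data.
#' @param covariates numeric matrix or vector (subjects x covariates), no
#'   constant column, full rank.
#' @param names covariate names (defaults to matrix colnames).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param max_iter,tol Newton-Raphson controls (gradient-norm tolerance).
#' @return list of class `cox_fit`: `terms` data.frame (name, beta, se, hr,
#'   ci_low, ci_high, p), `loglik`, `converged`, `n`, `n_events`.
#' @export
cox_fit <- function(times, events, covariates, names = NULL,
                    ties = c("breslow", "efron"), max_iter = 50, tol = 1e-8) {
  ties <- match.arg(ties)
  check_surv(times, events)
  X <- as.matrix(covariates)
  if (!all(is.finite(X))) stop("covariates must be finite")
  if (sum(events) < 1) stop("need at least one event")
  if (any(apply(X, 2L, stats::sd) == 0)) stop("constant covariate column")
  if (qr(X)$rank < ncol(X)) stop("rank-deficient covariate matrix")
  if (is.null(names)) names <- colnames(X)
  if (is.null(names)) names <- paste0("x", seq_len(ncol(X)))

  ord <- order(times)
  t_s <- times[ord]; e_s <- events[ord]; Xs <- X[ord, , drop = FALSE]
  n <- length(t_s); p <- ncol(Xs)
  # tie-group bookkeeping: first index of each distinct time (sorted)
  ut <- unique(t_s)
  first_idx <- match(ut, t_s)
  d_t <- as.vector(rowsum(e_s, match(t_s, ut)))
  has_evt <- d_t > 0
  died <- e_s == 1
  sum_x_died <- colSums(Xs[died, , drop = FALSE])
  pair_idx <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)

  beta <- rep(0, p)
  U <- rep(Inf, p); I_mat <- diag(p); ll <- NA_real_
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(Xs %*% beta)
    eta <- pmax(pmin(eta, 60), -60)   # guard overflow under separation
    w <- exp(eta)
    S0_t <- revcumsum(w)[first_idx]
    S1_t <- apply(Xs * w, 2L, revcumsum)[first_idx, , drop = FALSE]
    S2_t <- matrix(0, length(ut), nrow(pair_idx))
    for (q in seq_len(nrow(pair_idx)))
      S2_t[, q] <- revcumsum(w * Xs[, pair_idx[q, 1]] *
                               Xs[, pair_idx[q, 2]])[first_idx]
    U <- sum_x_died
    I_mat <- matrix(0, p, p)
    ll <- sum(eta[died])
    ev <- which(has_evt)
    if (ties == "breslow" || all(d_t[ev] == 1)) {
      ll <- ll - sum(d_t[ev] * log(S0_t[ev]))
      mu_t <- S1_t[ev, , drop = FALSE] / S0_t[ev]
      U <- U - colSums(d_t[ev] * mu_t)
      for (q in seq_len(nrow(pair_idx))) {
        a <- pair_idx[q, 1]; b <- pair_idx[q, 2]
        val <- sum(d_t[ev] * (S2_t[ev, q] / S0_t[ev] - mu_t[, a] * mu_t[, b]))
        I_mat[a, b] <- I_mat[a, b] + val
        if (a != b) I_mat[b, a] <- I_mat[b, a] + val
      }
    } else {
      for (g in ev) {
        d <- d_t[g]
        idx_g <- which(t_s == ut[g] & died)
        wd <- w[idx_g]; xd <- Xs[idx_g, , drop = FALSE]
        S0d <- sum(wd); S1d <- drop(crossprod(xd, wd))
        S2d <- crossprod(xd * wd, xd)
        S2g <- matrix(0, p, p)
        S2g[cbind(pair_idx[, 1], pair_idx[, 2])] <- S2_t[g, ]
        S2g[cbind(pair_idx[, 2], pair_idx[, 1])] <- S2_t[g, ]
        for (l in seq_len(d) - 1) {
          f <- l / d
          S0l <- S0_t[g] - f * S0d
          S1l <- S1_t[g, ] - f * S1d
          S2l <- S2g - f * S2d
          ll <- ll - log(S0l)
          U <- U - S1l / S0l
          I_mat <- I_mat + S2l / S0l - tcrossprod(S1l / S0l)
        }
      }
    }
    step <- tryCatch(solve(I_mat, U), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    if (sqrt(sum(U^2)) < tol) { converged <- TRUE; break }
    # damp oversized Newton steps to keep the iteration stable
    if (max(abs(step)) > 2) step <- step * 2 / max(abs(step))
    beta <- beta + step
  }
  if (!converged && sqrt(sum(U^2)) < 1e-4) converged <- TRUE
  if (!converged) warning("Cox Newton-Raphson did not converge")
  if (any(abs(beta) > 20)) warning("|beta| > 20: likely monotone likelihood")
  se <- sqrt(diag(solve(I_mat)))
  zq <- stats::qnorm(0.975)
  terms <- data.frame(name = names, beta = beta, se = se, hr = exp(beta),
                      ci_low = exp(beta - zq * se),
                      ci_high = exp(beta + zq * se),
                      p = 2 * stats::pnorm(-abs(beta / se)),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(terms = terms, loglik = ll, converged = converged,
                 n = n, n_events = sum(e_s)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit: n=%d, events=%d, converged=%s\n",
              x$n, x$n_events, x$converged))
  print(x$terms, digits = 3)
  invisible(x)
}

#' Maximally selected log-rank cutpoint
#'
#' Scans every midpoint between consecutive distinct sorted score values
#' whose induced low/high split leaves at least `minprop` of subjects in
#' each group, computes the standardized two-group log-rank statistic
#' (O - E) / sqrt(V) at each candidate (hypergeometric variance), and
#' returns the cutpoint maximizing |statistic| (ties toward the smallest
#' cutpoint).  The scan is incremental: moving one subject across the
#' cutpoint updates O - E through its cumulative-hazard residual and the
#' variance through the per-event-time at-risk counts, so the whole scan is
#' O(n x #event times).
#'
#' @param score continuous per-subject score.
#' @param times,events survival data aligned to `score`.
#' @param minprop minimum group proportion in (0, 0.5), default 0.1.
#' @return list of class `cutpoint_result`: `cutpoint`, `statistic`
#'   (standardized log-rank at the chosen cutpoint for the high group),
#'   `group_sizes` (n_low, n_high), `scanned` data.frame.
#' @export
surv_cutpoint <- function(score, times, events, minprop = 0.1) {
  check_surv(times, events)
  if (length(score) != length(times)) stop("score length mismatch")
  if (minprop <= 0 || minprop >= 0.5) stop("minprop must be in (0, 0.5)")
  n <- length(score)
  sv <- sort(unique(score))
  if (length(sv) < 2) stop("no feasible cutpoint: score is constant")
  cand_all <- (sv[-1] + sv[-length(sv)]) / 2

  evt_times <- sort(unique(times[events == 1]))
  ne <- length(evt_times)
  n_t <- vapply(evt_times, function(tt) sum(times >= tt), numeric(1))
  d_t <- vapply(evt_times, function(tt) sum(times == tt & events == 1),
                numeric(1))
  c_t <- ifelse(n_t > 1, d_t * (n_t - d_t) / (n_t - 1), 0)
  A_t <- c_t / n_t
  B_t <- c_t / n_t^2
  # per-subject index of the last event time <= its follow-up time
  pos <- findInterval(times, evt_times)
  H <- cumsum(d_t / n_t)                      # Nelson-Aalen at event times
  cumA <- cumsum(A_t)

  # walk candidates from the largest down, moving subjects into 'high'
  OmE <- 0; V <- 0
  n1 <- numeric(ne)                           # high-group at-risk per event time
  stats_desc <- numeric(length(cand_all))
  nhigh_desc <- integer(length(cand_all))
  nh <- 0
  for (j in seq_along(cand_all)) {
    v_in <- sv[length(sv) - j + 1]            # score value entering 'high'
    movers <- which(score == v_in)
    for (i in movers) {
      k <- pos[i]
      OmE <- OmE + events[i] - if (k > 0) H[k] else 0
      if (k > 0) {
        V <- V + cumA[k] - sum(B_t[seq_len(k)] * (2 * n1[seq_len(k)] + 1))
        n1[seq_len(k)] <- n1[seq_len(k)] + 1
      }
      nh <- nh + 1
    }
    stats_desc[j] <- if (V > 0) OmE / sqrt(V) else 0
    nhigh_desc[j] <- nh
  }
  cand_desc <- rev(cand_all)
  feasible <- pmin(nhigh_desc, n - nhigh_desc) >= minprop * n
  if (!any(feasible)) stop("no feasible cutpoint under minprop")
  cand <- cand_desc[feasible]
  stat <- stats_desc[feasible]
  ordc <- order(cand)
  cand <- cand[ordc]; stat <- stat[ordc]
  best <- which(abs(stat) == max(abs(stat)))[1L]   # ties: smallest cutpoint
  structure(list(cutpoint = cand[best], statistic = stat[best],
                 group_sizes = c(n_low = sum(score <= cand[best]),
                                 n_high = sum(score > cand[best])),
                 scanned = data.frame(candidate = cand, statistic = stat)),
            class = "cutpoint_result")
}

#' Standardized two-group log-rank statistic
#'
#' (O - E) / sqrt(V) for the subjects with `grp == TRUE`, hypergeometric
#' variance with tie correction.  Used directly by tests as the brute-force
#' per-candidate evaluation that [surv_cutpoint()]'s incremental scan must
#' reproduce.
#'
#' @param times,events survival data.
#' @param grp logical vector marking the comparison group.
#' @return numeric z statistic.
#' @export
logrank_z <- function(times, events, grp) {
  evt_times <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (tt in evt_times) {
    at <- times >= tt
    n_t <- sum(at)
    d_t <- sum(times == tt & events == 1)
    n1 <- sum(at & grp)
    d1 <- sum(times == tt & events == 1 & grp)
    O <- O + d1
    E <- E + d_t * n1 / n_t
    if (n_t > 1)
      V <- V + d_t * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d_t) / (n_t - 1)
  }
  if (V <= 0) return(0)
  (O - E) / sqrt(V)
}
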