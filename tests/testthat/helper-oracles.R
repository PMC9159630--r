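## Independent oracles used across the test suite.  These deliberately
## re-derive quantities through different routes (direct enumeration,
## stats::fisher.test / chisq.test, metafor, plain GLS, brute-force search)
## than the package's implementations.

## Two-sided Fisher p by direct enumeration of all tables with the observed
## margins, using binomial coefficients only.
oracle_fisher_p <- function(e0, n0, e1, n1) {
  t <- e0 + e1
  if (t == 0 || t == n0 + n1) return(1)
  xs <- max(0, t - n0):min(n1, t)
  pr <- choose(n1, xs) * choose(n0, t - xs) / choose(n0 + n1, t)
  sum(pr[pr <= pr[xs == e1] * (1 + 1e-7)])
}

## p-value via the stock stats tests / hand-written Wald formulas.
oracle_p <- function(e0, n0, e1, n1, method, yates = TRUE) {
  m <- matrix(c(e0, n0 - e0, e1, n1 - e1), 2, byrow = TRUE)
  if (method == "fisher") return(stats::fisher.test(m)$p.value)
  if (method == "chisq")
    return(suppressWarnings(stats::chisq.test(m, correct = yates)$p.value))
  if (e0 == 0 || e0 == n0 || e1 == 0 || e1 == n1) {
    e0 <- e0 + 0.5; e1 <- e1 + 0.5; n0 <- n0 + 1; n1 <- n1 + 1
  }
  if (method == "OR") {
    y <- log((e1 / (n1 - e1)) / (e0 / (n0 - e0)))
    s <- sqrt(1 / e0 + 1 / (n0 - e0) + 1 / e1 + 1 / (n1 - e1))
  } else if (method == "RR") {
    y <- log((e1 / n1) / (e0 / n0))
    s <- sqrt(1 / e0 + 1 / e1 - 1 / n0 - 1 / n1)
  } else {
    y <- e1 / n1 - e0 / n0
    s <- sqrt(e0 * (n0 - e0) / n0^3 + e1 * (n1 - e1) / n1^3)
  }
  2 * stats::pnorm(-abs(y) / s)
}

## Brute-force FI over the full modification landscape with oracle p-values.
oracle_fi_enum <- function(e0, n0, e1, n1, method, alpha, yates = TRUE) {
  g <- expand.grid(f0 = -e0:(n0 - e0), f1 = -e1:(n1 - e1))
  p <- mapply(function(f0, f1) oracle_p(e0 + f0, n0, e1 + f1, n1, method,
                                        yates),
              g$f0, g$f1)
  p0 <- p[g$f0 == 0 & g$f1 == 0]
  flip <- if (p0 < alpha) p >= alpha else p < alpha
  d <- abs(g$f0) + abs(g$f1)
  flip <- flip & d > 0
  if (!any(flip)) return(list(FI = NA_integer_, mods = NULL, p0 = p0))
  FI <- min(d[flip])
  sel <- which(flip & d == FI)
  sel <- sel[order(g$f0[sel], g$f1[sel])]
  list(FI = FI, mods = cbind(f0 = g$f0[sel], f1 = g$f1[sel]), p0 = p0)
}

## Random 2x2 table with at least one subject per arm.
rand_table <- function(max_n = 30) {
  n0 <- sample(2:max_n, 1); n1 <- sample(2:max_n, 1)
  list(e0 = sample(0:n0, 1), n0 = n0, e1 = sample(0:n1, 1), n1 = n1)
}

## Independent DL random-effects fit with z CI (plain formulas, including
## the per-study continuity correction), for the brute-force MA searches.
oracle_ma_ci <- function(e0, n0, e1, n1, alpha = 0.05) {
  z <- e0 == 0 | e0 == n0 | e1 == 0 | e1 == n1
  a0 <- e0 + 0.5 * z; m0 <- n0 + z; a1 <- e1 + 0.5 * z; m1 <- n1 + z
  y <- log((a1 / (m1 - a1)) / (a0 / (m0 - a0)))
  v <- 1 / a0 + 1 / (m0 - a0) + 1 / a1 + 1 / (m1 - a1)
  N <- length(y)
  tau2 <- 0
  if (N > 1) {
    w <- 1 / v
    th <- sum(w * y) / sum(w)
    Q <- sum(w * (y - th)^2)
    tau2 <- max(0, (Q - (N - 1)) / (sum(w) - sum(w^2) / sum(w)))
  }
  w <- 1 / (v + tau2)
  th <- sum(w * y) / sum(w)
  se <- 1 / sqrt(sum(w))
  c(th, th - qnorm(1 - alpha / 2) * se, th + qnorm(1 - alpha / 2) * se)
}

oracle_ma_sig <- function(e0, n0, e1, n1, alpha = 0.05) {
  ci <- oracle_ma_ci(e0, n0, e1, n1, alpha)
  ci[2] > 0 || ci[3] < 0
}

## All signed modification vectors over `arms` cells with total L1 size d,
## respecting per-cell bounds [lo, hi]; applied recursively.
.delta_vectors <- function(d, lo, hi) {
  k <- length(lo)
  if (k == 1) {
    out <- intersect(c(-d, d), lo[1]:hi[1])
    return(lapply(unique(out), function(v) v))
  }
  res <- list()
  for (v in max(-d, lo[1]):min(d, hi[1])) {
    rest <- .delta_vectors(d - abs(v), lo[-1], hi[-1])
    for (r in rest) res[[length(res) + 1]] <- c(v, r)
  }
  res
}

## Minimal number of single-event modifications that flips the significance
## of a DL z-interval meta-analysis, by exhaustive search of increasing
## total modification size (the true optimum the greedy algorithm bounds).
oracle_ma_min_fi <- function(e0, n0, e1, n1, alpha = 0.05, dmax = 6) {
  sig0 <- oracle_ma_sig(e0, n0, e1, n1, alpha)
  lo <- c(-e0, -e1); hi <- c(n0 - e0, n1 - e1)
  N <- length(e0)
  for (d in seq_len(dmax)) {
    for (v in .delta_vectors(d, lo, hi)) {
      de0 <- v[seq_len(N)]; de1 <- v[N + seq_len(N)]
      if (oracle_ma_sig(e0 + de0, n0, e1 + de1, n1, alpha) != sig0)
        return(d)
    }
  }
  NA_integer_
}

## Independent network meta-analysis: per-study baseline-contrast GLS with
## explicit block covariance matrices and a reference treatment, solved by
## ordinary matrix algebra (no graph construction).
oracle_nma_gls <- function(d, tau2 = 0, measure = "OR") {
  trts <- sort(unique(d$tid)); K <- length(trts)
  ys <- c(); Xs <- list(); blocks <- list()
  for (s in unique(d$sid)) {
    sub <- d[d$sid == s, ]
    e <- sub$e; n <- sub$n
    if (any(e == 0 | e == n)) { e <- e + 0.5; n <- n + 1 }
    if (measure == "OR") { g <- log(e / (n - e)); u <- 1 / e + 1 / (n - e) }
    else if (measure == "RR") { g <- log(e / n); u <- 1 / e - 1 / n }
    else { g <- e / n; u <- e * (n - e) / n^3 }
    p <- nrow(sub)
    X <- matrix(0, p - 1, K - 1)
    idx <- match(sub$tid, trts)
    for (j in 2:p) {
      if (idx[j] > 1) X[j - 1, idx[j] - 1] <- 1
      if (idx[1] > 1) X[j - 1, idx[1] - 1] <- -1
    }
    S <- matrix(u[1], p - 1, p - 1); diag(S) <- u[1] + u[-1]
    if (tau2 > 0) { D <- matrix(tau2 / 2, p - 1, p - 1); diag(D) <- tau2
                    S <- S + D }
    ys <- c(ys, g[-1] - g[1])
    Xs[[length(Xs) + 1]] <- X
    blocks[[length(blocks) + 1]] <- S
  }
  X <- do.call(rbind, Xs)
  W <- matrix(0, length(ys), length(ys)); at <- 0
  for (b in blocks) {
    i <- at + seq_len(nrow(b)); W[i, i] <- solve(b); at <- at + nrow(b)
  }
  V <- solve(t(X) %*% W %*% X)
  beta <- drop(V %*% t(X) %*% W %*% ys)
  ## expand to all-pairs matrices (treatment k vs treatment 1 = beta[k-1])
  mu <- c(0, beta)
  Vfull <- matrix(0, K, K)
  Vfull[-1, -1] <- V
  est <- outer(mu, mu, "-")
  se <- sqrt(pmax(outer(diag(Vfull), diag(Vfull), "+") - 2 * Vfull, 0))
  dimnames(est) <- dimnames(se) <- list(trts, trts)
  list(est = est, se = se)
}

## Random connected network dataset without zero cells (for exact
## cross-route comparisons).
rand_nma <- function(K = 3, n_studies = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- gen_nma(K, n_studies, theta = c(0, runif(K - 1, -0.8, 0.8)),
               tau2 = 0.05, p_multi = 0.3, n_range = c(50, 150),
               p0_range = c(0.2, 0.5), seed = NULL)
  d$e <- pmin(pmax(d$e, 1), d$n - 1)   # keep cells positive
  d
}
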