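## Frequentist contrast-based network meta-analysis by the graph-theoretical
## (weighted least squares) method: per-study contrasts with multi-arm
## variance adjustment, a single shared between-study variance estimated by
## the generalised method of moments, and normal confidence intervals for
## all pairwise comparisons.

## Validate long-format arm data and split into studies.
.nma_check <- function(sid, tid, e, n) {
  stopifnot(length(sid) >= 2, length(tid) == length(sid),
            length(e) == length(sid), length(n) == length(sid))
  if (any(sid != round(sid) | sid < 1) || any(tid != round(tid) | tid < 1))
    stop("study and treatment ids must be natural numbers starting from 1")
  bad <- which(e < 0 | e > n | e != round(e) | n < 1 | n != round(n))
  if (length(bad))
    stop("invalid event count or sample size in row(s) ",
         paste(bad, collapse = ", "))
  for (s in unique(sid)) {
    t_s <- tid[sid == s]
    if (length(t_s) < 2) stop("study ", s, " has fewer than two arms")
    if (anyDuplicated(t_s)) stop("study ", s, " has duplicated treatments")
  }
  trts <- sort(unique(tid))
  ## connectivity of the treatment network
  comp <- stats::setNames(seq_along(trts), trts)
  for (s in unique(sid)) {
    t_s <- as.character(tid[sid == s])
    tgt <- min(comp[t_s])
    comp[comp %in% comp[t_s]] <- tgt
  }
  if (length(unique(comp)) > 1) {
    parts <- split(names(comp), comp)
    stop("treatment network is disconnected; components: ",
         paste(vapply(parts, paste, "", collapse = ","), collapse = " | "))
  }
  trts
}

## Per-arm contributions to contrasts: y_ab = g_a - g_b with
## Var(y_ab) = u_a + u_b for all three measures, which makes the multi-arm
## covariance structure explicit (shared-arm covariance u of the common arm).
.nma_arm_components <- function(e, n, measure) {
  if (measure == "OR") list(g = log(e / (n - e)), u = 1 / e + 1 / (n - e))
  else if (measure == "RR") list(g = log(e / n), u = 1 / e - 1 / n)
  else list(g = e / n, u = e * (n - e) / n^3)
}

## Continuity handling mirroring the usual arm-level conventions:
## by default `incr` is added to the cells (e and n - e) of every arm of a
## study that contains a zero cell; `allincr` extends this to all studies as
## soon as one study needs it; `addincr` always adds it.  For OR and RR,
## studies providing no information (all arms with zero events, or all arms
## with zero non-events) are dropped unless `allstudies = TRUE`.
.nma_prep <- function(sid, tid, e, n, measure, incr = 0.5, allincr = FALSE,
                      addincr = FALSE, allstudies = FALSE) {
  trts <- .nma_check(sid, tid, e, n)
  sids <- unique(sid)
  zero_arm <- e == 0 | e == n
  zero_study <- vapply(sids, function(s) any(zero_arm[sid == s]), logical(1))
  corr <- if (addincr) rep(TRUE, length(sids))
          else if (allincr && any(zero_study)) rep(TRUE, length(sids))
          else zero_study
  drop <- rep(FALSE, length(sids))
  if (!allstudies && measure %in% c("OR", "RR"))
    drop <- vapply(sids, function(s)
      all(e[sid == s] == 0) || all(e[sid == s] == n[sid == s]), logical(1))
  studies <- list()
  for (k in seq_along(sids)) {
    if (drop[k]) next
    sel <- sid == sids[k]
    ek <- e[sel]; nk <- n[sel]
    if (corr[k]) { ek <- ek + incr; nk <- nk + 2 * incr }
    cmp <- .nma_arm_components(ek, nk, measure)
    studies[[length(studies) + 1L]] <-
      list(sid = sids[k], tid = tid[sel], g = cmp$g, u = cmp$u)
  }
  if (!length(studies)) stop("no informative studies left after exclusions")
  list(studies = studies, trts = trts, K = length(trts),
       dropped = sids[drop])
}

## Generalised method-of-moments (DerSimonian-Laird type) estimate of the
## shared between-study variance, from the stacked per-study baseline
## contrasts: tau2 = max(0, (Q - df) / tr(P Delta)).
.nma_tau2 <- function(prep) {
  K <- prep$K
  ys <- list(); Xs <- list(); Sig <- list(); Del <- list()
  for (st in prep$studies) {
    p <- length(st$tid)
    y <- st$g[-1] - st$g[1]
    idx <- match(st$tid, prep$trts)
    X <- matrix(0, p - 1, K - 1)
    for (j in 2:p) {
      if (idx[j] > 1) X[j - 1, idx[j] - 1] <- 1
      if (idx[1] > 1) X[j - 1, idx[1] - 1] <- -1
    }
    S <- matrix(st$u[1], p - 1, p - 1)
    diag(S) <- st$u[1] + st$u[-1]
    D <- matrix(0.5, p - 1, p - 1); diag(D) <- 1
    ys[[length(ys) + 1]] <- y; Xs[[length(Xs) + 1]] <- X
    Sig[[length(Sig) + 1]] <- S; Del[[length(Del) + 1]] <- D
  }
  y <- unlist(ys)
  X <- do.call(rbind, Xs)
  M <- length(y)
  W <- matrix(0, M, M); Delta <- matrix(0, M, M)
  at <- 0L
  for (k in seq_along(Sig)) {
    idx <- at + seq_len(nrow(Sig[[k]]))
    W[idx, idx] <- solve(Sig[[k]])
    Delta[idx, idx] <- Del[[k]]
    at <- at + length(idx)
  }
  XtWX <- crossprod(X, W %*% X)
  df <- M - qr(X)$rank
  beta <- solve(XtWX, crossprod(X, W %*% y))
  r <- y - X %*% beta
  Q <- drop(crossprod(r, W %*% r))
  P <- W - W %*% X %*% solve(XtWX, t(X) %*% W)
  C <- sum(P * Delta)   # tr(P Delta), both symmetric
  list(tau2 = max(0, (Q - df) / C), Q = Q, df = df)
}

## Solve the network at a given tau2 via the graph route: each study
## contributes edge weights w_ab = -L_s[a, b], where L_s is the study's
## information Laplacian (inverse of the baseline-contrast covariance
## expanded to arm space); the multi-arm adjustment is exactly this
## expansion.  Relative treatment effects come from the Moore-Penrose
## inverse of the network Laplacian.
.nma_solve <- function(prep, tau2 = 0) {
  K <- prep$K
  L <- matrix(0, K, K)
  rhs <- numeric(K)
  for (st in prep$studies) {
    p <- length(st$tid)
    S <- matrix(st$u[1], p - 1, p - 1)
    diag(S) <- st$u[1] + st$u[-1]
    if (tau2 > 0) {
      D <- matrix(tau2 / 2, p - 1, p - 1); diag(D) <- tau2
      S <- S + D
    }
    Kmat <- solve(S)
    B <- cbind(-1, diag(1, p - 1))      # baseline contrasts in arm space
    Ls <- t(B) %*% Kmat %*% B           # study information Laplacian
    idx <- match(st$tid, prep$trts)
    L[idx, idx] <- L[idx, idx] + Ls
    ## normal-equation contribution: t(B) K y with y the baseline contrasts
    yb <- st$g[-1] - st$g[1]
    rhs[idx] <- rhs[idx] + drop(t(B) %*% (Kmat %*% yb))
  }
  J <- matrix(1 / K, K, K)
  V <- solve(L + J) - J                  # Moore-Penrose inverse of L
  mu <- drop(V %*% rhs)
  list(mu = mu, V = V)
}

#' Per-study pairwise contrasts with multi-arm adjusted variances
#'
#' Expands each study into all within-study pairwise treatment contrasts
#' (effect of the first-listed vs. the second-listed treatment).  For
#' studies with more than two arms, the naive contrast variances overstate
#' the information; the adjusted variances are derived from the study's
#' information Laplacian so that weighted least squares over the redundant
#' contrasts carries exactly the information of the joint model.
#'
#' @inheritParams nma_fit
#' @return A data frame with one row per within-study contrast: \code{sid},
#'   \code{tid1}, \code{tid2}, effect \code{y} (tid1 vs. tid2), naive
#'   variance \code{v_naive} and adjusted variance \code{v}.
#' @export
arms_to_contrasts <- function(sid, tid, e, n, data = NULL,
                              measure = c("OR", "RR", "RD"), incr = 0.5,
                              allincr = FALSE, addincr = FALSE,
                              allstudies = FALSE) {
  if (!is.null(data)) { sid <- data$sid; tid <- data$tid
                        e <- data$e; n <- data$n }
  measure <- match.arg(measure)
  prep <- .nma_prep(sid, tid, e, n, measure, incr, allincr, addincr,
                    allstudies)
  rows <- list()
  for (st in prep$studies) {
    p <- length(st$tid)
    S <- matrix(st$u[1], p - 1, p - 1)
    diag(S) <- st$u[1] + st$u[-1]
    Kmat <- solve(S)
    B <- cbind(-1, diag(1, p - 1))
    Ls <- t(B) %*% Kmat %*% B
    for (a in seq_len(p - 1)) for (b in (a + 1):p) {
      w <- -Ls[a, b]
      rows[[length(rows) + 1L]] <- data.frame(
        sid = st$sid, tid1 = st$tid[a], tid2 = st$tid[b],
        y = st$g[a] - st$g[b], v_naive = st$u[a] + st$u[b], v = 1 / w)
    }
  }
  do.call(rbind, rows)
}

#' Fit a frequentist network meta-analysis
#'
#' Contrast-based network meta-analysis over a connected network of
#' \code{K} treatments, solved by weighted least squares on the treatment
#' graph (the information matrix is a graph Laplacian; its Moore-Penrose
#' inverse yields all \code{K(K-1)/2} comparisons and their variances).
#' Multi-arm studies are handled by the variance-adjustment scheme of the
#' graph-theoretical method.  Under the random-effects model a single
#' between-study variance, estimated by a generalised method-of-moments
#' (DerSimonian-Laird type) estimator, is added to every contrast variance
#' with the appropriate multi-arm covariance structure.
#'
#' @param sid,tid,e,n Study id, treatment id, event count and sample size,
#'   one row per study arm; ids should be natural numbers starting from 1.
#' @param data Optional data frame with columns \code{sid, tid, e, n}.
#' @param measure \code{"OR"}, \code{"RR"} or \code{"RD"}.
#' @param random Random-effects model?  \code{FALSE} forces the
#'   between-study variance to 0.
#' @param alpha Significance level; CIs have level \code{1 - alpha}.
#' @param incr,allincr,addincr,allstudies Continuity-correction rules; see
#'   \code{\link{arms_to_contrasts}}.
#'
#' @return An object of class \code{"nma_fit"}: treatment labels
#'   \code{trts}, \code{K}, K x K matrices \code{est} (row vs. column
#'   effect, antisymmetric), \code{se}, \code{ci.lb}, \code{ci.ub},
#'   heterogeneity \code{tau2} with \code{Q} and \code{df}, and the flags
#'   used.
#' @examples
#' d <- read_nma(frag_example("dat_copd.csv"))
#' nma_fit(data = d, random = FALSE)
#' @export
nma_fit <- function(sid, tid, e, n, data = NULL,
                    measure = c("OR", "RR", "RD"), random = TRUE,
                    alpha = 0.05, incr = 0.5, allincr = FALSE,
                    addincr = FALSE, allstudies = FALSE) {
  if (!is.null(data)) { sid <- data$sid; tid <- data$tid
                        e <- data$e; n <- data$n }
  measure <- match.arg(measure)
  stopifnot(alpha > 0, alpha < 1)
  prep <- .nma_prep(sid, tid, e, n, measure, incr, allincr, addincr,
                    allstudies)
  tq <- .nma_tau2(prep)
  tau2 <- if (random) tq$tau2 else 0
  sol <- .nma_solve(prep, tau2)
  K <- prep$K
  est <- outer(sol$mu, sol$mu, "-")
  se <- sqrt(pmax(outer(diag(sol$V), diag(sol$V), "+") - 2 * sol$V, 0))
  diag(se) <- 0
  crit <- stats::qnorm(1 - alpha / 2)
  lab <- as.character(prep$trts)
  dimnames(est) <- dimnames(se) <- list(lab, lab)
  out <- list(trts = prep$trts, K = K, est = est, se = se,
              ci.lb = est - crit * se, ci.ub = est + crit * se,
              tau2 = tau2, Q = tq$Q, df = tq$df, random = random,
              measure = measure, alpha = alpha, mu = sol$mu, V = sol$V,
              dropped = prep$dropped,
              data = data.frame(sid = sid, tid = tid, e = e, n = n))
  class(out) <- "nma_fit"
  out
}

#' @export
print.nma_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Network meta-analysis: %d treatments, %d studies (%s, %s)\n",
              x$K, length(unique(x$data$sid)), x$measure,
              if (x$random) "random effects" else "fixed effect"))
  cat(sprintf("  tau^2 = %s (Q = %s on %d df)\n",
              format(round(x$tau2, digits)), format(round(x$Q, digits)),
              x$df))
  cat("  estimates (row vs column):\n")
  print(round(x$est, digits))
  invisible(x)
}

## Pair summary at a given state; internal fast path for the greedy search.
.nma_ci_pair <- function(prep, random, alpha, t1, t2) {
  tau2 <- if (random) .nma_tau2(prep)$tau2 else 0
  sol <- .nma_solve(prep, tau2)
  i <- match(t1, prep$trts); j <- match(t2, prep$trts)
  theta <- sol$mu[i] - sol$mu[j]
  se <- sqrt(max(0, sol$V[i, i] + sol$V[j, j] - 2 * sol$V[i, j]))
  crit <- stats::qnorm(1 - alpha / 2)
  c(theta = theta, lb = theta - crit * se, ub = theta + crit * se,
    tau2 = tau2)
}
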