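## Inverse-variance pairwise meta-analysis: per-study effects, between-study
## variance (DerSimonian-Laird moment estimator, REML), pooling, and normal
## or Hartung-Knapp-Sidik-Jonkman confidence intervals.

#' Per-study effect estimates for a meta-analysis
#'
#' Computes the effect size \code{y_i} and standard error \code{s_i} of each
#' study on the analysis scale (log OR, log RR, or RD).  The continuity
#' correction is applied per study, only to studies with at least one zero
#' cell.
#'
#' @param e0,n0,e1,n1 Vectors of event counts and sample sizes, one entry per
#'   study.
#' @param measure \code{"OR"}, \code{"RR"} or \code{"RD"}.
#' @param incr Continuity-correction increment (default 0.5).
#' @return A data frame with columns \code{y}, \code{s}, \code{corrected}.
#' @export
study_effects <- function(e0, n0, e1, n1, measure = c("OR", "RR", "RD"),
                          incr = 0.5) {
  measure <- match.arg(measure)
  stopifnot(length(e0) >= 1, length(n0) == length(e0),
            length(e1) == length(e0), length(n1) == length(e0),
            all(e0 >= 0), all(e0 <= n0), all(e1 >= 0), all(e1 <= n1))
  est <- .effect_vec(e0, n0, e1, n1, measure, incr)
  data.frame(y = est$y, s = est$se, corrected = est$corrected)
}

#' DerSimonian-Laird estimator of the between-study variance
#'
#' Moment estimator based on Cochran's Q with fixed-effect weights
#' \code{1/s_i^2}, truncated at zero.  A single study gives 0.
#'
#' @param y,s Per-study effect estimates and standard errors.
#' @return Estimated between-study variance (non-negative).
#' @export
tau2_dl <- function(y, s) {
  stopifnot(length(y) == length(s), all(s > 0))
  N <- length(y)
  if (N < 2) return(0)
  w <- 1 / s^2
  theta_fe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - theta_fe)^2)
  C <- sum(w) - sum(w^2) / sum(w)
  max(0, (Q - (N - 1)) / C)
}

#' REML estimator of the between-study variance
#'
#' Iterative restricted maximum likelihood under the normal-normal model,
#' truncated at zero.  Starts from the DerSimonian-Laird value; if the
#' iteration does not converge within \code{maxit} steps the DL estimate is
#' returned with a warning.
#'
#' @param y,s Per-study effect estimates and standard errors.
#' @param tol Convergence tolerance on successive estimates.
#' @param maxit Maximum number of iterations.
#' @return Estimated between-study variance (non-negative).
#' @export
tau2_reml <- function(y, s, tol = 1e-8, maxit = 100) {
  stopifnot(length(y) == length(s), all(s > 0))
  N <- length(y)
  if (N < 2) return(0)
  tau2 <- tau2_dl(y, s)
  for (it in seq_len(maxit)) {
    w <- 1 / (s^2 + tau2)
    theta <- sum(w * y) / sum(w)
    ## REML fixed-point update with the degrees-of-freedom correction term
    tau2_new <- max(0, sum(w^2 * ((y - theta)^2 - s^2)) / sum(w^2) +
                      1 / sum(w))
    if (abs(tau2_new - tau2) < tol) return(tau2_new)
    tau2 <- tau2_new
  }
  warning("REML did not converge in ", maxit,
          " iterations; falling back to DerSimonian-Laird")
  tau2_dl(y, s)
}

#' Pool study effects into an overall estimate with a confidence interval
#'
#' Inverse-variance pooling with weights \code{w_i = 1 / (s_i^2 + tau2)}.
#' The confidence interval at level \code{1 - alpha} is either the
#' conventional normal (z) interval, or the Hartung-Knapp-Sidik-Jonkman
#' interval using a t quantile with \code{N - 1} degrees of freedom and the
#' weighted residual scale (no truncation of the scale factor).
#'
#' @param y,s Per-study effect estimates and standard errors.
#' @param tau2 Between-study variance to use (0 for a fixed-effect fit).
#' @param alpha Significance level; the CI has level \code{1 - alpha}.
#' @param ci_method \code{"z"} or \code{"hksj"}.
#' @return A list of class \code{"ma_fit"}: \code{theta} (pooled estimate),
#'   \code{se}, \code{ci.lb}, \code{ci.ub}, \code{tau2}, \code{weights}
#'   (normalised), \code{y}, \code{s}, \code{alpha}, \code{ci_method}.
#' @export
ma_pool <- function(y, s, tau2 = 0, alpha = 0.05,
                    ci_method = c("z", "hksj")) {
  ci_method <- match.arg(ci_method)
  stopifnot(length(y) >= 1, length(s) == length(y), all(s > 0), tau2 >= 0,
            alpha > 0, alpha < 1)
  N <- length(y)
  if (ci_method == "hksj" && N < 2)
    stop("the HKSJ interval needs at least two studies")
  w <- 1 / (s^2 + tau2)
  theta <- sum(w * y) / sum(w)
  se_z <- 1 / sqrt(sum(w))
  if (ci_method == "z") {
    se <- se_z
    crit <- stats::qnorm(1 - alpha / 2)
  } else {
    se <- sqrt(sum(w * (y - theta)^2) / ((N - 1) * sum(w)))
    crit <- stats::qt(1 - alpha / 2, df = N - 1)
  }
  structure(list(theta = theta, se = se, ci.lb = theta - crit * se,
                 ci.ub = theta + crit * se, tau2 = tau2,
                 weights = w / sum(w), y = y, s = s, alpha = alpha,
                 ci_method = ci_method, N = N),
            class = "ma_fit")
}

#' Fit a pairwise meta-analysis from 2x2 tables
#'
#' Composes \code{\link{study_effects}}, a between-study variance estimator,
#' and \code{\link{ma_pool}}.  The default configuration (OR, DL, z interval)
#' is the conventional random-effects analysis.
#'
#' @inheritParams study_effects
#' @param tau2_method \code{"DL"}, \code{"REML"}, or \code{"FE"} (fixed
#'   effect: the between-study variance is forced to 0).
#' @param ci_method \code{"z"} or \code{"hksj"}.
#' @param alpha Significance level of the CI.
#' @return An \code{"ma_fit"} object (see \code{\link{ma_pool}}) with the
#'   measure and per-study data attached.
#' @examples
#' fit <- ma_fit(e0 = c(3, 2), n0 = c(24, 10), e1 = c(4, 1), n1 = c(20, 9))
#' fit$theta
#' @export
ma_fit <- function(e0, n0, e1, n1, measure = c("OR", "RR", "RD"),
                   tau2_method = c("DL", "REML", "FE"),
                   ci_method = c("z", "hksj"), alpha = 0.05, incr = 0.5) {
  measure <- match.arg(measure)
  tau2_method <- match.arg(tau2_method)
  ci_method <- match.arg(ci_method)
  eff <- study_effects(e0, n0, e1, n1, measure, incr)
  tau2 <- switch(tau2_method,
                 FE = 0,
                 DL = tau2_dl(eff$y, eff$s),
                 REML = tau2_reml(eff$y, eff$s))
  fit <- ma_pool(eff$y, eff$s, tau2, alpha, ci_method)
  fit$measure <- measure
  fit$tau2_method <- tau2_method
  fit$data <- data.frame(e0 = e0, n0 = n0, e1 = e1, n1 = n1)
  fit
}

#' @export
print.ma_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Meta-analysis of %d studies%s\n", x$N,
              if (!is.null(x$measure)) paste0(" (", x$measure, ")") else ""))
  cat(sprintf("  pooled estimate %s, %s%% CI [%s, %s] (%s)\n",
              format(round(x$theta, digits)),
              format(100 * (1 - x$alpha)),
              format(round(x$ci.lb, digits)),
              format(round(x$ci.ub, digits)), x$ci_method))
  cat(sprintf("  tau^2 = %s\n", format(round(x$tau2, digits))))
  invisible(x)
}

## Fast internal fit on a prepared (y, s2) representation; used by the
## greedy fragility search, which refits thousands of candidate datasets.
.ma_ci_fast <- function(y, s2, tau2_method, ci_method, alpha) {
  N <- length(y)
  if (tau2_method == "FE" || N < 2) tau2 <- 0
  else if (tau2_method == "REML") tau2 <- suppressWarnings(
    tau2_reml(y, sqrt(s2)))
  else {
    w <- 1 / s2
    th <- sum(w * y) / sum(w)
    Q <- sum(w * (y - th)^2)
    C <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (Q - (N - 1)) / C)
  }
  w <- 1 / (s2 + tau2)
  theta <- sum(w * y) / sum(w)
  if (ci_method == "z") {
    se <- 1 / sqrt(sum(w))
    crit <- stats::qnorm(1 - alpha / 2)
  } else {
    se <- sqrt(sum(w * (y - theta)^2) / ((N - 1) * sum(w)))
    crit <- stats::qt(1 - alpha / 2, df = N - 1)
  }
  c(theta = theta, lb = theta - crit * se, ub = theta + crit * se,
    tau2 = tau2)
}
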