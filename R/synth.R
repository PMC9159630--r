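## Synthetic data generators emulating the three dataset schemas, with
## binomial arm events and per-study true log odds ratios drawn from a
## normal random-effects distribution.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  expr
}

## One two-arm study: baseline probability p0, study log OR theta_i.
.gen_arms <- function(ns, n_range, p0_range, theta_i) {
  n0 <- sample(n_range[1]:n_range[2], ns, replace = TRUE)
  n1 <- sample(n_range[1]:n_range[2], ns, replace = TRUE)
  p0 <- stats::runif(ns, p0_range[1], p0_range[2])
  p1 <- stats::plogis(stats::qlogis(p0) + theta_i)
  data.frame(e0 = stats::rbinom(ns, n0, p0), n0 = n0,
             e1 = stats::rbinom(ns, n1, p1), n1 = n1)
}

#' Generate synthetic individual 2x2 trials
#'
#' Each trial draws a baseline event probability uniformly from
#' \code{p0_range}, a true log odds ratio from
#' \code{N(theta, tau2)}, and binomial event counts in both arms.
#' The true per-trial parameters are attached as attribute \code{"truth"}.
#'
#' @param n_trials Number of trials.
#' @param theta True mean log odds ratio (group 1 vs. group 0).
#' @param tau2 Between-trial variance of the log odds ratio.
#' @param n_range Integer range for each arm's sample size.
#' @param p0_range Range of the group-0 event probability.
#' @param seed Optional seed; the output is fully determined by it.
#' @return A data frame with columns \code{e0, n0, e1, n1}.
#' @examples
#' gen_trials(3, theta = 0.5, seed = 1)
#' @export
gen_trials <- function(n_trials, theta = 0, tau2 = 0, n_range = c(20, 200),
                       p0_range = c(0.1, 0.4), seed = NULL) {
  stopifnot(n_trials >= 1, tau2 >= 0, n_range[1] >= 2,
            p0_range[1] > 0, p0_range[2] < 1)
  .with_seed(seed, {
    theta_i <- stats::rnorm(n_trials, theta, sqrt(tau2))
    d <- .gen_arms(n_trials, n_range, p0_range, theta_i)
    attr(d, "truth") <- data.frame(theta = theta_i)
    d
  })
}

#' Generate a synthetic pairwise meta-analysis
#'
#' A single meta-analysis of \code{N} studies under the binomial-normal
#' model: study-specific true log odds ratios are \code{N(theta, tau2)} and
#' events are binomial.  The truth record (per-study \code{theta_i}) is
#' attached as attribute \code{"truth"}.
#'
#' @param N Number of studies.
#' @inheritParams gen_trials
#' @return A data frame with columns \code{e0, n0, e1, n1}.
#' @export
gen_ma <- function(N, theta = 0, tau2 = 0.1, n_range = c(20, 200),
                   p0_range = c(0.1, 0.4), seed = NULL) {
  d <- gen_trials(N, theta, tau2, n_range, p0_range, seed)
  attr(d, "truth") <- data.frame(theta = attr(d, "truth")$theta)
  d
}

#' Generate multiple synthetic pairwise meta-analyses
#'
#' Stacks \code{n_ma} independent meta-analyses in the \code{ma.id} schema.
#'
#' @param n_ma Number of meta-analyses.
#' @param N_range Integer range for the number of studies per MA.
#' @inheritParams gen_trials
#' @return A data frame with columns \code{ma.id, e0, n0, e1, n1}.
#' @export
gen_mas <- function(n_ma, N_range = c(3, 10), theta = 0, tau2 = 0.1,
                    n_range = c(20, 200), p0_range = c(0.1, 0.4),
                    seed = NULL) {
  stopifnot(n_ma >= 1)
  .with_seed(seed, {
    out <- lapply(seq_len(n_ma), function(k) {
      N <- sample(N_range[1]:N_range[2], 1)
      cbind(ma.id = k, gen_ma(N, theta, tau2, n_range, p0_range,
                              seed = NULL))
    })
    do.call(rbind, out)
  })
}

#' Generate a synthetic network meta-analysis
#'
#' Builds a connected network of \code{K} treatments: the first
#' \code{K - 1} studies compare treatment 1 with each other treatment
#' (guaranteeing connectivity), and the remaining studies compare random
#' treatment pairs; a fraction of studies may receive a third arm.  Each
#' treatment k has a true log-odds offset \code{theta_k} against treatment 1
#' (given in \code{theta}, a vector of length \code{K} with first element
#' 0), and each study arm receives an independent \code{N(0, tau2/2)}
#' log-odds perturbation, so every within-study contrast has heterogeneity
#' variance \code{tau2} with the shared-arm covariance \code{tau2/2} assumed
#' by the random-effects network model.
#'
#' @param K Number of treatments (>= 2).
#' @param n_studies Total number of studies (>= K - 1).
#' @param theta Numeric vector of length \code{K}: true log-odds of each
#'   treatment relative to treatment 1 (\code{theta[1]} must be 0).
#' @param tau2 Heterogeneity variance of the within-study contrasts.
#' @param p_multi Probability that a study receives a third arm.
#' @inheritParams gen_trials
#' @return A data frame with columns \code{sid, tid, e, n}.
#' @export
gen_nma <- function(K, n_studies = max(K, 6), theta = numeric(K),
                    tau2 = 0.05, p_multi = 0.2, n_range = c(50, 200),
                    p0_range = c(0.1, 0.4), seed = NULL) {
  stopifnot(K >= 2, n_studies >= K - 1, length(theta) == K, theta[1] == 0,
            tau2 >= 0, p_multi >= 0, p_multi <= 1)
  .with_seed(seed, {
    rows <- list()
    for (s in seq_len(n_studies)) {
      if (s <= K - 1) arms <- c(1L, s + 1L)
      else arms <- sort(sample(K, 2))
      if (K >= 3 && stats::runif(1) < p_multi)
        arms <- sort(unique(c(arms, sample(setdiff(seq_len(K), arms), 1))))
      base_logit <- stats::qlogis(stats::runif(1, p0_range[1], p0_range[2]))
      ## independent N(0, tau2/2) arm effects give each contrast variance
      ## tau2 and shared-arm covariance tau2/2 -- the random-effects
      ## structure assumed by the network model
      re <- stats::rnorm(length(arms), 0, sqrt(tau2 / 2))
      for (k in seq_along(arms)) {
        a <- arms[k]
        n <- sample(n_range[1]:n_range[2], 1)
        p <- stats::plogis(base_logit + theta[a] + re[k])
        rows[[length(rows) + 1L]] <-
          data.frame(sid = s, tid = a, e = stats::rbinom(1, n, p), n = n)
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "truth") <- list(theta = theta, tau2 = tau2)
    out
  })
}
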