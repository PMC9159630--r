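## Per-comparison fragility of a network meta-analysis: greedy CI-driven
## search with event-status modifications restricted to the arms of the two
## compared treatments.

## Candidate single-event modifications for comparison t1 vs t2.  Target
## "left" lowers theta(t1 vs t2): remove events from t1 arms or add events
## to t2 arms.  Order encodes the tie rule: studies in ascending sid order,
## within a study the arm of the first-named treatment (t1) first.
.nma_candidates <- function(d, t1, t2, target) {
  out <- list()
  dec <- if (target == "left") t1 else t2   # treatment whose events decrease
  inc <- if (target == "left") t2 else t1
  for (s in unique(d$sid)) {
    rows <- which(d$sid == s)
    rows <- rows[order(match(d$tid[rows], c(t1, t2)))]
    for (r in rows) {
      if (d$tid[r] == dec && d$e[r] > 0)
        out[[length(out) + 1L]] <- c(r, -1L)
      else if (d$tid[r] == inc && d$e[r] < d$n[r])
        out[[length(out) + 1L]] <- c(r, +1L)
    }
  }
  if (!length(out)) return(NULL)
  m <- do.call(rbind, out)
  colnames(m) <- c("row", "delta")
  m
}

## One greedy run for one comparison in one direction; analogous to the
## pairwise-MA run but refitting the whole network at every candidate.
.nma_greedy_run <- function(d, t1, t2, measure, null, alpha, target, goal,
                            random, incr, allincr, addincr, allstudies,
                            max_iter) {
  fits <- 0L
  traj <- list()
  for (iter in seq_len(max_iter)) {
    cand <- .nma_candidates(d, t1, t2, target)
    if (is.null(cand))
      return(list(FI = NA_integer_, trajectory = .nma_traj_df(traj),
                  data = d, fits = fits,
                  reason = "no legal modification left in the two arms"))
    score <- numeric(nrow(cand))
    cis <- matrix(NA_real_, nrow(cand), 4)
    for (j in seq_len(nrow(cand))) {
      dj <- d
      dj$e[cand[j, 1]] <- dj$e[cand[j, 1]] + cand[j, 2]
      prep <- .nma_prep(dj$sid, dj$tid, dj$e, dj$n, measure, incr, allincr,
                        addincr, allstudies)
      cis[j, ] <- .nma_ci_pair(prep, random, alpha, t1, t2)
      score[j] <- if (target == "left") cis[j, 2] else cis[j, 3]
      fits <- fits + 1L
    }
    best <- if (target == "left") which.min(score) else which.max(score)
    r <- cand[best, 1]
    d$e[r] <- d$e[r] + cand[best, 2]
    ci <- unname(cis[best, ])
    traj[[iter]] <- c(iter = iter, sid = d$sid[r], tid = d$tid[r],
                      delta = unname(cand[best, 2]), theta = ci[1],
                      ci.lb = ci[2], ci.ub = ci[3], tau2 = ci[4])
    flipped <- if (goal == "cover")
      ci[2] <= null && null <= ci[3]
    else if (target == "left") ci[3] < null else ci[2] > null
    if (flipped)
      return(list(FI = iter, trajectory = .nma_traj_df(traj), data = d,
                  fits = fits, reason = "flipped"))
  }
  list(FI = NA_integer_, trajectory = .nma_traj_df(traj), data = d,
       fits = fits, reason = "iteration cap reached")
}

.nma_traj_df <- function(traj) {
  if (!length(traj))
    return(data.frame(iter = integer(), sid = integer(), tid = integer(),
                      delta = integer(), theta = numeric(),
                      ci.lb = numeric(), ci.ub = numeric(),
                      tau2 = numeric()))
  as.data.frame(do.call(rbind, traj))
}

#' Fragility quotients for a network meta-analysis comparison
#'
#' The FI of a comparison A vs. B can be scaled by two denominators: the
#' sample size \code{n_AB} of the arms of the two compared treatments across
#' all studies (so the quotient stays in (0, 100] and is comparable across
#' pairs), or the total sample size \code{n_NMA} of the whole network (whose
#' quotient is bounded above by \code{n_AB / n_NMA * 100} because only the
#' two compared arms are ever modified).
#'
#' @param fi Fragility index (NA propagates).
#' @param n_AB Sample size in the arms of the two compared treatments.
#' @param n_NMA Total sample size of the network.
#' @return A list with \code{FQ.pair} and \code{FQ.network} (percentages).
#' @export
fq_nma <- function(fi, n_AB, n_NMA) {
  stopifnot(n_AB >= 1, n_AB <= n_NMA)
  list(FQ.pair = fi / n_AB * 100, FQ.network = fi / n_NMA * 100)
}

#' Fragility of a network meta-analysis
#'
#' Assesses, for each requested treatment comparison, the minimal number of
#' single-event status modifications that alters the statistical
#' significance of that comparison's network estimate.  Following the
#' restriction that makes the search practical and interpretable,
#' modifications are confined to arms of the two compared treatments (in any
#' study containing them); after every candidate modification the entire
#' network is refitted, re-estimating the between-study variance under the
#' random-effects model.  An \code{NA} fragility index therefore means that
#' significance cannot be altered \emph{by modifications in those two arms},
#' not that it cannot be altered at all.
#'
#' @inheritParams nma_fit
#' @param mod.dir Direction of CI movement for originally non-significant
#'   comparisons: \code{"both"}, \code{"left"}, \code{"right"}, \code{"one"}.
#' @param tid1.f,tid2.f Optional vectors of treatment pairs to assess
#'   (comparison \code{tid1.f[k]} vs. \code{tid2.f[k]}); by default all
#'   \code{K(K-1)/2} comparisons are assessed.
#' @param null.OR,null.RR,null.RD Null values on the natural scales.
#' @param max_iter Iteration cap per direction (default: total network
#'   sample size).
#'
#' @return An object of class \code{"frag_nma"}: symmetric K x K matrices
#'   \code{FI}, \code{FQ.pair} (denominator \code{n_AB}) and
#'   \code{FQ.network} (denominator \code{n_NMA}), the original fit
#'   \code{fit0}, and a per-comparison list \code{comparisons} with
#'   direction, trajectory, modified final dataset and fit counts.
#' @examples
#' d <- read_nma(frag_example("dat_copd.csv"))
#' out <- frag_nma(data = d, random = FALSE, tid1.f = 2, tid2.f = 1)
#' out$FI["2", "1"]
#' @export
frag_nma <- function(sid, tid, e, n, data = NULL,
                     measure = c("OR", "RR", "RD"), random = TRUE,
                     alpha = 0.05, mod.dir = c("both", "left", "right",
                                               "one"),
                     tid1.f = NULL, tid2.f = NULL,
                     null.OR = 1, null.RR = 1, null.RD = 0,
                     incr = 0.5, allincr = FALSE, addincr = FALSE,
                     allstudies = FALSE, max_iter = NULL) {
  if (!is.null(data)) { sid <- data$sid; tid <- data$tid
                        e <- data$e; n <- data$n }
  measure <- match.arg(measure)
  mod.dir <- match.arg(mod.dir)
  d <- data.frame(sid = sid, tid = tid, e = e, n = n)
  fit0 <- nma_fit(data = d, measure = measure, random = random,
                  alpha = alpha, incr = incr, allincr = allincr,
                  addincr = addincr, allstudies = allstudies)
  trts <- fit0$trts
  K <- fit0$K
  if (is.null(tid1.f) != is.null(tid2.f))
    stop("tid1.f and tid2.f must be given together")
  if (is.null(tid1.f)) {
    pairs <- utils::combn(trts, 2)
    tid1.f <- pairs[2, ]; tid2.f <- pairs[1, ]   # larger vs smaller
  }
  stopifnot(length(tid1.f) == length(tid2.f))
  if (!all(tid1.f %in% trts) || !all(tid2.f %in% trts) ||
      any(tid1.f == tid2.f))
    stop("requested comparison(s) involve unknown or identical treatments")
  null <- .null_on_scale(measure, null.OR, null.RR, null.RD)
  n_NMA <- sum(d$n)
  if (is.null(max_iter)) max_iter <- n_NMA
  lab <- as.character(trts)
  FI <- FQp <- FQn <- matrix(NA_real_, K, K, dimnames = list(lab, lab))
  comparisons <- list()
  for (k in seq_along(tid1.f)) {
    t1 <- tid1.f[k]; t2 <- tid2.f[k]
    i <- match(t1, trts); j <- match(t2, trts)
    theta0 <- fit0$est[i, j]
    lb0 <- fit0$ci.lb[i, j]; ub0 <- fit0$ci.ub[i, j]
    sig0 <- lb0 > null || ub0 < null
    if (sig0) {
      targets <- if (theta0 > null) "left" else "right"
      goal <- "cover"; dir <- "sig2nonsig"
    } else {
      targets <- switch(mod.dir,
                        both = c("left", "right"),
                        left = "left", right = "right",
                        one = {
                          if (theta0 == null)
                            warning("estimate equals the null for ", t1,
                                    " vs ", t2, "; moving the CI right")
                          if (theta0 < null) "left" else "right"
                        })
      goal <- "exclude"; dir <- "nonsig2sig"
    }
    runs <- lapply(targets, function(tg)
      .nma_greedy_run(d, t1, t2, measure, null, alpha, tg, goal, random,
                      incr, allincr, addincr, allstudies, max_iter))
    names(runs) <- targets
    fis <- vapply(runs, function(r) as.numeric(r$FI), numeric(1))
    if (all(is.na(fis))) { fi_k <- NA_integer_; win <- runs[[1L]] }
    else { fi_k <- min(fis, na.rm = TRUE)
           win <- runs[[which(fis == fi_k)[1L]]] }
    n_AB <- sum(d$n[d$tid %in% c(t1, t2)])
    q <- fq_nma(fi_k, n_AB, n_NMA)
    FI[i, j] <- FI[j, i] <- fi_k
    FQp[i, j] <- FQp[j, i] <- q$FQ.pair
    FQn[i, j] <- FQn[j, i] <- q$FQ.network
    comparisons[[paste(t1, "vs", t2)]] <-
      list(tid1 = t1, tid2 = t2, FI = fi_k, dir = dir,
           FQ.pair = q$FQ.pair, FQ.network = q$FQ.network, n_AB = n_AB,
           theta0 = theta0, ci0 = c(lb0, ub0),
           trajectory = win$trajectory, final_data = win$data,
           fits_performed = sum(vapply(runs, function(r) r$fits,
                                       numeric(1))),
           runs = runs)
  }
  out <- list(FI = FI, FQ.pair = FQp, FQ.network = FQn, fit0 = fit0,
              comparisons = comparisons, tid1.f = tid1.f, tid2.f = tid2.f,
              measure = measure, random = random, alpha = alpha,
              null = null, n_NMA = n_NMA, data = d)
  class(out) <- "frag_nma"
  out
}

#' @export
print.frag_nma <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Fragility of a network meta-analysis: %d treatments, %d studies (%s, %s)\n",
    x$fit0$K, length(unique(x$data$sid)), x$measure,
    if (x$random) "random effects" else "fixed effect"))
  cat(sprintf("  alpha = %s, tau^2 = %s\n", format(x$alpha),
              format(round(x$fit0$tau2, digits))))
  cat("\n  fragility index (row vs column):\n")
  print(x$FI)
  cat("\n  FQ (%) with the two-arm sample size as denominator:\n")
  print(round(x$FQ.pair, digits))
  invisible(x)
}

#' Fragility of a network meta-analysis at multiple significance levels
#'
#' Runs \code{\link{frag_nma}} at each level of an equally spaced grid of
#' significance levels.  Because every level requires a full greedy search
#' per comparison, the default grid is deliberately coarse
#' (\code{alpha.breaks = 10}).
#'
#' @inheritParams frag_nma
#' @inheritParams frag_study_alpha
#' @return An object of classes \code{"frag_alpha"} and
#'   \code{"frag_nma_alpha"}: \code{alphas}, an array \code{FI} (levels x
#'   comparisons) with matching \code{FQ.pair} and \code{dir}, and
#'   per-comparison averages.
#' @export
frag_nma_alpha <- function(sid, tid, e, n, data = NULL,
                           measure = c("OR", "RR", "RD"), random = TRUE,
                           alpha.from = 0.005, alpha.to = 0.05,
                           alpha.breaks = 10,
                           mod.dir = c("both", "left", "right", "one"),
                           tid1.f = NULL, tid2.f = NULL,
                           null.OR = 1, null.RR = 1, null.RD = 0,
                           incr = 0.5, allincr = FALSE, addincr = FALSE,
                           allstudies = FALSE, max_iter = NULL) {
  if (!is.null(data)) { sid <- data$sid; tid <- data$tid
                        e <- data$e; n <- data$n }
  alphas <- .alpha_grid(alpha.from, alpha.to, alpha.breaks)
  res <- lapply(alphas, function(a)
    frag_nma(sid, tid, e, n, measure = measure, random = random, alpha = a,
             mod.dir = mod.dir, tid1.f = tid1.f, tid2.f = tid2.f,
             null.OR = null.OR, null.RR = null.RR, null.RD = null.RD,
             incr = incr, allincr = allincr, addincr = addincr,
             allstudies = allstudies, max_iter = max_iter))
  cmp <- names(res[[1]]$comparisons)
  FI <- t(vapply(res, function(r)
    vapply(r$comparisons, function(cc) as.numeric(cc$FI), numeric(1)),
    numeric(length(cmp))))
  FQ <- t(vapply(res, function(r)
    vapply(r$comparisons, function(cc) as.numeric(cc$FQ.pair), numeric(1)),
    numeric(length(cmp))))
  dir <- t(vapply(res, function(r)
    vapply(r$comparisons, function(cc) cc$dir, character(1)),
    character(length(cmp))))
  if (length(cmp) == 1L) { FI <- t(FI); FQ <- t(FQ); dir <- t(dir) }
  dimnames(FI) <- dimnames(FQ) <- dimnames(dir) <- list(NULL, cmp)
  out <- list(alphas = alphas, FI = FI, FQ = FQ, dir = dir,
              FI.avg = colMeans(FI, na.rm = TRUE),
              FQ.avg = colMeans(FQ, na.rm = TRUE),
              n.NA = colSums(is.na(FI)),
              measure = match.arg(measure), p0 = NULL)
  class(out) <- c("frag_nma_alpha", "frag_alpha")
  out
}
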