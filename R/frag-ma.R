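## Fragility of a pairwise meta-analysis: greedy CI-driven single-event
## modification search, alpha sweep, and batch assessment.

## Null value on the analysis scale.
.null_on_scale <- function(measure, null.OR, null.RR, null.RD)
  switch(measure, OR = log(null.OR), RR = log(null.RR), RD = null.RD)

## Candidate single-event modifications moving the pooled estimate in the
## target direction.  Target "left" lowers the group-1 vs group-0 effect:
## remove an event from group 1 or add one to group 0; "right" mirrors.
## Order encodes the tie rule: lowest study id first, within a study the
## group-1 candidate before the group-0 one.
.ma_candidates <- function(e0, n0, e1, n1, target) {
  out <- vector("list", 2L * length(e0))
  k <- 0L
  for (i in seq_along(e0)) {
    if (target == "left") {
      if (e1[i] > 0)     { k <- k + 1L; out[[k]] <- c(i, 1L, -1L) }
      if (e0[i] < n0[i]) { k <- k + 1L; out[[k]] <- c(i, 0L, +1L) }
    } else {
      if (e1[i] < n1[i]) { k <- k + 1L; out[[k]] <- c(i, 1L, +1L) }
      if (e0[i] > 0)     { k <- k + 1L; out[[k]] <- c(i, 0L, -1L) }
    }
  }
  if (k == 0L) return(NULL)
  m <- do.call(rbind, out[seq_len(k)])
  colnames(m) <- c("study", "group", "delta")
  m
}

## One greedy run in a fixed direction.  `goal` is "cover" (an originally
## significant CI must come to cover the null) or "exclude" (an originally
## non-significant CI must leave the null on the target side).  Returns the
## number of steps (FI for this direction, NA if unattainable), the
## trajectory, the modified dataset, and the number of meta-analyses fitted.
.ma_greedy_run <- function(e0, n0, e1, n1, measure, null, alpha, target,
                           goal, tau2_method, ci_method, incr, max_iter) {
  eff <- .effect_vec(e0, n0, e1, n1, measure, incr)
  y <- eff$y; s2 <- eff$se^2
  fits <- 0L
  traj <- list()
  e0c <- e0; e1c <- e1
  for (iter in seq_len(max_iter)) {
    cand <- .ma_candidates(e0c, n0, e1c, n1, target)
    if (is.null(cand))
      return(list(FI = NA_integer_, trajectory = .ma_traj_df(traj),
                  e0 = e0c, e1 = e1c, fits = fits,
                  reason = "no legal modification left"))
    score <- numeric(nrow(cand))
    cis <- matrix(NA_real_, nrow(cand), 4)
    for (j in seq_len(nrow(cand))) {
      i <- cand[j, 1]
      a0 <- e0c[i]; a1 <- e1c[i]
      if (cand[j, 2] == 0L) a0 <- a0 + cand[j, 3] else a1 <- a1 + cand[j, 3]
      ej <- .effect_vec(a0, n0[i], a1, n1[i], measure, incr)
      yj <- y; s2j <- s2
      yj[i] <- ej$y; s2j[i] <- ej$se^2
      cis[j, ] <- .ma_ci_fast(yj, s2j, tau2_method, ci_method, alpha)
      score[j] <- if (target == "left") cis[j, 2] else cis[j, 3]
      fits <- fits + 1L
    }
    best <- if (target == "left") which.min(score) else which.max(score)
    i <- cand[best, 1]
    if (cand[best, 2] == 0L) e0c[i] <- e0c[i] + cand[best, 3]
    else e1c[i] <- e1c[i] + cand[best, 3]
    eb <- .effect_vec(e0c[i], n0[i], e1c[i], n1[i], measure, incr)
    y[i] <- eb$y; s2[i] <- eb$se^2
    ci <- unname(cis[best, ])
    traj[[iter]] <- c(iter = iter, cand[best, ], theta = ci[1],
                      ci.lb = ci[2], ci.ub = ci[3], tau2 = ci[4])
    flipped <- if (goal == "cover")
      ci[2] <= null && null <= ci[3]
    else if (target == "left") ci[3] < null else ci[2] > null
    if (flipped)
      return(list(FI = iter, trajectory = .ma_traj_df(traj),
                  e0 = e0c, e1 = e1c, fits = fits, reason = "flipped"))
  }
  list(FI = NA_integer_, trajectory = .ma_traj_df(traj), e0 = e0c, e1 = e1c,
       fits = fits, reason = "iteration cap reached")
}

.ma_traj_df <- function(traj) {
  if (!length(traj))
    return(data.frame(iter = integer(), study = integer(), group = integer(),
                      delta = integer(), theta = numeric(),
                      ci.lb = numeric(), ci.ub = numeric(),
                      tau2 = numeric()))
  as.data.frame(do.call(rbind, traj))
}

#' Fragility of a pairwise meta-analysis
#'
#' Derives the fragility index of a meta-analysis by the greedy CI-driven
#' iterative algorithm: at each step every feasible single-event modification
#' (one event removed or added in one group of one study) is tried, the full
#' meta-analysis is refitted for each (the between-study variance is
#' re-estimated every time), and the modification moving the relevant
#' confidence bound furthest in the target direction is kept.  The iteration
#' stops as soon as the CI's significance state flips.  Significance is
#' judged by the CI: a result is significant when the null value lies
#' strictly outside the interval.
#'
#' For an originally significant result the CI is pushed toward the null
#' until it is covered.  For an originally non-significant result the CI can
#' be pushed left or right of the null; \code{mod.dir} selects the
#' direction(s), and with \code{"both"} the reported FI is the smaller of the
#' two directional FIs.  Each step evaluates at most 2N candidates, so at
#' most \code{2 * N * FI} meta-analyses are fitted per direction.
#'
#' @inheritParams ma_fit
#' @param data Optional data frame with columns \code{e0, n0, e1, n1}.
#' @param mod.dir Direction of CI movement when the original result is
#'   non-significant: \code{"both"}, \code{"left"}, \code{"right"}, or
#'   \code{"one"} (the side of the original point estimate).
#' @param null.OR,null.RR,null.RD Null values on the natural scales.
#' @param max_iter Iteration cap per direction; defaults to the total sample
#'   size.  Exceeding it yields \code{FI = NA}.
#'
#' @return An object of class \code{"frag_ma"}: \code{FI}, \code{FQ}
#'   (percentage of the total sample size), \code{dir}, the original fit
#'   \code{fit0}, the winning \code{trajectory} (one row per single-event
#'   step with the refitted estimate and CI), the modified final dataset,
#'   \code{fits_performed}, and the per-direction runs.
#' @examples
#' d <- gen_ma(N = 5, theta = 0.9, tau2 = 0, n_range = c(40, 60), seed = 7)
#' frag_ma(data = d)$FI
#' @export
frag_ma <- function(e0, n0, e1, n1, data = NULL,
                    measure = c("OR", "RR", "RD"), alpha = 0.05,
                    mod.dir = c("both", "left", "right", "one"),
                    null.OR = 1, null.RR = 1, null.RD = 0,
                    tau2_method = c("DL", "REML", "FE"),
                    ci_method = c("z", "hksj"), incr = 0.5,
                    max_iter = NULL) {
  cnt <- .resolve_counts(e0, n0, e1, n1, data)
  measure <- match.arg(measure)
  mod.dir <- match.arg(mod.dir)
  tau2_method <- match.arg(tau2_method)
  ci_method <- match.arg(ci_method)
  stopifnot(alpha > 0, alpha < 1)
  e0 <- cnt$e0; n0 <- cnt$n0; e1 <- cnt$e1; n1 <- cnt$n1
  n_total <- sum(n0) + sum(n1)
  if (is.null(max_iter)) max_iter <- n_total
  null <- .null_on_scale(measure, null.OR, null.RR, null.RD)

  fit0 <- ma_fit(e0, n0, e1, n1, measure, tau2_method, ci_method, alpha,
                 incr)
  sig0 <- fit0$ci.lb > null || fit0$ci.ub < null
  if (sig0) {
    target <- if (fit0$theta > null) "left" else "right"
    runs <- list(.ma_greedy_run(e0, n0, e1, n1, measure, null, alpha,
                                target, "cover", tau2_method, ci_method,
                                incr, max_iter))
    names(runs) <- target
    dir <- "sig2nonsig"
  } else {
    targets <- switch(mod.dir,
                      both = c("left", "right"),
                      left = "left", right = "right",
                      one = {
                        if (fit0$theta == null)
                          warning("point estimate equals the null; ",
                                  "mod.dir = \"one\" moves the CI right")
                        if (fit0$theta < null) "left" else "right"
                      })
    runs <- lapply(targets, function(tg)
      .ma_greedy_run(e0, n0, e1, n1, measure, null, alpha, tg, "exclude",
                     tau2_method, ci_method, incr, max_iter))
    names(runs) <- targets
    dir <- "nonsig2sig"
  }
  fis <- vapply(runs, function(r) as.numeric(r$FI), numeric(1))
  if (all(is.na(fis))) {
    FI <- NA_integer_
    win <- runs[[1L]]
  } else {
    FI <- min(fis, na.rm = TRUE)
    win <- runs[[which(fis == FI)[1L]]]
  }
  out <- list(FI = FI, FQ = fq(FI, n_total), dir = dir,
              mod.dir = mod.dir, fit0 = fit0, null = null,
              measure = measure, alpha = alpha,
              tau2_method = tau2_method, ci_method = ci_method,
              trajectory = win$trajectory,
              data = data.frame(e0 = e0, n0 = n0, e1 = e1, n1 = n1),
              final_data = data.frame(e0 = win$e0, n0 = n0, e1 = win$e1,
                                      n1 = n1),
              fits_performed = sum(vapply(runs, function(r) r$fits,
                                          numeric(1))),
              runs = runs, n_total = n_total)
  class(out) <- "frag_ma"
  out
}

#' @export
print.frag_ma <- function(x, digits = 3, ...) {
  cat(sprintf("Fragility of a meta-analysis of %d studies (%s, %s, %s CI)\n",
              nrow(x$data), x$measure, x$tau2_method, x$ci_method))
  cat(sprintf("  original estimate %s, %s%% CI [%s, %s]\n",
              format(round(x$fit0$theta, digits)),
              format(100 * (1 - x$alpha)),
              format(round(x$fit0$ci.lb, digits)),
              format(round(x$fit0$ci.ub, digits))))
  cat(sprintf("  FI = %s (%s), FQ = %s%%\n",
              ifelse(is.na(x$FI), "NA", x$FI), x$dir,
              ifelse(is.na(x$FQ), "NA", format(round(x$FQ, digits)))))
  if (!is.na(x$FI) && nrow(x$trajectory))
    cat(sprintf("  studies modified: %s\n",
                paste(unique(x$trajectory$study), collapse = ", ")))
  invisible(x)
}

#' Fragility of a meta-analysis at multiple significance levels
#'
#' Runs \code{\link{frag_ma}} at each of \code{alpha.breaks} equally spaced
#' significance levels and averages the fragility indices over the levels at
#' which they are defined.
#'
#' @inheritParams frag_ma
#' @inheritParams frag_study_alpha
#' @return An object of classes \code{"frag_alpha"} and
#'   \code{"frag_ma_alpha"}: \code{alphas}, vectors \code{FI}, \code{FQ},
#'   \code{dir}, averages \code{FI.avg}, \code{FQ.avg}, and \code{n.NA}.
#' @export
frag_ma_alpha <- function(e0, n0, e1, n1, data = NULL,
                          measure = c("OR", "RR", "RD"),
                          alpha.from = 0.005, alpha.to = 0.05,
                          alpha.breaks = 100,
                          mod.dir = c("both", "left", "right", "one"),
                          null.OR = 1, null.RR = 1, null.RD = 0,
                          tau2_method = c("DL", "REML", "FE"),
                          ci_method = c("z", "hksj"), incr = 0.5,
                          max_iter = NULL) {
  cnt <- .resolve_counts(e0, n0, e1, n1, data)
  alphas <- .alpha_grid(alpha.from, alpha.to, alpha.breaks)
  res <- lapply(alphas, function(a)
    frag_ma(cnt$e0, cnt$n0, cnt$e1, cnt$n1, measure = measure, alpha = a,
            mod.dir = mod.dir, null.OR = null.OR, null.RR = null.RR,
            null.RD = null.RD, tau2_method = tau2_method,
            ci_method = ci_method, incr = incr, max_iter = max_iter))
  FI <- vapply(res, function(r) as.numeric(r$FI), numeric(1))
  FQ <- vapply(res, function(r) as.numeric(r$FQ), numeric(1))
  dir <- vapply(res, function(r) r$dir, character(1))
  out <- list(alphas = alphas, FI = FI, FQ = FQ, dir = dir,
              FI.avg = mean(FI, na.rm = TRUE), FQ.avg = mean(FQ, na.rm = TRUE),
              n.NA = sum(is.na(FI)), p0 = NULL,
              measure = match.arg(measure), n.total = sum(cnt$n0 + cnt$n1))
  class(out) <- c("frag_ma_alpha", "frag_alpha")
  out
}

#' Fragility of multiple pairwise meta-analyses
#'
#' Applies \code{\link{frag_ma}} to every meta-analysis in a stacked dataset
#' indexed by \code{ma.id} and summarises the fragility measures by the
#' original significance of each pooled result.
#'
#' @inheritParams frag_ma
#' @param ma.id Vector indexing the meta-analyses (one value per study row);
#'   groups are taken in order of first appearance.
#' @param data Optional data frame with columns \code{ma.id, e0, n0, e1, n1}.
#' @return An object of classes \code{"frag_multi"} and \code{"frag_mas"}:
#'   per-MA vectors \code{FI}, \code{FQ}, \code{dir} and a per-direction
#'   \code{summary}.
#' @export
frag_mas <- function(e0, n0, e1, n1, ma.id, data = NULL,
                     measure = c("OR", "RR", "RD"), alpha = 0.05,
                     mod.dir = c("both", "left", "right", "one"),
                     null.OR = 1, null.RR = 1, null.RD = 0,
                     tau2_method = c("DL", "REML", "FE"),
                     ci_method = c("z", "hksj"), incr = 0.5,
                     max_iter = NULL) {
  if (!is.null(data)) {
    if (!"ma.id" %in% names(data)) stop("`data` must contain column ma.id")
    ma.id <- data$ma.id
    cnt <- .resolve_counts(NULL, NULL, NULL, NULL, data)
  } else cnt <- list(e0 = e0, n0 = n0, e1 = e1, n1 = n1)
  stopifnot(length(ma.id) == length(cnt$e0))
  ids <- unique(ma.id)
  n_ma <- length(ids)
  FI <- FQ <- rep(NA_real_, n_ma)
  dir <- rep(NA_character_, n_ma)
  errors <- stats::setNames(rep(NA_character_, n_ma), ids)
  results <- stats::setNames(vector("list", n_ma), ids)
  for (k in seq_len(n_ma)) {
    sel <- ma.id == ids[k]
    res <- tryCatch(
      frag_ma(cnt$e0[sel], cnt$n0[sel], cnt$e1[sel], cnt$n1[sel],
              measure = measure, alpha = alpha, mod.dir = mod.dir,
              null.OR = null.OR, null.RR = null.RR, null.RD = null.RD,
              tau2_method = tau2_method, ci_method = ci_method,
              incr = incr, max_iter = max_iter),
      error = function(e) conditionMessage(e))
    if (is.character(res)) { errors[k] <- res; next }
    FI[k] <- res$FI; FQ[k] <- res$FQ; dir[k] <- res$dir
    results[[k]] <- res
  }
  out <- list(ma.ids = ids, alpha = alpha, FI = FI, FQ = FQ, dir = dir,
              summary = .frag_multi_summary(FI, FQ, dir),
              errors = errors[!is.na(errors)], results = results,
              methods = "MA")
  class(out) <- c("frag_mas", "frag_multi")
  out
}

#' @export
print.frag_mas <- function(x, digits = 2, ...) {
  cat(sprintf("Fragility of %d pairwise meta-analyses (alpha = %s)\n",
              length(x$ma.ids), format(x$alpha)))
  for (d in c("sig2nonsig", "nonsig2sig")) {
    s <- x$summary[[d]]
    if (s$n == 0) next
    cat(sprintf(
      "  %s (n = %d): FI median %s [IQR %s-%s, range %s-%s]%s\n",
      ifelse(d == "sig2nonsig", "originally significant    ",
             "originally non-significant"),
      s$n, format(s$FI.median), format(round(s$FI.iqr[1], digits)),
      format(round(s$FI.iqr[2], digits)), format(s$FI.range[1]),
      format(s$FI.range[2]),
      if (s$n.FI.NA > 0) sprintf(" (%d NA)", s$n.FI.NA) else ""))
  }
  if (length(x$errors))
    cat(sprintf("  %d MA(s) failed: %s\n", length(x$errors),
                paste(names(x$errors), collapse = ", ")))
  invisible(x)
}
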