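#' Construct a 2x2 contingency table for a two-group binary outcome
#'
#' A trial comparing two treatment groups (labelled 0 and 1) with a binary
#' outcome is summarised by the event counts and sample sizes of the two
#' groups.  All fragility computations in this package start from this
#' representation.
#'
#' @param e0,n0 Event count and sample size in group 0.
#' @param e1,n1 Event count and sample size in group 1.
#'
#' @return An object of class \code{"frag_table"}: a list with elements
#'   \code{e0}, \code{n0}, \code{e1}, \code{n1}.
#'
#' @examples
#' frag_table(7, 107, 12, 105)
#' @export
frag_table <- function(e0, n0, e1, n1) {
  check_count <- function(e, n, grp) {
    if (length(e) != 1L || length(n) != 1L || is.na(e) || is.na(n))
      stop("counts for group ", grp, " must be single non-missing numbers")
    if (n < 1 || n != round(n)) stop("n", grp, " must be a positive integer")
    if (e < 0 || e > n || e != round(e))
      stop("e", grp, " must be an integer in [0, n", grp, "]")
  }
  check_count(e0, n0, 0L)
  check_count(e1, n1, 1L)
  structure(list(e0 = as.numeric(e0), n0 = as.numeric(n0),
                 e1 = as.numeric(e1), n1 = as.numeric(n1)),
            class = "frag_table")
}

#' @export
print.frag_table <- function(x, ...) {
  m <- matrix(c(x$e0, x$n0 - x$e0, x$n0, x$e1, x$n1 - x$e1, x$n1),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("group 0", "group 1"),
                              c("event", "non-event", "n")))
  print(m)
  invisible(x)
}

#' Apply an event-status modification to a 2x2 table
#'
#' An event-status modification changes \code{f0} non-events to events in
#' group 0 and \code{f1} in group 1 (negative values change events back to
#' non-events).  Sample sizes are never altered.
#'
#' @param table A \code{\link{frag_table}}.
#' @param f0,f1 Signed integer changes to the event counts of groups 0 and 1.
#'   Legal values satisfy \code{-e_k <= f_k <= n_k - e_k}.
#'
#' @return The modified \code{frag_table}.
#' @examples
#' apply_modification(frag_table(7, 107, 12, 105), f0 = 6, f1 = 0)
#' @export
apply_modification <- function(table, f0 = 0, f1 = 0) {
  stopifnot(inherits(table, "frag_table"))
  if (f0 != round(f0) || f1 != round(f1))
    stop("modifications must be integers")
  if (f0 < -table$e0 || f0 > table$n0 - table$e0)
    stop("modification f0 = ", f0, " out of range [", -table$e0, ", ",
         table$n0 - table$e0, "] for group 0")
  if (f1 < -table$e1 || f1 > table$n1 - table$e1)
    stop("modification f1 = ", f1, " out of range [", -table$e1, ", ",
         table$n1 - table$e1, "] for group 1")
  frag_table(table$e0 + f0, table$n0, table$e1 + f1, table$n1)
}

#' Continuity correction for zero cells
#'
#' If any of the four cells of the 2x2 table (events or non-events in either
#' group) is zero, \code{incr} is added to all four cells before odds-ratio,
#' relative-risk or risk-difference estimation; the effective group sizes
#' become \code{n_k + 2 * incr}.  Tables without zero cells are returned
#' unchanged.  Fisher's exact test and the chi-squared test never use the
#' correction.
#'
#' @param table A \code{\link{frag_table}}.
#' @param incr Positive increment, by default 0.5.
#'
#' @return A list with numeric cells \code{e0}, \code{n0}, \code{e1},
#'   \code{n1} (possibly non-integer) and a flag \code{corrected}.
#' @export
continuity_correct <- function(table, incr = 0.5) {
  stopifnot(inherits(table, "frag_table"), incr > 0)
  zero <- table$e0 == 0 || table$e0 == table$n0 ||
    table$e1 == 0 || table$e1 == table$n1
  if (zero)
    list(e0 = table$e0 + incr, n0 = table$n0 + 2 * incr,
         e1 = table$e1 + incr, n1 = table$n1 + 2 * incr, corrected = TRUE)
  else
    list(e0 = table$e0, n0 = table$n0, e1 = table$e1, n1 = table$n1,
         corrected = FALSE)
}

## ---- Fisher's exact test -------------------------------------------------

## Two-sided exact conditional p with the probability-mass rule: the sum of
## hypergeometric probabilities of all tables (margins fixed) whose
## probability does not exceed that of the observed table, with the same
## relative tolerance used by stats::fisher.test.
.fisher_p_scalar <- function(e0, n0, e1, n1) {
  t <- e0 + e1
  if (t == 0 || t == n0 + n1) return(1)
  support <- max(0, t - n0):min(n1, t)
  d <- stats::dhyper(support, n1, n0, t)
  min(1, sum(d[d <= d[support == e1] * (1 + 1e-7)]))
}

#' Fisher's exact test p-value for a 2x2 table
#'
#' Two-sided exact conditional p-value based on the hypergeometric
#' distribution with both margins fixed, using the probability-mass rule of
#' standard statistical software (the sum of probabilities of all tables no
#' more probable than the observed one).  Degenerate margins (no events or no
#' non-events in total) give p = 1.
#'
#' @param table A \code{\link{frag_table}}.
#' @return A p-value in (0, 1].
#' @examples
#' fisher_p(frag_table(0, 3, 3, 3))  # 0.1
#' @export
fisher_p <- function(table) {
  stopifnot(inherits(table, "frag_table"))
  .fisher_p_scalar(table$e0, table$n0, table$e1, table$n1)
}

## Full matrix of two-sided Fisher p-values for fixed group sizes:
## M[a0 + 1, a1 + 1] = p of table (a0, n0, a1, n1).  Computed per margin
## total with a sort/cumsum pass, so the whole (n0+1) x (n1+1) landscape
## costs O((n0 + n1) * min(n0, n1) log n) rather than one enumeration per
## cell.  Used by the exhaustive fragility search and the plots.
.fisher_p_matrix <- function(n0, n1) {
  M <- matrix(NA_real_, n0 + 1, n1 + 1)
  for (t in 0:(n0 + n1)) {
    support <- max(0, t - n0):min(n1, t)
    d <- stats::dhyper(support, n1, n0, t)
    o <- order(d)
    cs <- cumsum(d[o])
    p <- numeric(length(d))
    ## rank of the largest sorted value <= d * (1 + tol)
    p[o] <- cs[findInterval(d[o] * (1 + 1e-7), d[o])]
    p <- pmin(p, 1)
    M[cbind((t - support) + 1, support + 1)] <- p
  }
  M
}

## ---- chi-squared test ----------------------------------------------------

## Vectorised Pearson chi-squared p over event-count vectors (margins from
## scalars n0, n1).  Mirrors stats::chisq.test for 2x2 tables, including its
## capped Yates correction.  Zero margins give p = 1.
.chisq_p_vec <- function(e0, n0, e1, n1, yates = TRUE) {
  n <- n0 + n1
  t <- e0 + e1
  ## X^2 = n (ad - bc)^2 / (r1 r2 c1 c2); Yates subtracts min(n/2, |ad-bc|/n)
  ## from |p1 - p0| scaled form, equivalently from |ad - bc| / n.
  num <- abs(e1 * (n0 - e0) - e0 * (n1 - e1))
  if (yates) num <- pmax(0, num - n / 2)
  den <- as.numeric(n0) * n1 * t * (n - t)
  stat <- ifelse(den == 0, NA_real_, n * num^2 / den)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  ifelse(den == 0, 1, p)
}

#' Chi-squared test p-value for a 2x2 table
#'
#' Pearson chi-squared statistic with 1 degree of freedom; p-value from the
#' upper tail of the asymptotic chi-squared distribution.  The Yates
#' continuity correction is applied by default, matching the default of
#' \code{\link[stats]{chisq.test}} for 2x2 tables.  A table with a zero
#' margin yields p = 1 with a warning.
#'
#' @param table A \code{\link{frag_table}}.
#' @param yates Apply the Yates continuity correction?  Default \code{TRUE}.
#' @return A p-value in (0, 1].
#' @export
chisq_p <- function(table, yates = TRUE) {
  stopifnot(inherits(table, "frag_table"))
  t <- table$e0 + table$e1
  if (t == 0 || t == table$n0 + table$n1) {
    warning("degenerate margin: chi-squared p-value set to 1")
    return(1)
  }
  .chisq_p_vec(table$e0, table$n0, table$e1, table$n1, yates = yates)
}

## ---- effect sizes and Wald tests ----------------------------------------

## Vectorised effect estimate y and standard error s on the analysis scale
## (log for OR/RR, probability scale for RD).  The continuity correction is
## re-evaluated per table: any zero cell adds `incr` to all four cells.
.effect_vec <- function(e0, n0, e1, n1, measure, incr = 0.5) {
  zero <- e0 == 0 | e0 == n0 | e1 == 0 | e1 == n1
  a0 <- e0 + incr * zero; m0 <- n0 + 2 * incr * zero
  a1 <- e1 + incr * zero; m1 <- n1 + 2 * incr * zero
  if (measure == "OR") {
    y <- log((a1 / (m1 - a1)) / (a0 / (m0 - a0)))
    s <- sqrt(1 / a0 + 1 / (m0 - a0) + 1 / a1 + 1 / (m1 - a1))
  } else if (measure == "RR") {
    y <- log((a1 / m1) / (a0 / m0))
    s <- sqrt(1 / a0 + 1 / a1 - 1 / m0 - 1 / m1)
  } else if (measure == "RD") {
    y <- a1 / m1 - a0 / m0
    s <- sqrt(a0 * (m0 - a0) / m0^3 + a1 * (m1 - a1) / m1^3)
  } else stop("unknown effect measure: ", measure)
  list(y = y, se = s, corrected = zero)
}

#' Estimate a comparative effect size from a 2x2 table
#'
#' Computes the point estimate and its large-sample standard error for the
#' comparison of group 1 vs. group 0: the log odds ratio, log relative risk,
#' or risk difference.  If the table has a zero cell, the continuity
#' correction (\code{\link{continuity_correct}}) is applied first, so the
#' estimate and standard error are always finite.
#'
#' @param table A \code{\link{frag_table}}.
#' @param measure One of \code{"OR"}, \code{"RR"}, \code{"RD"}.
#' @param incr Continuity-correction increment (default 0.5).
#'
#' @return A list of class \code{"effect_estimate"} with elements
#'   \code{measure}, \code{y}, \code{se}, \code{corrected}.
#' @examples
#' effect_estimate(frag_table(7, 107, 12, 105), "OR")
#' @export
effect_estimate <- function(table, measure = c("OR", "RR", "RD"), incr = 0.5) {
  stopifnot(inherits(table, "frag_table"))
  measure <- match.arg(measure)
  est <- .effect_vec(table$e0, table$n0, table$e1, table$n1, measure, incr)
  structure(list(measure = measure, y = est$y, se = est$se,
                 corrected = est$corrected),
            class = "effect_estimate")
}

#' Wald test p-value from an effect estimate
#'
#' The estimated log OR, log RR, and RD approximately follow normal
#' distributions, so the p-value is \code{2 * pnorm(-|y - null| / se)}
#' (two-sided) or \code{pnorm(-|y - null| / se)} (one-sided).  The null value
#' must be given on the analysis scale (log scale for OR and RR).  Note that
#' the one-sided variant always takes the tail in the direction of the
#' observed deviation and is therefore exactly half the two-sided p; it is
#' not a directional (pre-specified-sign) test.
#'
#' @param est An \code{\link{effect_estimate}}.
#' @param null Null value on the analysis scale (default 0, i.e. OR = RR = 1
#'   or RD = 0).
#' @param alternative \code{"two.sided"} (default) or \code{"one.sided"}.
#' @return A p-value in (0, 1].
#' @export
wald_p <- function(est, null = 0, alternative = c("two.sided", "one.sided")) {
  stopifnot(inherits(est, "effect_estimate"), est$se > 0)
  alternative <- match.arg(alternative)
  p1 <- stats::pnorm(-abs(est$y - null) / est$se)
  if (alternative == "two.sided") 2 * p1 else p1
}

## Canonical internal method ids and their user-facing labels.
.frag_methods <- c(fisher = "Fisher", chisq = "chisq",
                   OR = "OR", RR = "RR", RD = "RD")

.match_methods <- function(methods) {
  ids <- names(.frag_methods)
  m <- ids[match(tolower(methods), tolower(ids))]
  if (anyNA(m)) stop("unknown method(s): ",
                     paste(methods[is.na(m)], collapse = ", "),
                     "; available: ", paste(ids, collapse = ", "))
  m
}

#' Association p-value for a 2x2 table by any supported method
#'
#' Dispatches to Fisher's exact test, the chi-squared test, or a Wald test on
#' the OR, RR or RD scale.  Fisher and chi-squared p-values are always
#' two-sided; the effect-size tests honour \code{alternative}.
#'
#' @param table A \code{\link{frag_table}}.
#' @param method One of \code{"fisher"}, \code{"chisq"}, \code{"OR"},
#'   \code{"RR"}, \code{"RD"} (case-insensitive).
#' @param alternative \code{"two.sided"} or \code{"one.sided"} (effect-size
#'   methods only).
#' @param null.OR,null.RR,null.RD Null values on the natural scales.
#' @param yates Yates correction for the chi-squared test.
#' @param incr Continuity-correction increment for effect-size methods.
#' @return A p-value in (0, 1].
#' @export
p_value <- function(table, method = "fisher",
                    alternative = c("two.sided", "one.sided"),
                    null.OR = 1, null.RR = 1, null.RD = 0,
                    yates = TRUE, incr = 0.5) {
  stopifnot(inherits(table, "frag_table"))
  method <- .match_methods(method)[1L]
  alternative <- match.arg(alternative)
  switch(method,
    fisher = fisher_p(table),
    chisq  = chisq_p(table, yates = yates),
    OR = wald_p(effect_estimate(table, "OR", incr), log(null.OR), alternative),
    RR = wald_p(effect_estimate(table, "RR", incr), log(null.RR), alternative),
    RD = wald_p(effect_estimate(table, "RD", incr), null.RD, alternative))
}

## Vectorised p over event-count vectors for one method; fisher goes through
## a supplied precomputed matrix when available (exhaustive mode) or the
## scalar routine otherwise.
.p_value_vec <- function(e0, n0, e1, n1, method, alternative = "two.sided",
                         null.OR = 1, null.RR = 1, null.RD = 0,
                         yates = TRUE, incr = 0.5, fisher_matrix = NULL) {
  if (method == "fisher") {
    if (!is.null(fisher_matrix))
      return(fisher_matrix[cbind(e0 + 1, e1 + 1)])
    m <- max(length(e0), length(e1))
    e0 <- rep_len(e0, m); e1 <- rep_len(e1, m)
    return(vapply(seq_len(m), function(i)
      .fisher_p_scalar(e0[i], n0, e1[i], n1), numeric(1)))
  }
  if (method == "chisq")
    return(.chisq_p_vec(e0, n0, e1, n1, yates = yates))
  est <- .effect_vec(e0, n0, e1, n1, method, incr)
  null <- switch(method, OR = log(null.OR), RR = log(null.RR), RD = null.RD)
  p1 <- stats::pnorm(-abs(est$y - null) / est$se)
  if (alternative == "two.sided") pmin(1, 2 * p1) else p1
}
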