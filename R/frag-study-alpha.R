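## Fragility of a study across a grid of significance levels, and batch
## assessment of many studies.

#' Equally spaced grid of significance levels
#' @noRd
.alpha_grid <- function(alpha.from, alpha.to, alpha.breaks) {
  stopifnot(alpha.from > 0, alpha.to < 1, alpha.from < alpha.to,
            alpha.breaks >= 2)
  seq(alpha.from, alpha.to, length.out = alpha.breaks)
}

## FI at every level of an alpha grid for one method, sharing work across
## levels: each shell of modifications is evaluated once and only its
## minimum and maximum p are needed to decide, for every alpha, whether the
## shell contains a significance flip.
.fi_sweep_core <- function(e0, n0, e1, n1, method, alphas, r0, r1, opts) {
  p0 <- .p_value_vec(e0, n0, e1, n1, method, opts$alternative,
                     opts$null.OR, opts$null.RR, opts$null.RD,
                     opts$yates, opts$incr)
  sig0 <- p0 < alphas
  FI <- rep(NA_real_, length(alphas))
  mmax <- max(abs(r0)) + max(abs(r1))
  if (mmax >= 1) for (m in seq_len(mmax)) {
    cells <- .shell_cells(m, r0, r1)
    if (is.null(cells)) next
    p <- .p_value_vec(e0 + cells[, 1], n0, e1 + cells[, 2], n1, method,
                      opts$alternative, opts$null.OR, opts$null.RR,
                      opts$null.RD, opts$yates, opts$incr)
    pmn <- min(p); pmx <- max(p)
    hit <- is.na(FI) & ((sig0 & pmx >= alphas) | (!sig0 & pmn < alphas))
    FI[hit] <- m
    if (!anyNA(FI)) break
  }
  list(FI = FI, dir = ifelse(sig0, "sig2nonsig", "nonsig2sig"), p0 = p0)
}

#' Fragility of a study at multiple significance levels
#'
#' Evaluates the fragility index over \code{alpha.breaks} equally spaced
#' significance levels between \code{alpha.from} and \code{alpha.to} and
#' averages them.  The average FI approximates the normalised area under the
#' step function FI(alpha) over the range, a single-number summary of
#' fragility that does not depend on one conventional level.  Levels at which
#' the FI is undefined (no attainable flip) are excluded from the average and
#' counted in \code{n.NA}.
#'
#' @inheritParams frag_study
#' @param alpha.from,alpha.to,alpha.breaks Smallest level, largest level, and
#'   number of equally spaced levels (endpoints included).
#'
#' @return An object of classes \code{"frag_alpha"} and
#'   \code{"frag_study_alpha"}: a list with \code{alphas}, per-method
#'   matrices \code{FI}, \code{FQ} and \code{dir} (levels x methods),
#'   per-method averages \code{FI.avg}, \code{FQ.avg}, NA-level counts
#'   \code{n.NA}, and the original p-values \code{p0}.
#' @export
frag_study_alpha <- function(e0, n0, e1, n1, data = NULL,
                             methods = c("fisher", "chisq", "OR", "RR", "RD"),
                             modify0 = "both", modify1 = "both",
                             alpha.from = 0.005, alpha.to = 0.05,
                             alpha.breaks = 100,
                             alternative = "two.sided",
                             null.OR = 1, null.RR = 1, null.RD = 0,
                             yates = TRUE, incr = 0.5) {
  cnt <- .resolve_counts(e0, n0, e1, n1, data)
  tab <- frag_table(cnt$e0, cnt$n0, cnt$e1, cnt$n1)
  methods <- .match_methods(methods)
  opts <- .study_opts(alternative, null.OR, null.RR, null.RD, yates, incr)
  alphas <- .alpha_grid(alpha.from, alpha.to, alpha.breaks)
  r0 <- .mod_range(tab$e0, tab$n0, modify0)
  r1 <- .mod_range(tab$e1, tab$n1, modify1)
  lab <- .frag_methods[methods]
  FI <- dir <- matrix(NA, length(alphas), length(methods),
                      dimnames = list(NULL, lab))
  p0 <- stats::setNames(rep(NA_real_, length(methods)), lab)
  for (k in seq_along(methods)) {
    sw <- .fi_sweep_core(tab$e0, tab$n0, tab$e1, tab$n1, methods[k], alphas,
                         r0, r1, opts)
    FI[, k] <- sw$FI
    dir[, k] <- sw$dir
    p0[k] <- sw$p0
  }
  FQ <- fq(FI, tab$n0 + tab$n1)
  out <- list(table = tab, methods = lab, alphas = alphas, opts = opts,
              p0 = p0, FI = FI, FQ = FQ, dir = dir,
              FI.avg = colMeans(FI, na.rm = TRUE),
              FQ.avg = colMeans(FQ, na.rm = TRUE),
              n.NA = colSums(is.na(FI)),
              n.total = tab$n0 + tab$n1)
  class(out) <- c("frag_study_alpha", "frag_alpha")
  out
}

#' @export
print.frag_study_alpha <- function(x, digits = 3, ...) {
  cat("Fragility of an individual study at multiple significance levels\n")
  cat(sprintf("  group 0: %d/%d events; group 1: %d/%d events\n",
              as.integer(x$table$e0), as.integer(x$table$n0),
              as.integer(x$table$e1), as.integer(x$table$n1)))
  cat(sprintf("  %d levels in [%s, %s]\n", length(x$alphas),
              format(min(x$alphas)), format(max(x$alphas))))
  cat("\n  p-values:\n"); print(round(x$p0, digits))
  cat("\n  average FI (levels with NA excluded):\n")
  print(round(x$FI.avg, 2))
  cat("\n  average FQ (%):\n"); print(round(x$FQ.avg, digits))
  if (any(x$n.NA > 0)) { cat("\n  NA levels:\n"); print(x$n.NA) }
  invisible(x)
}

#' Fragility of a collection of individual studies
#'
#' Applies \code{\link{frag_study}} to every row of a study table and
#' summarises the fragility indices and quotients by the direction of the
#' significance change.  Rows that fail (for example, degenerate tables)
#' are recorded and do not interrupt the batch.
#'
#' @inheritParams frag_study
#' @param e0,n0,e1,n1 Vectors of event counts and sample sizes, one entry per
#'   study, or columns taken from \code{data}.
#' @param data Optional data frame with columns \code{e0, n0, e1, n1}.
#'
#' @return An object of classes \code{"frag_multi"} and
#'   \code{"frag_studies"}: matrices \code{p0}, \code{FI}, \code{FQ},
#'   \code{dir} (studies x methods) and a per-method, per-direction
#'   \code{summary} (count, median, IQR, range).
#' @export
frag_studies <- function(e0, n0, e1, n1, data = NULL,
                         methods = c("fisher", "chisq", "OR", "RR", "RD"),
                         modify0 = "both", modify1 = "both", alpha = 0.05,
                         alternative = "two.sided",
                         null.OR = 1, null.RR = 1, null.RD = 0,
                         yates = TRUE, incr = 0.5) {
  cnt <- .resolve_counts(e0, n0, e1, n1, data)
  ns <- length(cnt$e0)
  stopifnot(ns >= 1, length(cnt$n0) == ns, length(cnt$e1) == ns,
            length(cnt$n1) == ns)
  methods <- .match_methods(methods)
  lab <- .frag_methods[methods]
  p0 <- FI <- FQ <- matrix(NA_real_, ns, length(methods),
                           dimnames = list(NULL, lab))
  dir <- matrix(NA_character_, ns, length(methods),
                dimnames = list(NULL, lab))
  errors <- stats::setNames(rep(NA_character_, ns), seq_len(ns))
  for (i in seq_len(ns)) {
    res <- tryCatch(
      frag_study(cnt$e0[i], cnt$n0[i], cnt$e1[i], cnt$n1[i],
                 methods = methods, modify0 = modify0, modify1 = modify1,
                 alpha = alpha, alternative = alternative, null.OR = null.OR,
                 null.RR = null.RR, null.RD = null.RD, yates = yates,
                 incr = incr),
      error = function(e) conditionMessage(e))
    if (is.character(res)) { errors[i] <- res; next }
    p0[i, ] <- res$p0; FI[i, ] <- res$FI; FQ[i, ] <- res$FQ
    dir[i, ] <- res$dir
  }
  summ <- lapply(stats::setNames(seq_along(methods), lab), function(k)
    .frag_multi_summary(FI[, k], FQ[, k], dir[, k]))
  out <- list(methods = lab, alpha = alpha, p0 = p0, FI = FI, FQ = FQ,
              dir = dir, summary = summ,
              errors = errors[!is.na(errors)], n.studies = ns)
  class(out) <- c("frag_studies", "frag_multi")
  out
}

## Median / IQR / range of FI and FQ within each direction stratum.
.frag_multi_summary <- function(FI, FQ, dir) {
  strat <- function(d) {
    sel <- !is.na(dir) & dir == d
    def <- sel & !is.na(FI)
    list(n = sum(sel), n.FI.NA = sum(sel) - sum(def),
         FI.median = stats::median(FI[def]),
         FI.range = if (any(def)) range(FI[def]) else c(NA, NA),
         FI.iqr = if (any(def))
           stats::quantile(FI[def], c(0.25, 0.75), names = FALSE)
         else c(NA, NA),
         FQ.median = stats::median(FQ[def]),
         FQ.range = if (any(def)) range(FQ[def]) else c(NA, NA),
         FQ.iqr = if (any(def))
           stats::quantile(FQ[def], c(0.25, 0.75), names = FALSE)
         else c(NA, NA))
  }
  list(sig2nonsig = strat("sig2nonsig"), nonsig2sig = strat("nonsig2sig"))
}

#' @export
print.frag_studies <- function(x, digits = 2, ...) {
  cat(sprintf("Fragility of %d individual studies (alpha = %s)\n",
              x$n.studies, format(x$alpha)))
  for (m in x$methods) {
    cat(sprintf("\n  method %s:\n", m))
    for (d in c("sig2nonsig", "nonsig2sig")) {
      s <- x$summary[[m]][[d]]
      if (s$n == 0) next
      cat(sprintf(
        "    %s (n = %d): FI median %s [IQR %s-%s, range %s-%s]%s\n",
        ifelse(d == "sig2nonsig", "originally significant    ",
               "originally non-significant"),
        s$n, format(s$FI.median), format(round(s$FI.iqr[1], digits)),
        format(round(s$FI.iqr[2], digits)), format(s$FI.range[1]),
        format(s$FI.range[2]),
        if (s$n.FI.NA > 0) sprintf(" (%d NA)", s$n.FI.NA) else ""))
    }
  }
  if (length(x$errors))
    cat(sprintf("\n  %d study(ies) failed: rows %s\n", length(x$errors),
                paste(names(x$errors), collapse = ", ")))
  invisible(x)
}

#' @export
print.frag_alpha <- function(x, digits = 3, ...) {
  cat(sprintf("Fragility at %d significance levels in [%s, %s]\n",
              length(x$alphas), format(min(x$alphas)),
              format(max(x$alphas))))
  cat("  average FI (levels with NA excluded):\n")
  print(round(x$FI.avg, 2))
  cat("  average FQ (%):\n")
  print(round(x$FQ.avg, digits))
  if (any(x$n.NA > 0)) { cat("  NA levels:\n"); print(x$n.NA) }
  invisible(x)
}
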