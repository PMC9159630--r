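## Fragility of an individual 2x2 trial: shell-by-shell minimal search,
## exhaustive p landscape, restricted (single-group) indices.

## Legal modification range for one group under a directional constraint.
.mod_range <- function(e, n, modify) {
  modify <- match.arg(modify, c("both", "increase", "decrease", "none"))
  switch(modify,
         both     = c(-e, n - e),
         increase = c(0, n - e),
         decrease = c(-e, 0),
         none     = c(0, 0))
}

## All (f0, f1) on the shell |f0| + |f1| = m inside the ranges, ordered by
## f0 ascending then f1 ascending (deterministic reporting order).
.shell_cells <- function(m, r0, r1) {
  f0 <- seq.int(max(-m, r0[1]), min(m, r0[2]))
  res <- lapply(f0, function(f) {
    rem <- m - abs(f)
    f1 <- unique(c(-rem, rem))
    f1 <- f1[f1 >= r1[1] & f1 <= r1[2]]
    if (length(f1)) cbind(f0 = f, f1 = sort(f1)) else NULL
  })
  do.call(rbind, res)
}

## Minimal-modification search for one method.  Walks shells of increasing
## total modification size and stops at the first shell containing a
## significance flip.  Returns FI (NA if no flip is attainable), the set of
## minimal modifications, and the original p-value.
.fi_search_core <- function(e0, n0, e1, n1, method, alpha, r0, r1, opts) {
  p0 <- .p_value_vec(e0, n0, e1, n1, method, opts$alternative,
                     opts$null.OR, opts$null.RR, opts$null.RD,
                     opts$yates, opts$incr)
  sig0 <- p0 < alpha
  mmax <- max(abs(r0)) + max(abs(r1))
  if (mmax >= 1) for (m in seq_len(mmax)) {
    cells <- .shell_cells(m, r0, r1)
    if (is.null(cells)) next
    p <- .p_value_vec(e0 + cells[, 1], n0, e1 + cells[, 2], n1, method,
                      opts$alternative, opts$null.OR, opts$null.RR,
                      opts$null.RD, opts$yates, opts$incr)
    flip <- if (sig0) p >= alpha else p < alpha
    if (any(flip))
      return(list(FI = m, mods = cells[flip, , drop = FALSE],
                  p.mods = p[flip], p0 = p0, sig0 = sig0))
  }
  list(FI = NA_integer_, mods = NULL, p.mods = NULL, p0 = p0, sig0 = sig0)
}

## Exhaustive landscape: p for every legal (f0, f1); FI and all argmins.
.fi_exhaustive_core <- function(e0, n0, e1, n1, method, alpha, r0, r1, opts,
                                cell_cap = 1e6) {
  f0 <- seq.int(r0[1], r0[2]); f1 <- seq.int(r1[1], r1[2])
  ncell <- length(f0) * length(f1)
  if (ncell > cell_cap)
    stop("exhaustive landscape would need ", ncell, " cells (cap ",
         format(cell_cap, scientific = FALSE),
         "); use the shell search (all = FALSE) or raise cell_cap")
  fisher_matrix <- if (method == "fisher") .fisher_p_matrix(n0, n1) else NULL
  cells <- cbind(f0 = rep(f0, times = length(f1)),
                 f1 = rep(f1, each = length(f0)))
  p <- .p_value_vec(e0 + cells[, 1], n0, e1 + cells[, 2], n1, method,
                    opts$alternative, opts$null.OR, opts$null.RR,
                    opts$null.RD, opts$yates, opts$incr,
                    fisher_matrix = fisher_matrix)
  grid <- matrix(p, nrow = length(f0), ncol = length(f1),
                 dimnames = list(f0 = f0, f1 = f1))
  p0 <- grid[as.character(0), as.character(0)]
  sig0 <- p0 < alpha
  dist <- abs(cells[, 1]) + abs(cells[, 2])
  flip <- if (sig0) p >= alpha else p < alpha
  flip <- flip & dist > 0
  if (any(flip)) {
    FI <- min(dist[flip])
    sel <- which(flip & dist == FI)
    sel <- sel[order(cells[sel, 1], cells[sel, 2])]
    mods <- cells[sel, , drop = FALSE]
    p.mods <- p[sel]
  } else {
    FI <- NA_integer_; mods <- NULL; p.mods <- NULL
  }
  list(FI = FI, mods = mods, p.mods = p.mods, p0 = p0, sig0 = sig0,
       grid = grid)
}

## FI restricted to a single group: 1-D scan over f_k, other group fixed 0.
.fi_restricted_core <- function(e0, n0, e1, n1, method, alpha, r, group,
                                opts) {
  p0 <- .p_value_vec(e0, n0, e1, n1, method, opts$alternative,
                     opts$null.OR, opts$null.RR, opts$null.RD,
                     opts$yates, opts$incr)
  sig0 <- p0 < alpha
  f <- setdiff(seq.int(r[1], r[2]), 0)
  if (!length(f)) return(NA_integer_)
  p <- if (group == 0)
    .p_value_vec(e0 + f, n0, e1, n1, method, opts$alternative,
                 opts$null.OR, opts$null.RR, opts$null.RD,
                 opts$yates, opts$incr)
  else
    .p_value_vec(e0, n0, e1 + f, n1, method, opts$alternative,
                 opts$null.OR, opts$null.RR, opts$null.RD,
                 opts$yates, opts$incr)
  flip <- if (sig0) p >= alpha else p < alpha
  if (any(flip)) min(abs(f[flip])) else NA_integer_
}

.study_opts <- function(alternative = "two.sided", null.OR = 1, null.RR = 1,
                        null.RD = 0, yates = TRUE, incr = 0.5) {
  alternative <- match.arg(alternative, c("two.sided", "one.sided"))
  stopifnot(null.OR > 0, null.RR > 0, null.RD > -1, null.RD < 1, incr > 0)
  list(alternative = alternative, null.OR = null.OR, null.RR = null.RR,
       null.RD = null.RD, yates = yates, incr = incr)
}

## Resolve (e0, n0, e1, n1) either from a data frame row(s) or from vectors.
.resolve_counts <- function(e0, n0, e1, n1, data) {
  if (!is.null(data)) {
    need <- c("e0", "n0", "e1", "n1")
    if (!all(need %in% names(data)))
      stop("`data` must contain columns ", paste(need, collapse = ", "))
    list(e0 = data$e0, n0 = data$n0, e1 = data$e1, n1 = data$n1)
  } else list(e0 = e0, n0 = n0, e1 = e1, n1 = n1)
}

#' Fragility of a single two-group clinical study
#'
#' Computes the fragility index (FI) of a 2x2 trial: the minimal number of
#' event-status modifications \code{|f0| + |f1|} that alters statistical
#' significance at level \code{alpha}, together with the fragility quotient
#' (FQ, the FI as a percentage of the total sample size), the group-restricted
#' indices FI0 and FI1, and all minimal modification sets.  With
#' \code{all = TRUE} the p-value for every legal modification is retained so
#' the significance landscape can be plotted.
#'
#' When the original result is significant (\code{p < alpha}) the FI counts
#' modifications needed to lose significance, and conversely.  If no legal
#' modification can alter significance the FI is \code{NA}.  The bound
#' \code{1 <= FI <= min(FI0, FI1)} holds whenever all three are defined.
#'
#' @param e0,n0,e1,n1 Event counts and sample sizes of groups 0 and 1, or
#'   column values taken from \code{data}.
#' @param data Optional one-row data frame with columns \code{e0, n0, e1, n1}.
#' @param all If \code{TRUE}, evaluate every legal modification and keep the
#'   p-value grid (memory-capped by \code{cell_cap}); otherwise use the
#'   shell-by-shell minimal search.
#' @param methods Character vector from \code{"fisher"}, \code{"chisq"},
#'   \code{"OR"}, \code{"RR"}, \code{"RD"}.
#' @param modify0,modify1 Allowed modification direction per group:
#'   \code{"both"}, \code{"increase"}, \code{"decrease"}, or \code{"none"}.
#' @param alpha Significance level (p = alpha counts as non-significant).
#' @param alternative \code{"two.sided"} or \code{"one.sided"} (effect-size
#'   methods only).
#' @param null.OR,null.RR,null.RD Null values of the effect measures.
#' @param yates Yates correction for the chi-squared test.
#' @param incr Continuity-correction increment.
#' @param cell_cap Maximum number of landscape cells for \code{all = TRUE}.
#'
#' @return An object of class \code{"frag_study"} (and \code{"frag_study_all"}
#'   if \code{all = TRUE}): a list with the per-method p-values \code{p0},
#'   \code{FI}, \code{FQ}, \code{FI0}, \code{FI1}, direction \code{dir}
#'   (\code{"sig2nonsig"} or \code{"nonsig2sig"}), minimal modification sets
#'   \code{mods}, modification ranges, and (if \code{all}) the p-value grids.
#'
#' @examples
#' x <- frag_study(0, 3, 3, 3, methods = "fisher", alpha = 0.11)
#' x$FI  # 1
#' @export
frag_study <- function(e0, n0, e1, n1, data = NULL, all = FALSE,
                       methods = c("fisher", "chisq", "OR", "RR", "RD"),
                       modify0 = "both", modify1 = "both", alpha = 0.05,
                       alternative = "two.sided",
                       null.OR = 1, null.RR = 1, null.RD = 0,
                       yates = TRUE, incr = 0.5, cell_cap = 1e6) {
  cnt <- .resolve_counts(e0, n0, e1, n1, data)
  tab <- frag_table(cnt$e0, cnt$n0, cnt$e1, cnt$n1)
  stopifnot(alpha > 0, alpha < 1)
  methods <- .match_methods(methods)
  opts <- .study_opts(alternative, null.OR, null.RR, null.RD, yates, incr)
  r0 <- .mod_range(tab$e0, tab$n0, modify0)
  r1 <- .mod_range(tab$e1, tab$n1, modify1)

  FI <- FI0 <- FI1 <- p0 <- stats::setNames(rep(NA_real_, length(methods)),
                                            .frag_methods[methods])
  dir <- stats::setNames(rep(NA_character_, length(methods)),
                         .frag_methods[methods])
  mods <- grids <- stats::setNames(vector("list", length(methods)),
                                   .frag_methods[methods])
  for (k in seq_along(methods)) {
    m <- methods[k]
    core <- if (all)
      .fi_exhaustive_core(tab$e0, tab$n0, tab$e1, tab$n1, m, alpha, r0, r1,
                          opts, cell_cap)
    else
      .fi_search_core(tab$e0, tab$n0, tab$e1, tab$n1, m, alpha, r0, r1, opts)
    p0[k] <- core$p0
    FI[k] <- core$FI
    dir[k] <- if (core$sig0) "sig2nonsig" else "nonsig2sig"
    mods[[k]] <- core$mods
    if (all) grids[[k]] <- core$grid
    FI0[k] <- .fi_restricted_core(tab$e0, tab$n0, tab$e1, tab$n1, m, alpha,
                                  r0, 0L, opts)
    FI1[k] <- .fi_restricted_core(tab$e0, tab$n0, tab$e1, tab$n1, m, alpha,
                                  r1, 1L, opts)
  }
  out <- list(table = tab, methods = .frag_methods[methods], alpha = alpha,
              opts = opts, modify0 = modify0, modify1 = modify1,
              f0.range = r0, f1.range = r1,
              p0 = p0, FI = FI, FQ = fq(FI, tab$n0 + tab$n1),
              FI0 = FI0, FI1 = FI1, dir = dir, mods = mods)
  if (all) out$p_grid <- grids
  class(out) <- c(if (all) "frag_study_all", "frag_study")
  out
}

#' Group-restricted fragility index
#'
#' FI with event-status modifications confined to a single treatment group
#' (FI0 for group 0, FI1 for group 1).
#'
#' @inheritParams frag_study
#' @param table A \code{\link{frag_table}}.
#' @param group Which group may be modified: \code{0} or \code{1}.
#' @param method A single method name.
#' @param modify Allowed direction of modification within the group.
#' @return A positive integer, or \code{NA} if significance cannot be altered.
#' @export
fi_restricted <- function(table, group, method = "fisher", alpha = 0.05,
                          modify = "both", alternative = "two.sided",
                          null.OR = 1, null.RR = 1, null.RD = 0,
                          yates = TRUE, incr = 0.5) {
  stopifnot(inherits(table, "frag_table"), group %in% c(0, 1))
  opts <- .study_opts(alternative, null.OR, null.RR, null.RD, yates, incr)
  r <- if (group == 0) .mod_range(table$e0, table$n0, modify)
       else .mod_range(table$e1, table$n1, modify)
  .fi_restricted_core(table$e0, table$n0, table$e1, table$n1,
                      .match_methods(method)[1L], alpha, r, group, opts)
}

#' Fragility quotient
#'
#' The FI expressed as the minimal percentage of participants whose event
#' status must change to alter significance: \code{FI / n_total * 100}.
#' \code{NA} fragility indices propagate.
#'
#' @param fi Fragility index (vectorised).
#' @param n_total Total sample size (study: \code{n0 + n1}; meta-analysis:
#'   total across studies).
#' @return Percentage(s) in (0, 100].
#' @examples
#' fq(5, 500)  # 1
#' @export
fq <- function(fi, n_total) {
  stopifnot(all(n_total >= 1))
  fi / n_total * 100
}

#' @export
print.frag_study <- function(x, digits = 3, ...) {
  cat("Fragility of an individual study\n")
  cat(sprintf("  group 0: %d/%d events; group 1: %d/%d events\n",
              as.integer(x$table$e0), as.integer(x$table$n0),
              as.integer(x$table$e1), as.integer(x$table$n1)))
  cat(sprintf("  modification ranges: f0 in [%d, %d], f1 in [%d, %d]\n",
              as.integer(x$f0.range[1]), as.integer(x$f0.range[2]),
              as.integer(x$f1.range[1]), as.integer(x$f1.range[2])))
  cat(sprintf("  significance level: %s\n", format(x$alpha)))
  cat("\n  p-values:\n")
  print(round(x$p0, digits))
  cat("\n  fragility index (direction):\n")
  for (m in names(x$FI))
    cat(sprintf("    %-6s FI = %-4s FQ = %s%%  [%s]\n", m,
                ifelse(is.na(x$FI[m]), "NA", x$FI[m]),
                ifelse(is.na(x$FQ[m]), "NA", format(round(x$FQ[m], digits))),
                x$dir[m]))
  invisible(x)
}
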