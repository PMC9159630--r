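## Plot methods: significance landscape of a single study, fragility vs
## significance level, modification trajectories of (network)
## meta-analyses, and distributions of fragility measures across datasets.
## Significant results are drawn in red and non-significant ones in green
## (a colour-vision-safe orange/blue pair is available via `palette`), with
## colour opacity linear in -log10(p) up to the truncation exponent.

.frag_palette <- function(palette = c("redgreen", "colorblind")) {
  palette <- match.arg(palette)
  if (palette == "redgreen") c(sig = "red", nonsig = "forestgreen")
  else c(sig = "#D55E00", nonsig = "#0072B2")
}

## Opacity linear in -log10 p between the significance level (faintest) and
## the truncation threshold 10^-trun (fullest).
.p_alpha_level <- function(p, trun, lo = 0.15, hi = 1) {
  v <- pmin(-log10(pmax(p, 10^-trun)), trun) / trun
  lo + (hi - lo) * v
}

.col_with_alpha <- function(col, alpha) {
  rgb <- grDevices::col2rgb(col) / 255
  grDevices::rgb(rgb[1, ], rgb[2, ], rgb[3, ], alpha)
}

#' Plot the significance landscape of a single study
#'
#' For a \code{\link{frag_study}} result computed with \code{all = TRUE}.
#' When both groups are modifiable the landscape is a matrix of points
#' (modifications in group 0 on the x axis, group 1 on the y axis), each
#' coloured by the significance and magnitude of its p-value; dashed lines
#' mark no modification and cross at a square point (the original table),
#' and triangles mark all minimal modifications that alter significance.
#' When only one group is modified, \code{-log10(p)} is drawn against the
#' modification with significance bands; plus signs mark p-values truncated
#' at \code{10^-trun}.
#'
#' @param x A \code{"frag_study_all"} object.
#' @param method Which method's landscape to draw (default: the first).
#' @param modify0,modify1 Logical; draw modifications of each group.
#'   Defaults to whether the group's modification range is non-degenerate.
#' @param trun Truncation exponent: p-values below \code{10^-trun} are
#'   drawn at full opacity as plus signs.
#' @param cex.pts Point size.
#' @param palette \code{"redgreen"} (default) or \code{"colorblind"}.
#' @param legend Draw the p-value magnitude legend?
#' @param ... Passed to \code{\link[graphics]{plot.default}}.
#' @return Invisibly, \code{x}.
#' @export
plot.frag_study_all <- function(x, method = NULL, modify0 = NULL,
                                modify1 = NULL, trun = 10, cex.pts = 0.6,
                                palette = "redgreen", legend = TRUE, ...) {
  if (is.null(method)) method <- names(x$p_grid)[1]
  method <- match.arg(method, x$methods)
  grid <- x$p_grid[[method]]
  if (is.null(grid)) stop("no p-value grid stored; rerun with all = TRUE")
  if (is.null(modify0)) modify0 <- diff(x$f0.range) > 0
  if (is.null(modify1)) modify1 <- diff(x$f1.range) > 0
  if (!modify0 && !modify1) stop("at least one group must be modifiable")
  pal <- .frag_palette(palette)
  f0 <- as.integer(rownames(grid)); f1 <- as.integer(colnames(grid))
  if (modify0 && modify1) {
    pts <- expand.grid(f0 = f0, f1 = f1)
    p <- as.vector(grid)
    sig <- p < x$alpha
    colv <- .col_with_alpha(ifelse(sig, pal["sig"], pal["nonsig"]),
                            .p_alpha_level(p, trun))
    truncd <- p < 10^-trun
    graphics::plot(pts$f0, pts$f1, pch = ifelse(truncd, 3, 16),
                   col = colv, cex = cex.pts,
                   xlab = "modification of events in group 0",
                   ylab = "modification of events in group 1", ...)
    graphics::abline(v = 0, lty = 2); graphics::abline(h = 0, lty = 2)
    p0 <- x$p0[method]
    graphics::points(0, 0, pch = 22, bg = "white",
                     col = ifelse(p0 < x$alpha, pal["sig"], pal["nonsig"]),
                     cex = cex.pts * 2.2, lwd = 2)
    if (!is.null(x$mods[[method]]))
      graphics::points(x$mods[[method]][, 1], x$mods[[method]][, 2],
                       pch = 24, bg = "white", cex = cex.pts * 2,
                       col = ifelse(p0 < x$alpha, pal["nonsig"],
                                    pal["sig"]), lwd = 2)
    if (legend) {
      pv <- c(x$alpha, 10^-(c(2, 4, 6, 8)), 10^-trun)
      pv <- sort(unique(pv[pv <= 1]), decreasing = TRUE)
      graphics::legend("topright", bty = "n", cex = 0.7,
                       legend = signif(pv, 2), pch = 16,
                       col = .col_with_alpha(pal["sig"],
                                             .p_alpha_level(pv, trun)),
                       title = "p")
    }
  } else {
    grp <- if (modify0) 0 else 1
    f <- if (grp == 0) f0 else f1
    p <- if (grp == 0) grid[, colnames(grid) == "0"]
         else grid[rownames(grid) == "0", ]
    lg <- pmin(-log10(p), trun)
    ymax <- max(lg) * 1.05
    graphics::plot(f, lg, type = "n", ylim = c(0, ymax),
                   xlab = sprintf("modification of events in group %d", grp),
                   ylab = "-log10(p)", ...)
    thr <- -log10(x$alpha)
    usr <- graphics::par("usr")
    graphics::rect(usr[1], thr, usr[2], usr[4],
                   col = .col_with_alpha(pal["sig"], 0.08), border = NA)
    graphics::rect(usr[1], usr[3], usr[2], thr,
                   col = .col_with_alpha(pal["nonsig"], 0.08), border = NA)
    graphics::abline(h = thr, lty = 3)
    graphics::abline(v = 0, lty = 2)
    sig <- p < x$alpha
    truncd <- p < 10^-trun
    graphics::points(f, lg, pch = ifelse(truncd, 3, 16), cex = cex.pts,
                     col = ifelse(sig, pal["sig"], pal["nonsig"]))
    graphics::points(0, pmin(-log10(x$p0[method]), trun), pch = 22,
                     bg = "white", cex = cex.pts * 2.2, lwd = 2)
    FIr <- if (grp == 0) x$FI0[method] else x$FI1[method]
    if (!is.na(FIr)) {
      sig0 <- x$p0[method] < x$alpha
      flip <- if (sig0) !sig else sig
      cand <- f[abs(f) == FIr & flip]
      graphics::points(cand, lg[match(cand, f)], pch = 24, bg = "white",
                       cex = cex.pts * 2, lwd = 2)
    }
  }
  invisible(x)
}

#' Plot fragility against the significance level
#'
#' Step plot of the FI (or FQ) over a grid of significance levels, for
#' sweep objects from \code{\link{frag_study_alpha}},
#' \code{\link{frag_ma_alpha}} or \code{\link{frag_nma_alpha}}.  Points are
#' red where the original result is significant at that level (the FI
#' removes significance) and green where it is not (the FI creates it); for
#' a study, a dashed vertical line marks the original p-value where it
#' falls inside the range.
#'
#' @param x A \code{"frag_alpha"} object.
#' @param method For study sweeps, which method's column to draw.
#' @param comparison For network sweeps, which comparison column.
#' @param fragility \code{"FI"} or \code{"FQ"}.
#' @param palette \code{"redgreen"} or \code{"colorblind"}.
#' @param cex.pts Point size.
#' @param ... Passed to \code{\link[graphics]{plot.default}} (e.g.
#'   \code{log = "x"}).
#' @return Invisibly, \code{x}.
#' @export
plot.frag_alpha <- function(x, method = NULL, comparison = NULL,
                            fragility = c("FI", "FQ"),
                            palette = "redgreen", cex.pts = 0.8, ...) {
  fragility <- match.arg(fragility)
  pal <- .frag_palette(palette)
  val <- x[[fragility]]
  dir <- x$dir
  p0 <- NULL
  if (is.matrix(val)) {
    sel <- if (!is.null(method)) match.arg(method, colnames(val))
           else if (!is.null(comparison)) match.arg(comparison,
                                                    colnames(val))
           else colnames(val)[1]
    if (!is.null(x$p0)) p0 <- x$p0[sel]
    val <- val[, sel]; dir <- dir[, sel]
  }
  colv <- ifelse(dir == "sig2nonsig", pal["sig"], pal["nonsig"])
  graphics::plot(x$alphas, val, type = "s", col = "grey50",
                 xlab = "significance level",
                 ylab = if (fragility == "FI") "fragility index"
                        else "fragility quotient (%)", ...)
  graphics::points(x$alphas, val, pch = 16, cex = cex.pts, col = colv)
  if (!is.null(p0) && !is.na(p0) && p0 >= min(x$alphas) &&
      p0 <= max(x$alphas))
    graphics::abline(v = p0, lty = 2)
  invisible(x)
}

## Shared trajectory plot: two per-group total-event-count lines against
## the iteration, study labels at each modification (an asterisk repeats
## the previous iteration's study), optional y-axis break.
.plot_trajectory <- function(tot0, tot1, labels, label_line, group_names,
                             ybreaks = NULL, study.marker = TRUE,
                             cex.marker = 0.7, offset.marker = 0.4,
                             col.line = c("blue", "red"), lwd = 2,
                             legend = TRUE, x.legend = "right",
                             y.legend = NULL, cex.legend = 0.9,
                             xlab = "iteration", ylab = "total event count",
                             ...) {
  iters <- seq_along(tot0) - 1
  gap <- 0
  tr <- function(y) {
    if (is.null(ybreaks)) return(y)
    ifelse(y > ybreaks[2], y - gap, y)
  }
  if (!is.null(ybreaks)) {
    stopifnot(length(ybreaks) == 2, ybreaks[1] < ybreaks[2])
    gap <- ybreaks[2] - ybreaks[1]
  }
  yall <- c(tr(tot0), tr(tot1))
  graphics::plot(range(iters), range(yall) + c(-1, 1), type = "n",
                 xlab = xlab, ylab = ylab, yaxt = if (is.null(ybreaks))
                   "s" else "n", ...)
  if (!is.null(ybreaks)) {
    ticks <- pretty(c(min(yall), max(c(tot0, tot1))))
    ticks <- ticks[ticks < ybreaks[1] | ticks > ybreaks[2]]
    graphics::axis(2, at = tr(ticks), labels = ticks)
    ## axis-break marks at the compression point
    yb <- tr(ybreaks[1])
    usr <- graphics::par("usr")
    for (dy in c(-0.4, 0.4))
      graphics::segments(usr[1] - 0.2, yb + dy + 0.4,
                         usr[1] + 0.2, yb + dy - 0.4, xpd = TRUE)
  }
  graphics::lines(iters, tr(tot0), col = col.line[1], lwd = lwd)
  graphics::lines(iters, tr(tot1), col = col.line[2], lwd = lwd)
  if (study.marker && length(labels)) {
    shown <- as.character(labels)
    rep_prev <- c(FALSE, shown[-1] == shown[-length(shown)])
    shown[rep_prev] <- "*"
    for (k in seq_along(shown)) {
      y <- if (label_line[k] == 0) tr(tot0[k + 1]) else tr(tot1[k + 1])
      graphics::text(iters[k + 1], y + offset.marker, shown[k],
                     cex = cex.marker,
                     col = col.line[label_line[k] + 1])
    }
  }
  if (legend)
    graphics::legend(x.legend, y.legend, legend = group_names,
                     col = col.line, lwd = lwd, cex = cex.legend,
                     bty = "n")
}

#' Plot the modification trajectory of a meta-analysis fragility search
#'
#' Shows the total event count of each treatment group across the
#' iterations of the greedy search, with the study modified at each step
#' labelled next to the affected line (an asterisk means the same study as
#' the previous iteration).  A range supplied in \code{ybreaks} is omitted
#' from the y axis (drawn as an axis break) when the two group totals are
#' far apart.
#'
#' @param x A \code{"frag_ma"} object with a defined FI.
#' @param ybreaks Optional numeric range to cut out of the y axis.
#' @param study.marker Label the modified studies?
#' @param cex.marker,offset.marker Size and offset of the study labels.
#' @param col.line Two line colours (group 0, group 1).
#' @param lwd Line width.
#' @param legend,x.legend,y.legend,cex.legend Legend switches passed to
#'   \code{\link[graphics]{legend}}.
#' @param ... Passed to \code{\link[graphics]{plot.default}}.
#' @return Invisibly, \code{x}.
#' @export
plot.frag_ma <- function(x, ybreaks = NULL, study.marker = TRUE,
                         cex.marker = 0.7, offset.marker = 0.4,
                         col.line = c("blue", "red"), lwd = 2,
                         legend = TRUE, x.legend = "right", y.legend = NULL,
                         cex.legend = 0.9, ...) {
  if (is.na(x$FI)) stop("no trajectory to plot: the FI is NA")
  traj <- x$trajectory
  tot0 <- sum(x$data$e0); tot1 <- sum(x$data$e1)
  t0 <- cumsum(c(tot0, ifelse(traj$group == 0, traj$delta, 0)))
  t1 <- cumsum(c(tot1, ifelse(traj$group == 1, traj$delta, 0)))
  .plot_trajectory(t0, t1, traj$study, traj$group,
                   c("group 0", "group 1"), ybreaks, study.marker,
                   cex.marker, offset.marker, col.line, lwd, legend,
                   x.legend, y.legend, cex.legend, ...)
  invisible(x)
}

#' Plot the modification trajectory of a network-meta-analysis comparison
#'
#' As \code{\link{plot.frag_ma}}, for one treatment comparison of a
#' \code{\link{frag_nma}} result: the lines are the total event counts in
#' the arms of the two compared treatments across all studies.
#'
#' @param x A \code{"frag_nma"} object.
#' @param tid1,tid2 The comparison to draw (default: the first assessed).
#' @inheritParams plot.frag_ma
#' @return Invisibly, \code{x}.
#' @export
plot.frag_nma <- function(x, tid1 = NULL, tid2 = NULL, ybreaks = NULL,
                          study.marker = TRUE, cex.marker = 0.7,
                          offset.marker = 0.4, col.line = c("blue", "red"),
                          lwd = 2, legend = TRUE, x.legend = "right",
                          y.legend = NULL, cex.legend = 0.9, ...) {
  if (is.null(tid1)) { tid1 <- x$tid1.f[1]; tid2 <- x$tid2.f[1] }
  key <- paste(tid1, "vs", tid2)
  cmp <- x$comparisons[[key]]
  if (is.null(cmp)) cmp <- x$comparisons[[paste(tid2, "vs", tid1)]]
  if (is.null(cmp)) stop("comparison ", key, " was not assessed")
  if (is.na(cmp$FI)) stop("no trajectory to plot: the FI is NA")
  traj <- cmp$trajectory
  tot1 <- sum(x$data$e[x$data$tid == cmp$tid1])
  tot2 <- sum(x$data$e[x$data$tid == cmp$tid2])
  is1 <- traj$tid == cmp$tid1
  t1 <- cumsum(c(tot1, ifelse(is1, traj$delta, 0)))
  t2 <- cumsum(c(tot2, ifelse(!is1, traj$delta, 0)))
  .plot_trajectory(t2, t1, traj$sid, as.integer(is1),
                   paste("treatment", c(cmp$tid2, cmp$tid1)), ybreaks,
                   study.marker, cex.marker, offset.marker, col.line, lwd,
                   legend, x.legend, y.legend, cex.legend, ...)
  invisible(x)
}

#' Plot the distribution of fragility measures across datasets
#'
#' For batch results (\code{\link{frag_studies}}, \code{\link{frag_mas}}):
#' a bar plot of the integer FIs, coloured by the original significance
#' (red = significant, green = non-significant), or a histogram of the FQs.
#' Values above \code{max.f} are stacked into a rightmost truncated bar.
#'
#' @param x A \code{"frag_multi"} object.
#' @param method For study batches, which method's results to draw.
#' @param dir \code{"both"}, \code{"sig2nonsig"} or \code{"nonsig2sig"}.
#' @param fragility \code{"FI"} (bar plot) or \code{"FQ"} (histogram).
#' @param max.f Optional truncation; larger values join the last bar.
#' @param breaks Number of histogram breaks for FQ.
#' @param palette \code{"redgreen"} or \code{"colorblind"}.
#' @param ... Passed to \code{\link[graphics]{barplot}} or
#'   \code{\link[graphics]{hist}}.
#' @return Invisibly, \code{x}.
#' @export
plot.frag_multi <- function(x, method = NULL,
                            dir = c("both", "sig2nonsig", "nonsig2sig"),
                            fragility = c("FI", "FQ"), max.f = NULL,
                            breaks = NULL, palette = "redgreen", ...) {
  dir <- match.arg(dir)
  fragility <- match.arg(fragility)
  pal <- .frag_palette(palette)
  val <- x[[fragility]]
  dr <- x$dir
  if (is.matrix(val)) {
    sel <- if (!is.null(method)) match.arg(method, colnames(val))
           else colnames(val)[1]
    val <- val[, sel]; dr <- dr[, sel]
  }
  keep <- !is.na(val) & (dir == "both" | dr == dir)
  val <- val[keep]; dr <- dr[keep]
  if (!length(val)) stop("no defined fragility values to plot")
  if (fragility == "FI") {
    truncated <- !is.null(max.f) && any(val > max.f)
    if (truncated) val <- pmin(val, max.f + 1)
    lv <- seq_len(max(val))
    counts <- rbind(sig2nonsig = tabulate(val[dr == "sig2nonsig"],
                                          nbins = max(val)),
                    nonsig2sig = tabulate(val[dr == "nonsig2sig"],
                                          nbins = max(val)))
    nm <- as.character(lv)
    if (truncated) nm[length(nm)] <- paste0(">", max.f)
    graphics::barplot(counts, names.arg = nm, space = 0,
                      col = pal[c("sig", "nonsig")], border = "grey30",
                      xlab = "fragility index", ylab = "count", ...)
  } else {
    if (!is.null(max.f)) val <- pmin(val, max.f)
    graphics::hist(val, breaks = if (is.null(breaks)) "Sturges" else breaks,
                   col = .col_with_alpha(pal["sig"], 0.6),
                   xlab = "fragility quotient (%)", main = "", ...)
  }
  invisible(x)
}
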