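## Reading and writing the three CSV schemas: individual trials
## (e0, n0, e1, n1), stacked pairwise meta-analyses (ma.id, e0, n0, e1, n1),
## and long-format network meta-analyses (sid, tid, e, n).

.read_csv_checked <- function(path, columns) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(columns, names(d))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  d <- d[columns]
  for (cl in columns) {
    v <- d[[cl]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != round(v)))
      stop("column ", cl, " must be integer-valued with no missing entries",
           " (row ", paste(utils::head(which(is.na(v) | v != round(v)), 3),
                           collapse = ", "), ")")
  }
  d
}

.check_counts_df <- function(d) {
  bad <- which(d$e0 < 0 | d$e0 > d$n0 | d$e1 < 0 | d$e1 > d$n1 |
                 d$n0 < 1 | d$n1 < 1)
  if (length(bad))
    stop("event count exceeds sample size (or size < 1) in row(s) ",
         paste(bad, collapse = ", "))
  d
}

#' Read a table of individual 2x2 trials
#'
#' Expects a CSV with integer columns \code{e0, n0, e1, n1}, one row per
#' trial; row order is preserved.
#'
#' @param path Path to a CSV file.
#' @return A data frame with columns \code{e0, n0, e1, n1}.
#' @export
read_trials <- function(path)
  .check_counts_df(.read_csv_checked(path, c("e0", "n0", "e1", "n1")))

#' Read a stacked collection of pairwise meta-analyses
#'
#' Expects a CSV with integer columns \code{ma.id, e0, n0, e1, n1}; each
#' distinct \code{ma.id} (in order of first appearance) is one meta-analysis.
#'
#' @param path Path to a CSV file.
#' @return A data frame with columns \code{ma.id, e0, n0, e1, n1}.
#' @export
read_ma <- function(path)
  .check_counts_df(.read_csv_checked(path,
                                     c("ma.id", "e0", "n0", "e1", "n1")))

#' Read a long-format network meta-analysis dataset
#'
#' Expects a CSV with integer columns \code{sid, tid, e, n}, one row per
#' study arm.  Validates counts, arm multiplicity and within-study
#' treatment uniqueness.
#'
#' @param path Path to a CSV file.
#' @return A data frame with columns \code{sid, tid, e, n}.
#' @export
read_nma <- function(path) {
  d <- .read_csv_checked(path, c("sid", "tid", "e", "n"))
  bad <- which(d$e < 0 | d$e > d$n | d$n < 1)
  if (length(bad))
    stop("event count exceeds sample size (or size < 1) in row(s) ",
         paste(bad, collapse = ", "))
  for (s in unique(d$sid)) {
    rows <- which(d$sid == s)
    if (length(rows) < 2)
      stop("study ", s, " has a single arm (row ", rows, ")")
    if (anyDuplicated(d$tid[rows]))
      stop("study ", s, " lists a treatment twice")
  }
  d
}

#' Path to a packaged example dataset
#'
#' The package ships small plain-text example datasets: the complete 3-study,
#' 4-treatment network on inhaled drugs for chronic obstructive pulmonary
#' disease (\code{dat_copd.csv}), and the printed 6-row excerpts of the
#' antidepressant-trial collection (\code{dat_ad_head.csv}), the
#' nutrition-support meta-analyses (\code{dat_ns_head.csv}) and the
#' smoking-cessation network (\code{dat_sc_head.csv}).
#'
#' @param file File name; with no argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @examples
#' frag_example()
#' read_nma(frag_example("dat_copd.csv"))
#' @export
frag_example <- function(file = NULL) {
  dir <- system.file("extdata", package = "fragtools")
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path))
    stop("no packaged dataset called ", file, "; available: ",
         paste(list.files(dir), collapse = ", "))
  path
}

#' Export a fragility trajectory as CSV
#'
#' Writes the per-iteration record of a greedy fragility search (study,
#' group or treatment, event change, refitted estimate and CI) to a CSV
#' file.
#'
#' @param x A \code{"frag_ma"} or \code{"frag_nma"} object (for the latter,
#'   give \code{comparison} as \code{"t1 vs t2"}; default first).
#' @param path Output file path.
#' @param comparison Comparison label for \code{"frag_nma"} objects.
#' @return Invisibly, the trajectory data frame written.
#' @export
write_trajectory <- function(x, path, comparison = NULL) {
  traj <- if (inherits(x, "frag_ma")) x$trajectory
  else if (inherits(x, "frag_nma")) {
    if (is.null(comparison)) comparison <- names(x$comparisons)[1]
    x$comparisons[[comparison]]$trajectory
  } else stop("x must be a frag_ma or frag_nma object")
  utils::write.csv(traj, path, row.names = FALSE)
  invisible(traj)
}
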