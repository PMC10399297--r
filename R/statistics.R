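#' @include dynamics.R
NULL

#' Summarize the attractor structure of one network
#'
#' Computes the per-network summary statistics used throughout the ensemble
#' experiments: the number of attractors N(f), the total attractor size
#' S(f) (sum of cycle lengths), and the average attractor size
#' AS(f) = S(f)/N(f).
#'
#' @param report an \linkS4class{AttractorReport}.
#' @param n number of network nodes (recorded in the row).
#' @param depth canalizing depth of the sampled network (recorded).
#' @param sampleId,seed bookkeeping columns for sweep rows.
#' @return A one-row data.frame with columns \code{n}, \code{depth},
#'   \code{sample_id}, \code{seed}, \code{num_attractors},
#'   \code{total_attractor_size}, \code{avg_attractor_size},
#'   \code{attractor_sizes} and \code{basin_sizes} (semicolon-separated
#'   lists).
#' @export
summarizeNetwork <- function(report, n = nVars(report), depth = NA_integer_,
                             sampleId = NA_integer_, seed = NA_integer_) {
  lens <- attractorLengths(report)
  if (length(lens) == 0L) stop("empty attractor report")
  N <- length(lens)
  S <- sum(lens)
  data.frame(
    n = n, depth = depth, sample_id = sampleId, seed = seed,
    num_attractors = N,
    total_attractor_size = S,
    avg_attractor_size = S / N,
    attractor_sizes = paste(lens, collapse = ";"),
    basin_sizes = paste(basinSizes(report), collapse = ";"),
    stringsAsFactors = FALSE)
}

#' Ensemble sweep over canalizing depths
#'
#' For every pair (n, depth) on the grid, samples random Boolean networks
#' of that exact canalizing depth, enumerates their attractors and basins,
#' and collects one summary row per network.  Deterministic for a fixed
#' \code{seed}.
#'
#' @param nValues vector of network sizes.
#' @param depths vector of canalizing depths; cells with depth > n are
#'   skipped.
#' @param samples networks per (n, depth) cell.
#' @param seed RNG seed set once before the sweep.
#' @param progress emit a message per completed cell.
#' @return A data.frame of \code{summarizeNetwork()} rows.
#' @examples
#' sw <- runSweep(4, c(0, 4), samples = 5, seed = 1, progress = FALSE)
#' sampleMeans(sw)
#' @export
runSweep <- function(nValues, depths, samples, seed = 1L,
                     progress = interactive()) {
  if (length(nValues) == 0L || length(depths) == 0L || samples < 1L)
    stop("invalid sweep grid")
  if (all(depths > max(nValues))) stop("no depth fits any n on the grid")
  set.seed(seed)
  rows <- list()
  for (n in nValues) {
    for (k in depths) {
      if (k > n) next
      for (s in seq_len(samples)) {
        net <- sampleNetwork(n, k)
        rep <- attractorsAndBasins(net)
        rows[[length(rows) + 1L]] <-
          summarizeNetwork(rep, n = n, depth = k, sampleId = s, seed = seed)
      }
      if (progress)
        message(sprintf("sweep cell n=%d depth=%d done (%d samples)",
                        n, k, samples))
    }
  }
  do.call(rbind, rows)
}

#' Per-cell sample means of N(f) and AS(f)
#'
#' @param sweep a data.frame from [runSweep()].
#' @return A data.frame with one row per (n, depth) cell and columns
#'   \code{mean_num_attractors} and \code{mean_avg_attractor_size}.
#' @export
sampleMeans <- function(sweep) {
  if (nrow(sweep) == 0L) stop("empty sweep")
  agg <- stats::aggregate(
    cbind(num_attractors, avg_attractor_size) ~ n + depth,
    data = sweep, FUN = mean)
  names(agg)[names(agg) == "num_attractors"] <- "mean_num_attractors"
  names(agg)[names(agg) == "avg_attractor_size"] <- "mean_avg_attractor_size"
  agg[order(agg$n, agg$depth), , drop = FALSE]
}

#' Relative decrease of the mean statistics versus depth zero
#'
#' The ratio of the sample mean of N(f) (and of AS(f)) at canalizing depth
#' \code{k} to the corresponding mean at depth 0, for networks with
#' \code{n} nodes.  By definition both ratios are exactly 1 at \code{k = 0}.
#'
#' @param sweep a data.frame from [runSweep()] containing cells (n, k) and
#'   (n, 0).
#' @param k canalizing depth of the numerator cell.
#' @param n network size.
#' @return Named numeric vector \code{c(N = ..., AS = ...)}.
#' @export
relativeDecrease <- function(sweep, k, n) {
  top <- sweep[sweep$n == n & sweep$depth == k, , drop = FALSE]
  base <- sweep[sweep$n == n & sweep$depth == 0, , drop = FALSE]
  if (nrow(top) == 0L || nrow(base) == 0L)
    stop("sweep must contain both the (n, k) and the (n, 0) cell")
  c(N = mean(top$num_attractors) / mean(base$num_attractors),
    AS = mean(top$avg_attractor_size) / mean(base$avg_attractor_size))
}

#' Histogram of a summary statistic over one sweep cell
#'
#' Bins the empirical distribution of N(f) (integer bins) or AS(f)
#' (fixed-width bins) within a single (n, depth) cell.
#'
#' @param sweep a data.frame from [runSweep()].
#' @param field \code{"N"} for the number of attractors or \code{"AS"} for
#'   the average attractor size.
#' @param n,depth the cell.
#' @param binWidth bin width for AS (ignored for N).
#' @return A data.frame with columns \code{lower}, \code{upper},
#'   \code{count}; counts sum to the number of rows in the cell.
#' @export
attractorHistogram <- function(sweep, field = c("N", "AS"), n, depth,
                               binWidth = 0.25) {
  field <- match.arg(field)
  cell <- sweep[sweep$n == n & sweep$depth == depth, , drop = FALSE]
  if (nrow(cell) == 0L) stop("empty sweep cell")
  if (field == "N") {
    x <- cell$num_attractors
    vals <- seq(min(x), max(x))
    data.frame(lower = vals - 0.5, upper = vals + 0.5,
               count = vapply(vals, function(v) sum(x == v), numeric(1)))
  } else {
    x <- cell$avg_attractor_size
    lo <- floor(min(x) / binWidth) * binWidth
    hi <- ceiling(max(x) / binWidth) * binWidth
    if (hi <= lo) hi <- lo + binWidth
    edges <- seq(lo, hi, by = binWidth)
    idx <- pmin(findInterval(x, edges), length(edges) - 1L)
    data.frame(lower = utils::head(edges, -1), upper = edges[-1],
               count = tabulate(idx, nbins = length(edges) - 1L))
  }
}

#' Write a sweep to CSV
#'
#' Fixed schema (one row per sampled network) so downstream plotting is
#' reproducible; average attractor sizes are written with 6 decimal digits.
#'
#' @param sweep a data.frame from [runSweep()].
#' @param file output path.
#' @return The file path, invisibly.
#' @export
writeSweepCSV <- function(sweep, file) {
  out <- sweep
  out$avg_attractor_size <- sprintf("%.6f", out$avg_attractor_size)
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
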