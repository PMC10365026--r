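# Signal-track arithmetic on bedGraph-style tibbles (chrom, start, end, value).
# Tracks are piecewise constant over 0-based half-open records; gaps are 0.

#' Integrate a signal track over an interval
#'
#' Computes `sum(value * bp)` of a piecewise-constant track over `[start,
#' end)`. Vectorised over query intervals.
#'
#' @param track Signal tibble (`chrom`, `start`, `end`, `value`), sorted and
#'   non-overlapping within chromosomes (as produced by [read_bedgraph()]).
#' @param chrom Chromosome of the query interval(s).
#' @param start,end Query coordinates (0-based half-open).
#' @return Numeric vector of integrals (value x bp).
#' @export
signal_integral <- function(track, chrom, start, end) {
  n <- length(start)
  chrom <- rep_len(chrom, n)
  out <- numeric(n)
  for (cc in unique(chrom)) {
    tr <- track[track$chrom == cc, , drop = FALSE]
    idx <- which(chrom == cc)
    if (!nrow(tr)) next
    tr <- tr[order(tr$start), , drop = FALSE]
    # Cumulative integral F(x) evaluated via the record grid: F is piecewise
    # linear with slope `value` inside records and 0 in gaps.
    cum_end <- cumsum(tr$value * (tr$end - tr$start))       # F at record ends
    cum_start <- c(0, cum_end[-nrow(tr)])                   # F at record starts
    F_at <- function(x) {
      j <- findInterval(x, tr$start)                        # last record started before/at x
      val <- ifelse(j == 0, 0,
                    cum_start[pmax(j, 1)] +
                      tr$value[pmax(j, 1)] *
                        pmax(0, pmin(x, tr$end[pmax(j, 1)]) - tr$start[pmax(j, 1)]))
      as.numeric(val)
    }
    out[idx] <- F_at(end[idx]) - F_at(start[idx])
  }
  out
}

#' Mean signal over an interval
#'
#' @inheritParams signal_integral
#' @return Numeric vector: integral divided by interval width (gaps count
#'   as 0).
#' @export
signal_mean <- function(track, chrom, start, end) {
  signal_integral(track, chrom, start, end) / (end - start)
}

# Binned mean signal for one window [start, end) cut into nbins equal bins.
# Returns a numeric vector of per-bin means; bins outside [0, chrom length)
# are the caller's concern (clipped windows are padded upstream).
binned_means <- function(track, chrom, start, end, nbins) {
  edges <- as.integer(round(seq(start, end, length.out = nbins + 1L)))
  signal_mean(track, chrom, edges[-(nbins + 1L)], edges[-1L])
}
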