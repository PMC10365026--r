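# ROSE-style super-enhancer calling: stitching, signal ranking, tangent
# cutpoint, and TF-occupancy fractions over SE vs typical enhancers.

#' Stitch peaks into candidate enhancer regions
#'
#' Merges peaks whose gap is strictly smaller than `stitch_distance`
#' (transitive closure), optionally removing peaks whose midpoint lies within
#' `tss_exclusion_radius` of any TSS first. Stitching is idempotent.
#'
#' @param peaks BED tibble.
#' @param stitch_distance Maximum gap in bp, exclusive (default 12500, the
#'   published stitching default).
#' @param tss_exclusion_radius Radius around TSSs inside which peaks are
#'   dropped before stitching (default 0 = off).
#' @param gene_models Needed when `tss_exclusion_radius > 0`.
#' @return A tibble of stitched regions: `chrom`, `start`, `end`,
#'   `n_constituents`, `constituents` (list column of input row indices).
#' @export
stitch <- function(peaks, stitch_distance = 12500, tss_exclusion_radius = 0,
                   gene_models = NULL) {
  if (stitch_distance < 0) abort("`stitch_distance` must be >= 0.")
  validate_intervals(peaks, "peaks")
  keep_idx <- seq_len(nrow(peaks))
  if (tss_exclusion_radius > 0) {
    if (is.null(gene_models)) {
      abort("`gene_models` required when `tss_exclusion_radius` > 0.")
    }
    mid <- interval_midpoint(peaks$start, peaks$end)
    drop <- vapply(seq_len(nrow(peaks)), function(i) {
      tsses <- gene_models$tss[gene_models$chrom == peaks$chrom[i]]
      length(tsses) > 0 && any(abs(tsses - mid[i]) <= tss_exclusion_radius)
    }, logical(1))
    keep_idx <- keep_idx[!drop]
  }
  px <- peaks[keep_idx, , drop = FALSE]
  out <- list()
  for (cc in sort(unique(px$chrom))) {
    sel <- which(px$chrom == cc)
    sel <- sel[order(px$start[sel])]
    s <- px$start[sel]; e <- px$end[sel]
    grp <- cumsum(c(1L, as.integer(s[-1] - cummax(e[-length(e)]) >= stitch_distance)))
    for (g in unique(grp)) {
      m <- grp == g
      out[[length(out) + 1L]] <- tibble(
        chrom = cc, start = min(s[m]), end = max(e[m]),
        n_constituents = sum(m),
        constituents = list(keep_idx[sel[m]]))
    }
  }
  if (!length(out)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  n_constituents = integer(), constituents = list()))
  }
  bind_rows(out)
}

#' Score stitched regions by signal
#'
#' Region signal is the integral (value x bp) of the signal track over the
#' region, minus the same integral of an optional control track, floored
#' at 0.
#'
#' @param regions Tibble from [stitch()].
#' @param signal_track bedGraph tibble (treatment).
#' @param control_track Optional bedGraph tibble (input control).
#' @return `regions` with a `signal` column.
#' @export
score_regions <- function(regions, signal_track, control_track = NULL) {
  sig <- signal_integral(signal_track, regions$chrom, regions$start,
                         regions$end)
  if (!is.null(control_track)) {
    sig <- sig - signal_integral(control_track, regions$chrom, regions$start,
                                 regions$end)
  }
  regions$signal <- pmax(sig, 0)
  regions
}

#' Rank-signal cutpoint separating super-enhancers from typical enhancers
#'
#' Scales ascending ranks to x in \[0,1\] and signals to y in \[0,1\] and
#' finds the point where the convex rank-signal curve's slope reaches 1 (the
#' hockey-stick tangent construction), discretised as the index maximising
#' the vertical gap between the diagonal and the curve. Regions with signal
#' strictly above the cut value are super-enhancers. Ties are broken toward
#' the higher-signal index, i.e. fewer super-enhancers; a perfectly linear
#' (or all-equal) profile therefore yields 0 super-enhancers.
#'
#' @param signals Numeric vector of region signals (>= 3 values).
#' @return A list: `n_se` (number of super-enhancers), `cut_signal` (signal
#'   at the tangent point), `is_se` (logical in input order).
#' @export
se_cutpoint <- function(signals) {
  if (length(signals) < 3) abort("Need >= 3 regions to place a cutpoint.")
  if (length(unique(signals)) == 1) {
    warn("All region signals identical; declaring 0 super-enhancers.")
    return(list(n_se = 0L, cut_signal = signals[1],
                is_se = rep(FALSE, length(signals))))
  }
  o <- order(signals)
  s <- signals[o]
  n <- length(s)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - s[1]) / (s[n] - s[1])
  margin <- x - y
  i_star <- max(which(margin == max(margin)))   # ties -> higher signal, fewer SEs
  cut_signal <- s[i_star]
  is_se <- signals > cut_signal
  list(n_se = sum(is_se), cut_signal = cut_signal, is_se = is_se)
}

#' Call super-enhancers from peaks and a signal track
#'
#' The full caller: stitch, score, rank, cutpoint, and nearest-gene labelling
#' (TSS nearest to the region midpoint).
#'
#' @inheritParams stitch
#' @inheritParams score_regions
#' @param gene_models Optional gene models for nearest-gene labels (and TSS
#'   exclusion if requested).
#' @return An `se_calls` tibble ranked by descending signal: `chrom`,
#'   `start`, `end`, `n_constituents`, `signal`, `rank`, `is_SE`,
#'   `nearest_gene`; the cutpoint index (`n_se`) and cut signal are attached
#'   as attributes.
#' @export
call_superenhancers <- function(peaks, signal_track, control_track = NULL,
                                stitch_distance = 12500,
                                tss_exclusion_radius = 0,
                                gene_models = NULL) {
  regions <- stitch(peaks, stitch_distance = stitch_distance,
                    tss_exclusion_radius = tss_exclusion_radius,
                    gene_models = gene_models)
  regions <- score_regions(regions, signal_track, control_track)
  cut <- se_cutpoint(regions$signal)
  regions$is_SE <- cut$is_se
  regions <- regions[order(-regions$signal), , drop = FALSE]
  regions$rank <- seq_len(nrow(regions))
  if (!is.null(gene_models)) {
    mid <- interval_midpoint(regions$start, regions$end)
    regions$nearest_gene <- vapply(seq_len(nrow(regions)), function(i) {
      gm <- gene_models[gene_models$chrom == regions$chrom[i], ]
      if (!nrow(gm)) return(NA_character_)
      gm$gene_id[which.min(abs(gm$tss - mid[i]))]
    }, character(1))
  } else {
    regions$nearest_gene <- NA_character_
  }
  structure(regions[, c("chrom", "start", "end", "n_constituents", "signal",
                        "rank", "is_SE", "nearest_gene", "constituents")],
            cutpoint_index = cut$n_se, cut_signal = cut$cut_signal,
            class = c("se_calls", class(tibble())))
}

#' TF occupancy fractions over super-enhancers and typical enhancers
#'
#' @param tf_peaks BED tibble of TF binding sites.
#' @param se_calls An `se_calls` tibble from [call_superenhancers()].
#' @return A tibble with `fraction_se_bound` (SEs with >= 1 TF peak),
#'   `fraction_typical_bound`, and `fraction_tf_in_se` (TF peaks overlapping
#'   an SE). Fractions over an empty class are `NA`.
#' @export
tf_overlap_fractions <- function(tf_peaks, se_calls) {
  overlaps_any <- function(qs, qe, qc, ts, te, tc) {
    vapply(seq_along(qs), function(i) {
      any(tc == qc[i] & intervals_overlap(ts, te, qs[i], qe[i]))
    }, logical(1))
  }
  se <- se_calls[se_calls$is_SE, ]
  typ <- se_calls[!se_calls$is_SE, ]
  frac <- function(q) if (nrow(q) == 0) NA_real_ else {
    mean(overlaps_any(q$start, q$end, q$chrom,
                      tf_peaks$start, tf_peaks$end, tf_peaks$chrom))
  }
  f_se <- frac(se)
  f_typ <- frac(typ)
  f_tf <- if (nrow(se) == 0) NA_real_ else if (nrow(tf_peaks) == 0) 0 else {
    mean(overlaps_any(tf_peaks$start, tf_peaks$end, tf_peaks$chrom,
                      se$start, se$end, se$chrom))
  }
  tibble(fraction_se_bound = f_se, fraction_typical_bound = f_typ,
         fraction_tf_in_se = f_tf)
}
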