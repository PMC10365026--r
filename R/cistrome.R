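# Replicate-consensus peak derivation and GREAT-style basal-plus-extension
# regulatory-domain assignment of peaks to genes.

#' Replicate-consensus peaks
#'
#' Returns the maximal genomic segments supported by at least
#' `min_replicates` distinct replicates (support = >= 1 bp overlap; each
#' replicate counts once per base). For two peaks overlapping by 1 bp across
#' two replicates this is exactly the 1 bp intersection. Scores are the mean
#' score of the peaks overlapping each consensus segment. Output is
#' independent of replicate input order.
#'
#' @param replicate_peaksets List of >= 2 BED tibbles on the same assembly.
#' @param min_replicates Minimum distinct-replicate support (default 2).
#' @return A BED tibble (`chrom`, `start`, `end`, `name`, `score`) sorted by
#'   position.
#' @export
consensus_peaks <- function(replicate_peaksets, min_replicates = 2) {
  if (length(replicate_peaksets) < min_replicates) {
    abort(sprintf("Need >= %d replicate peak sets (got %d).",
                  min_replicates, length(replicate_peaksets)))
  }
  pooled <- bind_rows(lapply(seq_along(replicate_peaksets), function(i) {
    x <- replicate_peaksets[[i]]
    validate_intervals(x, sprintf("replicate %d", i))
    tibble(chrom = x$chrom, start = x$start, end = x$end,
           score = if ("score" %in% names(x)) x$score else NA_real_,
           rep = i)
  }))
  out <- list()
  for (cc in sort(unique(pooled$chrom))) {
    px <- pooled[pooled$chrom == cc, ]
    edges <- sort(unique(c(px$start, px$end)))
    if (length(edges) < 2) next
    seg_s <- head(edges, -1); seg_e <- edges[-1]
    # distinct-replicate support per segment
    support <- integer(length(seg_s))
    for (r in unique(px$rep)) {
      pr <- px[px$rep == r, ]
      cov <- logical(length(seg_s))
      for (j in seq_len(nrow(pr))) {
        cov <- cov | (seg_s >= pr$start[j] & seg_e <= pr$end[j])
      }
      support <- support + cov
    }
    keep <- support >= min_replicates
    if (!any(keep)) next
    # merge adjacent supported segments into maximal runs
    runs <- rle(keep)
    idx_end <- cumsum(runs$lengths)
    idx_start <- idx_end - runs$lengths + 1L
    sel <- which(runs$values)
    for (k in sel) {
      s <- seg_s[idx_start[k]]; e <- seg_e[idx_end[k]]
      # segments in a run are contiguous only if no gap; split at gaps
      run_idx <- idx_start[k]:idx_end[k]
      brk <- which(seg_s[run_idx][-1] != seg_e[run_idx][-length(run_idx)])
      piece_start <- c(1L, brk + 1L)
      piece_end <- c(brk, length(run_idx))
      for (pp in seq_along(piece_start)) {
        ps <- seg_s[run_idx[piece_start[pp]]]
        pe <- seg_e[run_idx[piece_end[pp]]]
        ov <- px[intervals_overlap(px$start, px$end, ps, pe), ]
        out[[length(out) + 1L]] <- tibble(
          chrom = cc, start = ps, end = pe,
          score = mean(ov$score, na.rm = TRUE))
      }
    }
  }
  if (!length(out)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = numeric()))
  }
  res <- bind_rows(out) |> arrange(.data$chrom, .data$start)
  res$name <- sprintf("consensus_%05d", seq_len(nrow(res)))
  res$score[is.nan(res$score)] <- NA_real_
  res[, c("chrom", "start", "end", "name", "score")]
}

#' Build GREAT-style basal-plus-extension regulatory domains
#'
#' Each gene gets a strand-aware basal domain around its TSS
#' (`basal_up` upstream, `basal_down` downstream; for `-` genes upstream is
#' the numerically increasing side), then each side is extended to the nearer
#' of `max_extension` from the TSS or the nearest other gene's basal-domain
#' boundary. Extensions never cross into a foreign basal domain; chromosome
#' ends clip when `chrom_sizes` is given.
#'
#' @param gene_models Tibble from [read_gene_models()].
#' @param basal_up,basal_down Basal window sizes in bp (defaults 5000 / 1000,
#'   the rule's published defaults).
#' @param max_extension Maximum extension from the TSS (default 1 Mb).
#' @param chrom_sizes Optional named vector of chromosome lengths for
#'   right-side clipping.
#' @return A tibble: `gene_id`, `chrom`, `strand`, `tss`, `basal_start`,
#'   `basal_end`, `ext_start`, `ext_end`.
#' @export
build_regulatory_domains <- function(gene_models, basal_up = 5000,
                                     basal_down = 1000,
                                     max_extension = 1e6,
                                     chrom_sizes = NULL) {
  gm <- gene_models
  if (any(gm$tss < 0)) abort("TSS outside chromosome (negative coordinate).")
  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes[gm$chrom]
    if (any(!is.na(lim) & gm$tss > lim)) abort("TSS outside chromosome bounds.")
  }
  dup_tss <- gm |>
    group_by(.data$chrom, .data$tss) |> filter(n() > 1) |> ungroup()
  if (nrow(dup_tss)) {
    inform(sprintf("build_regulatory_domains: %d genes share a TSS; ties broken by gene_id order.",
                   nrow(dup_tss)))
  }
  gm <- arrange(gm, .data$chrom, .data$tss, .data$gene_id)
  basal_start <- ifelse(gm$strand == "+", gm$tss - basal_up, gm$tss - basal_down)
  basal_end <- ifelse(gm$strand == "+", gm$tss + basal_down, gm$tss + basal_up)
  basal_start <- pmax(basal_start, 0)
  if (!is.null(chrom_sizes)) {
    basal_end <- pmin(basal_end, chrom_sizes[gm$chrom])
  }
  n <- nrow(gm)
  ext_start <- numeric(n); ext_end <- numeric(n)
  for (i in seq_len(n)) {
    same <- gm$chrom == gm$chrom[i]
    other_s <- basal_start[same]; other_e <- basal_end[same]
    self <- which(which(same) == i)
    other_s <- other_s[-self]; other_e <- other_e[-self]
    # Left: extend from own basal start toward tss - max_extension, stopping
    # at the nearest foreign basal end on the left; blocked entirely if a
    # foreign basal straddles our basal start.
    left_cap <- max(c(0, gm$tss[i] - max_extension,
                      other_e[other_e <= basal_start[i]]))
    if (any(other_s < basal_start[i] & other_e > basal_start[i])) {
      left_cap <- basal_start[i]
    }
    ext_start[i] <- min(basal_start[i], max(left_cap, 0))
    ext_start[i] <- max(ext_start[i], left_cap)
    # Right, mirrored.
    right_cap <- min(c(Inf, gm$tss[i] + max_extension,
                       other_s[other_s >= basal_end[i]]))
    if (any(other_s < basal_end[i] & other_e > basal_end[i])) {
      right_cap <- basal_end[i]
    }
    ext_end[i] <- max(basal_end[i], min(right_cap, Inf))
    ext_end[i] <- min(ext_end[i], right_cap)
    if (!is.null(chrom_sizes)) {
      ext_end[i] <- min(ext_end[i], chrom_sizes[gm$chrom[i]])
    }
    ext_start[i] <- max(ext_start[i], 0)
  }
  tibble(gene_id = gm$gene_id, chrom = gm$chrom, strand = gm$strand,
         tss = gm$tss,
         basal_start = as.numeric(basal_start),
         basal_end = as.numeric(basal_end),
         ext_start = pmin(ext_start, basal_start),
         ext_end = pmax(ext_end, basal_end))
}

#' Assign peaks to genes by regulatory-domain midpoint containment
#'
#' Under the default basal-plus-extension rule a peak is assigned to every
#' gene whose extended domain contains the peak midpoint (so a peak between
#' two genes can map to both). `rule = "nearest_only"` instead assigns each
#' peak to the single gene with the nearest TSS.
#'
#' @param peaks BED tibble.
#' @param domains Tibble from [build_regulatory_domains()].
#' @param rule `"basal_plus_extension"` (default) or `"nearest_only"`.
#' @return A `target_map` tibble: `peak_idx`, `gene_id`, `chrom`, `start`,
#'   `end`; unassigned peak indices are kept in the `unassigned` attribute.
#' @export
assign_peaks <- function(peaks, domains,
                         rule = c("basal_plus_extension", "nearest_only")) {
  rule <- match.arg(rule)
  validate_intervals(peaks, "peaks")
  mid <- interval_midpoint(peaks$start, peaks$end)
  rows <- list()
  assigned <- logical(nrow(peaks))
  for (cc in unique(peaks$chrom)) {
    dn <- domains[domains$chrom == cc, ]
    pidx <- which(peaks$chrom == cc)
    if (!nrow(dn)) next
    for (i in pidx) {
      if (rule == "basal_plus_extension") {
        hit <- which(dn$ext_start <= mid[i] & mid[i] < dn$ext_end)
      } else {
        hit <- which.min(abs(dn$tss - mid[i]))
      }
      if (length(hit)) {
        assigned[i] <- TRUE
        rows[[length(rows) + 1L]] <- tibble(
          peak_idx = i, gene_id = dn$gene_id[hit],
          chrom = cc, start = peaks$start[i], end = peaks$end[i])
      }
    }
  }
  out <- if (length(rows)) bind_rows(rows) else {
    tibble(peak_idx = integer(), gene_id = character(),
           chrom = character(), start = integer(), end = integer())
  }
  structure(out, unassigned = which(!assigned),
            class = c("target_map", class(tibble())))
}

#' Flag signature genes bound by the TF in every cell line
#'
#' Sets the `tf_bound` provenance flag for signature genes that have at least
#' one assigned peak in every supplied target map (intersection across cell
#' lines).
#'
#' @param signature A `consensus_signature`.
#' @param target_maps A `target_map` or list of them (one per cell line).
#' @return The signature with `tf_bound` updated.
#' @export
bound_signature <- function(signature, target_maps) {
  if (inherits(target_maps, "target_map")) target_maps <- list(target_maps)
  if (!length(target_maps)) return(signature)
  bound_sets <- lapply(target_maps, function(tm) unique(tm$gene_id))
  bound <- Reduce(intersect, bound_sets)
  signature$tf_bound <- signature$gene_id %in% bound
  signature
}
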