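# Chromatin-state classification of TF-bound sites: binned histone signal
# centered on each site, k-means with k = 3, and a relative labelling rule
# (highest H3K4me3 -> promoter; of the rest, higher H3K27ac -> active
# enhancer, the other -> poised enhancer).

#' Extract a site x bin signal matrix per histone mark
#'
#' For each site, a window of `2 * half_width` bp centered on the site
#' midpoint is cut into `bin`-bp bins and the mean track value per bin is
#' recorded. Windows clipped by a chromosome end are zero-padded and flagged.
#'
#' @param sites BED tibble of binding sites (a `name` column becomes the site
#'   id).
#' @param tracks Named list of bedGraph tibbles (e.g. H3K27ac, H3K4me1,
#'   H3K4me3).
#' @param half_width Window half-width in bp (default 2500).
#' @param bin Bin size in bp (default 100).
#' @param chrom_sizes Optional named chromosome lengths for right-edge
#'   clipping.
#' @return A `site_signal_matrix` list: `site_ids`, `marks` (named list of
#'   sites x bins matrices), `clipped` (logical), `half_width`, `bin`.
#' @export
extract_signal_matrix <- function(sites, tracks, half_width = 2500, bin = 100,
                                  chrom_sizes = NULL) {
  if (bin > 2 * half_width) abort("`bin` must not exceed the window width.")
  validate_intervals(sites, "sites")
  nbins <- floor(2 * half_width / bin)
  mid <- interval_midpoint(sites$start, sites$end)
  win_s <- mid - half_width
  win_e <- win_s + nbins * bin
  site_ids <- if ("name" %in% names(sites) && !anyNA(sites$name)) {
    sites$name
  } else {
    sprintf("site%04d", seq_len(nrow(sites)))
  }
  lim <- if (!is.null(chrom_sizes)) unname(chrom_sizes[sites$chrom]) else rep(Inf, nrow(sites))
  clipped <- win_s < 0 | win_e > lim
  marks <- lapply(tracks, function(tr) {
    m <- matrix(0, nrow = nrow(sites), ncol = nbins,
                dimnames = list(site_ids, NULL))
    for (i in seq_len(nrow(sites))) {
      edges <- win_s[i] + bin * (0:nbins)
      lo <- pmax(edges[-(nbins + 1)], 0)
      hi <- pmin(edges[-1], lim[i])
      ok <- hi > lo
      vals <- numeric(nbins)
      if (any(ok)) {
        vals[ok] <- signal_integral(tr, sites$chrom[i], lo[ok], hi[ok]) /
          (hi[ok] - lo[ok])
      }
      # Bins fully outside the chromosome stay 0 (zero padding).
      m[i, ] <- vals
    }
    m
  })
  structure(list(site_ids = site_ids, marks = marks, clipped = clipped,
                 half_width = half_width, bin = bin),
            class = "site_signal_matrix")
}

#' Cluster sites on their histone-mark profiles
#'
#' The default feature vector is one mean per mark over the whole window
#' (3 features); `features = "profile"` concatenates the full binned
#' profiles instead. K-means uses k-means++-style multi-start (50 restarts,
#' best inertia kept) under a fixed seed, so assignments are deterministic.
#'
#' @param matrix A `site_signal_matrix`.
#' @param k Number of clusters (default 3; must be >= 2).
#' @param seed RNG seed for the restarts.
#' @param features `"means"` (default) or `"profile"`.
#' @param normalize Divide each site's features by its total signal first
#'   (default FALSE).
#' @return Integer cluster index per site (named by site id).
#' @export
cluster_sites <- function(matrix, k = 3, seed = 1,
                          features = c("means", "profile"),
                          normalize = FALSE) {
  features <- match.arg(features)
  if (k < 2) abort("`k` must be >= 2.")
  feat <- site_features(matrix, features)
  if (nrow(feat) < k) abort("Need at least `k` sites.")
  if (normalize) {
    tot <- rowSums(feat)
    tot[tot == 0] <- 1
    feat <- feat / tot
  }
  set.seed(seed)
  fit <- kmeans(feat, centers = k, nstart = 50, iter.max = 100)
  setNames(fit$cluster, matrix$site_ids)
}

site_features <- function(matrix, features = "means") {
  stopifnot(inherits(matrix, "site_signal_matrix"))
  if (features == "means") {
    out <- vapply(matrix$marks, rowMeans, numeric(length(matrix$site_ids)))
    out <- base::matrix(out, nrow = length(matrix$site_ids),
                        dimnames = list(matrix$site_ids, names(matrix$marks)))
  } else {
    out <- do.call(cbind, matrix$marks)
  }
  out
}

#' Label clusters as promoter / active enhancer / poised enhancer
#'
#' With k = 3: the cluster with the highest mean H3K4me3 is the active
#' promoter; of the remaining two, the one with higher mean H3K27ac is the
#' active enhancer and the other the poised enhancer. The rule is relative,
#' so labels are invariant to cluster-index permutation and to rescaling any
#' single mark by a positive constant. Ties are broken by cluster index.
#'
#' @param assignment Cluster indices from [cluster_sites()] (k = 3).
#' @param matrix The `site_signal_matrix` the clustering was run on.
#' @return A `state_assignment` list: `sites` (tibble site_id, cluster,
#'   state), `cluster_means` (cluster x mark means), `state_fractions`.
#' @export
label_clusters <- function(assignment, matrix) {
  ks <- sort(unique(assignment))
  if (length(ks) != 3) abort("Labelling expects exactly 3 clusters.")
  need <- c("H3K27ac", "H3K4me1", "H3K4me3")
  if (!all(need %in% names(matrix$marks))) {
    abort(sprintf("Tracks must include %s.", paste(need, collapse = ", ")))
  }
  mark_mean <- vapply(need, function(mk) {
    vapply(ks, function(kk) {
      mean(matrix$marks[[mk]][assignment == kk, , drop = FALSE])
    }, numeric(1))
  }, numeric(length(ks)))
  rownames(mark_mean) <- as.character(ks)
  k4me3 <- mark_mean[, "H3K4me3"]
  prom <- ks[which.max(k4me3)]          # which.max breaks ties by index
  if (sum(k4me3 == max(k4me3)) > 1) {
    inform("label_clusters: H3K4me3 tie broken by cluster index.")
  }
  if (max(k4me3) <= 0) {
    warn("H3K4me3 is zero everywhere; promoter label assigned by the relative rule anyway.")
  }
  rest <- setdiff(ks, prom)
  k27 <- mark_mean[as.character(rest), "H3K27ac"]
  active <- rest[which.max(k27)]
  if (length(rest) == 2 && k27[1] == k27[2]) {
    inform("label_clusters: H3K27ac tie broken by cluster index.")
  }
  poised <- setdiff(rest, active)
  state_of <- setNames(character(length(ks)), as.character(ks))
  state_of[as.character(prom)] <- "active_promoter"
  state_of[as.character(active)] <- "active_enhancer"
  state_of[as.character(poised)] <- "poised_enhancer"
  sites <- tibble(site_id = names(assignment), cluster = unname(assignment),
                  state = unname(state_of[as.character(assignment)]))
  fr <- table(factor(sites$state, levels = c("active_promoter",
                                             "active_enhancer",
                                             "poised_enhancer"))) / nrow(sites)
  structure(list(sites = sites, cluster_means = mark_mean,
                 state_fractions = as.numeric(fr) |>
                   setNames(names(fr))),
            class = "state_assignment")
}

#' @export
print.state_assignment <- function(x, ...) {
  cat("<state_assignment>\n")
  print(round(x$state_fractions, 3))
  invisible(x)
}

#' @rdname label_clusters
#' @param x A `state_assignment`.
#' @param ... Unused.
#' @export
tidy.state_assignment <- function(x, ...) x$sites
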