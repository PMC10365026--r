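# Synthetic cohorts, knockdown experiments, ChIP landscapes and survival
# tables with planted, recorded ground truth. Every downstream stage has a
# recovery test against the truth object, so no external accession is needed.

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator in one validated list.
#' The defaults define the package's reference study conditions: a cohort of
#' 40 tumor and 40 matched-normal samples over 2,000 genes with one anchor
#' transcription factor, 100 anchor-activated and 50 anchor-repressed planted
#' targets (|log2 fold change| ~ N(1.5, 0.3^2), anchor coupling 0.6),
#' two knockdown cell lines at 3 control vs 3 knockdown replicates with a
#' -/+2 log2 knockdown effect, and a two-chromosome regulatory landscape
#' carrying 8 planted super-enhancers among 200 typical enhancers.
#'
#' @param n_genes Number of genes.
#' @param n_tumor,n_normal Cohort sample counts per condition.
#' @param anchor_gene_id Identifier of the anchor transcription factor gene.
#' @param n_activated_targets,n_repressed_targets Planted target counts.
#' @param target_log2fc_mean,target_log2fc_sd Tumor-vs-normal effect size
#'   distribution for planted targets (log2 units; sign set by target class).
#' @param anchor_coupling Latent-factor loading of targets in (0, 1]; 0 turns
#'   the coupling off (null).
#' @param nb_dispersion Negative-binomial dispersion of cohort counts
#'   (patient-to-patient; 0 = Poisson).
#' @param kd_nb_dispersion Dispersion of knockdown replicate counts
#'   (isogenic cell-line replicates are far less dispersed than patients).
#' @param library_size_range Two multiplicative bounds for per-sample library
#'   size factors.
#' @param n_celllines Number of knockdown cell lines.
#' @param kd_replicates Replicates per arm in each knockdown experiment.
#' @param kd_effect_log2fc Magnitude of the knockdown shift (activated targets
#'   move down by this much, repressed targets up).
#' @param n_chroms,chrom_length Synthetic genome geometry (bp).
#' @param n_planted_SEs,n_planted_typical_enhancers Planted enhancer entities.
#' @param n_distal_sites Distal TF binding sites carrying planted chromatin
#'   states.
#' @param histone_state_fractions Named fractions (promoter, active_enhancer,
#'   poised) for the distal sites; must sum to <= 1 and are renormalised.
#' @param survival_baseline_hazard Baseline hazard (events per day).
#' @param survival_log_hazard_per_sd Log-hazard slope per SD of expression.
#' @param survival_horizon_days Administrative censoring horizon.
#' @param seed Mandatory integer base seed; per-stage seeds are derived from
#'   it so stages can be rerun independently yet deterministically.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_tumor = 40,
                       n_normal = 40,
                       anchor_gene_id = "gene0001",
                       n_activated_targets = 100,
                       n_repressed_targets = 50,
                       target_log2fc_mean = 1.5,
                       target_log2fc_sd = 0.3,
                       anchor_coupling = 0.6,
                       nb_dispersion = 0.05,
                       kd_nb_dispersion = 0.005,
                       library_size_range = c(0.7, 1.3),
                       n_celllines = 2,
                       kd_replicates = 3,
                       kd_effect_log2fc = 2,
                       n_chroms = 2,
                       chrom_length = 6e7,
                       n_planted_SEs = 8,
                       n_planted_typical_enhancers = 200,
                       n_distal_sites = 150,
                       histone_state_fractions = c(promoter = 0.08,
                                                   active_enhancer = 0.22,
                                                   poised = 0.70),
                       survival_baseline_hazard = 1 / 1500,
                       survival_log_hazard_per_sd = log(2),
                       survival_horizon_days = 3650,
                       seed = 1) {
  cfg <- as.list(environment())
  if (is.null(seed) || !is.numeric(seed)) abort("`seed` is mandatory.")
  assert_scalar_number(n_genes, "n_genes", min = 10)
  assert_scalar_number(anchor_coupling, "anchor_coupling", min = 0, max = 1)
  assert_scalar_number(nb_dispersion, "nb_dispersion", min = 0)
  if (n_activated_targets + n_repressed_targets >= n_genes) {
    abort("Planted target counts must be smaller than `n_genes`.")
  }
  if (length(library_size_range) != 2 || any(library_size_range <= 0) ||
      diff(library_size_range) < 0) {
    abort("`library_size_range` must be two increasing positive numbers.")
  }
  f <- histone_state_fractions
  if (!all(c("promoter", "active_enhancer", "poised") %in% names(f)) ||
      any(f < 0) || any(f > 1) || sum(f) > 1 + 1e-9) {
    abort("`histone_state_fractions` needs promoter/active_enhancer/poised in [0,1] summing to <= 1.")
  }
  if (n_celllines < 1) abort("`n_celllines` must be >= 1.")
  structure(cfg, class = "sim_config")
}

gene_id_pool <- function(n) sprintf("gene%04d", seq_len(n))

nb_draw <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate a tumor/normal expression cohort with planted anchor targets
#'
#' Counts are negative binomial. A per-sample latent anchor activity scales
#' the anchor gene (loading 1) and the planted targets (loading
#' `anchor_coupling`, negated for repressed targets); tumor samples
#' additionally shift the anchor and targets by their planted log2 fold
#' changes. All other genes are independent of both the anchor and the
#' condition. TPM is derived from the counts with simulated gene lengths.
#'
#' @param config A [sim_config()].
#' @return A list with elements `counts` and `tpm` (both [expr_mat]) and
#'   `truth` (a list recording planted gene sets, effect sizes, gene lengths
#'   and the config echo).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "cohort"))
  n_genes <- config$n_genes
  ids <- gene_id_pool(n_genes)
  if (!config$anchor_gene_id %in% ids) {
    abort(sprintf("anchor gene '%s' is not in the simulated gene pool.",
                  config$anchor_gene_id))
  }
  mu <- runif(n_genes, 3, 9)                     # baseline log2 mean count
  names(mu) <- ids
  mu[config$anchor_gene_id] <- runif(1, 6, 8)    # keep the anchor well expressed
  lengths <- round(runif(n_genes, 500, 5000))
  names(lengths) <- ids

  pool <- sample(setdiff(ids, config$anchor_gene_id))
  activated <- sort(pool[seq_len(config$n_activated_targets)])
  repressed <- sort(pool[config$n_activated_targets +
                           seq_len(config$n_repressed_targets)])
  # Planted targets sit in the robustly expressed range: membership in a TF
  # target signature presupposes detectability in the cohort and in every
  # knockdown cell line, so near-silent "targets" are not part of the
  # emulated design (a 3-replicate design has no per-gene power there).
  mu[c(activated, repressed)] <- runif(length(activated) + length(repressed),
                                       8, 10)

  lfc <- setNames(numeric(n_genes), ids)
  lfc[activated] <- abs(rnorm(length(activated), config$target_log2fc_mean,
                              config$target_log2fc_sd))
  lfc[repressed] <- -abs(rnorm(length(repressed), config$target_log2fc_mean,
                               config$target_log2fc_sd))
  lfc[config$anchor_gene_id] <- config$target_log2fc_mean

  # `anchor_coupling` is the target Pearson correlation magnitude between a
  # planted target and the anchor. The latent-factor loading that realises a
  # correlation r against the N(0,1) shared factor, given log2-scale
  # measurement noise sd sigma_eps, is r / sqrt(1 - r^2) * sigma_eps.
  r <- config$anchor_coupling
  sigma_eps <- sqrt(config$nb_dispersion + 2^-9) / log(2)
  lam <- if (r > 0) r / sqrt(1 - min(r, 0.99)^2) * sigma_eps else 0
  beta <- setNames(numeric(n_genes), ids)
  beta[activated] <- lam
  beta[repressed] <- -lam
  beta[config$anchor_gene_id] <- 1

  n_samples <- config$n_tumor + config$n_normal
  sample_id <- c(sprintf("tumor%03d", seq_len(config$n_tumor)),
                 sprintf("normal%03d", seq_len(config$n_normal)))
  condition <- setNames(rep(c("tumor", "normal"),
                            c(config$n_tumor, config$n_normal)), sample_id)
  is_tumor <- as.numeric(condition == "tumor")
  libfac <- runif(n_samples, config$library_size_range[1],
                  config$library_size_range[2])
  z <- rnorm(n_samples)                          # latent anchor activity

  log2_mean <- outer(mu, rep(1, n_samples)) +
    outer(beta, z) + outer(lfc, is_tumor)
  mean_counts <- sweep(2^log2_mean, 2, libfac, "*")
  counts <- matrix(nb_draw(length(mean_counts), as.vector(mean_counts),
                           config$nb_dispersion),
                   nrow = n_genes, dimnames = list(ids, sample_id))
  counts_em <- expr_mat(counts, condition, unit = "count")
  tpm_em <- counts_to_tpm(counts_em, lengths)

  truth <- list(
    activated_gene_ids = activated,
    repressed_gene_ids = repressed,
    anchor_gene_id = config$anchor_gene_id,
    log2fc = lfc,
    gene_lengths = lengths,
    baseline_log2_mean = mu,
    latent_activity = setNames(z, sample_id),
    kd_responsive_map = tibble(
      gene_id = c(activated, repressed),
      expected_kd_direction = rep(c("-", "+"),
                                  c(length(activated), length(repressed)))
    ),
    config = unclass(config)
  )
  list(counts = counts_em, tpm = tpm_em, truth = truth)
}

#' Simulate knockdown experiments for each cell line
#'
#' Each cell line gets `kd_replicates` control and `kd_replicates` knockdown
#' replicates drawn from the cohort's baseline means. Activated targets are
#' shifted down by `kd_effect_log2fc` in the knockdown arm, repressed targets
#' up, non-targets left unshifted.
#'
#' @param config A [sim_config()].
#' @param truth Truth list from [simulate_cohort()].
#' @return Named list of count [expr_mat] objects, one per cell line, with
#'   labels `shControl` / `shKD`.
#' @export
simulate_knockdown <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_celllines < 1) abort("`n_celllines` must be >= 1.")
  ids <- names(truth$baseline_log2_mean)
  shift <- setNames(numeric(length(ids)), ids)
  shift[truth$activated_gene_ids] <- -config$kd_effect_log2fc
  shift[truth$repressed_gene_ids] <- config$kd_effect_log2fc
  shift[truth$anchor_gene_id] <- -config$kd_effect_log2fc  # the anchor itself is depleted

  out <- list()
  for (i in seq_len(config$n_celllines)) {
    cl <- paste0("cell", LETTERS[i])
    set.seed(derive_seed(config$seed, paste0("knockdown_", cl)))
    nrep <- config$kd_replicates
    sample_id <- c(sprintf("%s_ctrl%d", cl, seq_len(nrep)),
                   sprintf("%s_kd%d", cl, seq_len(nrep)))
    condition <- setNames(rep(c("shControl", "shKD"), each = nrep), sample_id)
    is_kd <- as.numeric(condition == "shKD")
    libfac <- runif(2 * nrep, config$library_size_range[1],
                    config$library_size_range[2])
    log2_mean <- outer(truth$baseline_log2_mean, rep(1, 2 * nrep)) +
      outer(shift, is_kd)
    mean_counts <- sweep(2^log2_mean, 2, libfac, "*")
    counts <- matrix(nb_draw(length(mean_counts), as.vector(mean_counts),
                             config$kd_nb_dispersion),
                     nrow = length(ids), dimnames = list(ids, sample_id))
    out[[cl]] <- expr_mat(counts, condition, unit = "count")
  }
  out
}

# ---- regulatory landscape -------------------------------------------------

# Slot geometry: every planted object (gene, super-enhancer, typical
# enhancer, distal TF site) lives in its own slot on a fixed grid, so no two
# objects can fall within stitching reach (12.5 kb) of each other or
# contaminate each other's histone windows.
slot_size_bp <- 50000

#' Simulate a ChIP landscape: TF peaks, histone tracks and gene models
#'
#' Plants super-enhancers (clusters of 4-10 H3K27ac peaks within stitching
#' reach), isolated typical enhancers, and three classes of TF binding sites:
#' promoter-proximal sites at the TSS of planted bound genes, sites inside the
#' planted super-enhancers, and distal sites whose chromatin state (promoter /
#' active enhancer / poised enhancer) is drawn from
#' `histone_state_fractions`. Each state drives which histone marks are
#' elevated around the site (promoter: H3K4me3-high; active enhancer:
#' H3K27ac- and H3K4me1-high; poised: H3K4me1-high only). TF peaks are emitted
#' as two jittered replicates.
#'
#' @param config A [sim_config()].
#' @param truth Truth list from [simulate_cohort()].
#' @return A list: `tf_peaks` (list of two replicate BED tibbles),
#'   `histone_tracks` (named list of bedGraph tibbles for H3K27ac, H3K4me1,
#'   H3K4me3), `gene_models`, `h3k27ac_peaks` (enhancer constituents, the SE
#'   caller's peak input), `chrom_sizes`, and an updated `truth` carrying
#'   `SE_regions`, `typical_regions`, `site_state_labels` and
#'   `bound_gene_ids`.
#' @export
simulate_chip_landscape <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "chip"))
  n_genes <- config$n_genes
  chroms <- paste0("chr", seq_len(config$n_chroms))
  slots_per_chrom <- floor(config$chrom_length / slot_size_bp)
  n_entities <- config$n_planted_SEs + config$n_planted_typical_enhancers +
    config$n_distal_sites
  if (n_genes + n_entities > config$n_chroms * slots_per_chrom) {
    abort(sprintf(
      "chrom_length too small: %d slots available for %d genes + %d planted regions.",
      config$n_chroms * slots_per_chrom, n_genes, n_entities))
  }

  slot_tbl <- tidyr::expand_grid(chrom = chroms,
                                 slot = seq_len(slots_per_chrom) - 1L) |>
    mutate(slot_start = .data$slot * slot_size_bp)
  types <- c(rep("gene", n_genes),
             rep("se", config$n_planted_SEs),
             rep("typ", config$n_planted_typical_enhancers),
             rep("distal", config$n_distal_sites))
  types <- c(types, rep("empty", nrow(slot_tbl) - length(types)))
  slot_tbl$type <- sample(types)

  # Gene models: TSS mid-slot with jitter, random strand.
  gene_slots <- slot_tbl |> filter(.data$type == "gene")
  ids <- gene_id_pool(n_genes)
  tss <- gene_slots$slot_start + 25000L +
    as.integer(round(runif(n_genes, -2000, 2000)))
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  glen <- as.integer(round(runif(n_genes, 2000, 10000)))
  gene_models <- tibble(
    gene_id = ids, chrom = gene_slots$chrom, strand = strand,
    tss = tss, tes = as.integer(ifelse(strand == "+", tss + glen, tss - glen))
  )
  gene_models$tes <- pmax(gene_models$tes, 0L)

  # Super-enhancers: 4-10 constituent peaks with gaps well under the 12.5 kb
  # stitching reach, tall H3K27ac.
  se_slots <- slot_tbl |> filter(.data$type == "se")
  se_peaks <- list(); se_regions <- list()
  for (i in seq_len(nrow(se_slots))) {
    np <- sample(4:10, 1)
    w <- as.integer(round(runif(np, 800, 1200)))
    gap <- as.integer(round(runif(np - 1, 800, 2000)))
    starts <- se_slots$slot_start[i] + 2000L + cumsum(c(0L, head(w, -1) + gap))
    se_peaks[[i]] <- tibble(
      chrom = se_slots$chrom[i], start = starts, end = starts + w,
      name = sprintf("SE%02d_p%d", i, seq_len(np)),
      height = runif(np, 20, 40), se_id = sprintf("SE%02d", i)
    )
    se_regions[[i]] <- tibble(
      se_id = sprintf("SE%02d", i), chrom = se_slots$chrom[i],
      start = min(starts), end = max(starts + w), n_peaks = np
    )
  }
  empty_peaks <- tibble(chrom = character(), start = integer(),
                        end = integer(), name = character(),
                        height = numeric(), se_id = character())
  se_peaks <- bind_rows(c(list(empty_peaks), se_peaks))
  se_regions <- bind_rows(c(list(tibble(se_id = character(), chrom = character(),
                                        start = integer(), end = integer(),
                                        n_peaks = integer())), se_regions))

  typ_slots <- slot_tbl |> filter(.data$type == "typ")
  nt <- nrow(typ_slots)
  tw <- as.integer(round(runif(nt, 800, 1200)))
  # Typical enhancers carry modest summed acetylation near a common plateau
  # with a minority of weaker elements (left-skewed), well below any planted
  # super-enhancer; the area (height x width) is drawn so that total signal,
  # not peak width, sets the rank-curve shape.
  typ_area <- 1000 * (1 + 2 * stats::rbeta(nt, 5, 1))
  typ_peaks <- tibble(
    chrom = typ_slots$chrom, start = typ_slots$slot_start + 2000L,
    end = typ_slots$slot_start + 2000L + tw,
    name = sprintf("TE%03d", seq_len(nt)),
    height = typ_area / tw, se_id = NA_character_
  )

  # TF binding sites --------------------------------------------------------
  planted_targets <- c(truth$activated_gene_ids, truth$repressed_gene_ids)
  n_bound_targets <- round(0.8 * length(planted_targets))
  bound_targets <- sort(sample(planted_targets, n_bound_targets))
  background_pool <- setdiff(ids, c(planted_targets, truth$anchor_gene_id))
  bound_background <- sort(sample(background_pool, 40))
  tss_bound <- c(bound_targets, bound_background)
  gm_idx <- match(tss_bound, gene_models$gene_id)
  tss_sites <- tibble(
    chrom = gene_models$chrom[gm_idx],
    pos = gene_models$tss[gm_idx] +
      as.integer(round(runif(length(tss_bound), -400, 400))),
    state = "active_promoter", origin = "tss", target_gene = tss_bound
  )

  se_site_rows <- se_peaks |>
    group_by(.data$se_id) |>
    dplyr::slice_sample(n = 2) |>
    ungroup()
  se_sites <- tibble(
    chrom = se_site_rows$chrom,
    pos = interval_midpoint(se_site_rows$start, se_site_rows$end),
    state = "active_enhancer", origin = "se", target_gene = NA_character_
  )

  distal_slots <- slot_tbl |> filter(.data$type == "distal")
  frac <- config$histone_state_fractions
  frac <- frac / sum(frac)
  nstate <- round(nrow(distal_slots) * frac)
  nstate[1] <- nrow(distal_slots) - sum(nstate[-1])
  distal_states <- sample(rep(c("active_promoter", "active_enhancer",
                                "poised_enhancer"), nstate))
  distal_sites <- tibble(
    chrom = distal_slots$chrom, pos = distal_slots$slot_start + 10000L,
    state = distal_states, origin = "distal", target_gene = NA_character_
  )

  sites <- bind_rows(tss_sites, se_sites, distal_sites) |>
    arrange(.data$chrom, .data$pos) |>
    mutate(site_id = sprintf("site%04d", row_number()))
  truth$site_state_labels <- sites

  # TF peak replicates: width 400 around each site, jittered per replicate.
  tf_peaks <- lapply(1:2, function(rep_i) {
    jit <- as.integer(round(runif(nrow(sites), -30, 30)))
    tibble(chrom = sites$chrom,
           start = sites$pos - 200L + jit,
           end = sites$pos + 200L + jit,
           name = sprintf("%s_rep%d", sites$site_id, rep_i),
           score = runif(nrow(sites), 5, 100))
  })

  # Histone tracks: level windows per mark, then 200 bp bins + uniform noise.
  lvl <- function(chrom, start, end, level) tibble(chrom = chrom, start = start,
                                                   end = end, level = level)
  enh <- bind_rows(se_peaks, typ_peaks)
  marks <- list(
    H3K27ac = lvl(enh$chrom, enh$start, enh$end, enh$height),
    H3K4me1 = lvl(enh$chrom, enh$start, enh$end,
                  runif(nrow(enh), 10, 20)),
    H3K4me3 = tibble(chrom = character(), start = integer(),
                     end = integer(), level = numeric())
  )
  state_site <- bind_rows(tss_sites, distal_sites)
  win_s <- state_site$pos - 1000L; win_e <- state_site$pos + 1000L
  add_mark <- function(mark, rows, level) {
    marks[[mark]] <<- bind_rows(marks[[mark]],
                                lvl(state_site$chrom[rows], win_s[rows],
                                    win_e[rows], level))
  }
  prom <- which(state_site$state == "active_promoter")
  act <- which(state_site$state == "active_enhancer")
  poi <- which(state_site$state == "poised_enhancer")
  add_mark("H3K4me3", prom, runif(length(prom), 25, 35))
  add_mark("H3K27ac", prom, runif(length(prom), 10, 18))
  add_mark("H3K4me1", prom, runif(length(prom), 2, 6))
  add_mark("H3K27ac", act, runif(length(act), 20, 30))
  add_mark("H3K4me1", act, runif(length(act), 15, 25))
  add_mark("H3K4me3", act, runif(length(act), 0.5, 2))
  add_mark("H3K4me1", poi, runif(length(poi), 15, 25))
  add_mark("H3K27ac", poi, runif(length(poi), 1, 4))
  add_mark("H3K4me3", poi, runif(length(poi), 0.5, 2))

  histone_tracks <- lapply(marks, function(m) {
    m <- merge_level_windows(m)
    binize_with_noise(m, bin = 200L)
  })

  # Planted truth for GREAT-style assignment: TSS-planted targets plus the
  # flanking genes (within 1 Mb) of every non-TSS site.
  nontss <- sites |> filter(.data$origin != "tss")
  flank <- flanking_genes(nontss$chrom, nontss$pos, gene_models,
                          max_extension = 1e6)
  truth$bound_gene_ids <- sort(unique(c(tss_bound, flank)))
  truth$tss_bound_gene_ids <- tss_bound

  # Nearest gene (TSS to region midpoint) per planted SE.
  se_mid <- interval_midpoint(se_regions$start, se_regions$end)
  se_regions$nearest_gene <- vapply(seq_len(nrow(se_regions)), function(i) {
    gm <- gene_models[gene_models$chrom == se_regions$chrom[i], ]
    gm$gene_id[which.min(abs(gm$tss - se_mid[i]))]
  }, character(1))
  truth$SE_regions <- se_regions
  truth$typical_regions <- typ_peaks[, c("chrom", "start", "end", "name")]

  chrom_sizes <- setNames(rep(config$chrom_length, config$n_chroms), chroms)
  list(tf_peaks = tf_peaks,
       histone_tracks = histone_tracks,
       gene_models = gene_models,
       h3k27ac_peaks = enh[, c("chrom", "start", "end", "name")],
       chrom_sizes = chrom_sizes,
       truth = truth)
}

# Genes flanking each position (previous and next TSS on the chromosome,
# capped at max_extension) -- the genes whose extended regulatory domains
# cover an intergenic site under the slot layout.
flanking_genes <- function(chrom, pos, gene_models, max_extension = 1e6) {
  out <- character(0)
  for (cc in unique(chrom)) {
    gm <- gene_models[gene_models$chrom == cc, ]
    gm <- gm[order(gm$tss), ]
    for (p in pos[chrom == cc]) {
      left <- max(which(gm$tss < p), -Inf)
      right <- min(which(gm$tss > p), Inf)
      if (is.finite(left) && p - gm$tss[left] <= max_extension) {
        out <- c(out, gm$gene_id[left])
      }
      if (is.finite(right) && gm$tss[right] - p <= max_extension) {
        out <- c(out, gm$gene_id[right])
      }
    }
  }
  unique(out)
}

# Sum overlapping level windows into disjoint piecewise-constant records.
merge_level_windows <- function(m) {
  if (!nrow(m)) return(m)
  out <- list()
  for (cc in unique(m$chrom)) {
    w <- m[m$chrom == cc, ]
    edges <- sort(unique(c(w$start, w$end)))
    seg_s <- head(edges, -1); seg_e <- edges[-1]
    val <- numeric(length(seg_s))
    for (i in seq_len(nrow(w))) {
      hit <- seg_s >= w$start[i] & seg_e <= w$end[i]
      val[hit] <- val[hit] + w$level[i]
    }
    keep <- val > 0
    out[[cc]] <- tibble(chrom = cc, start = seg_s[keep], end = seg_e[keep],
                        level = val[keep])
  }
  bind_rows(out)
}

# Cut each level record into `bin`-bp pieces and add U(0,1) noise.
binize_with_noise <- function(m, bin = 200L) {
  if (!nrow(m)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  value = numeric()))
  }
  pieces <- lapply(seq_len(nrow(m)), function(i) {
    s <- seq(m$start[i], m$end[i] - 1L, by = bin)
    e <- pmin(s + bin, m$end[i])
    tibble(chrom = m$chrom[i], start = as.integer(s), end = as.integer(e),
           level = m$level[i])
  })
  out <- bind_rows(pieces)
  out$value <- out$level + runif(nrow(out))
  out$level <- NULL
  arrange(out, .data$chrom, .data$start)
}

#' Simulate a clinical survival table tied to one gene's expression
#'
#' Event times are exponential with log hazard linear in the standardised
#' log2(TPM+1) expression of `gene_id` (`mode = "linear"`), or with a planted
#' step at an expression threshold (`mode = "threshold"`, hazard ratio
#' `threshold_hr` above the `threshold_quantile` quantile). Subjects still
#' event-free at `survival_horizon_days` are administratively censored.
#'
#' @param expr_tpm An [expr_mat] tagged `"tpm"`.
#' @param gene_id Gene whose expression drives the hazard.
#' @param config A [sim_config()].
#' @param mode `"linear"` or `"threshold"`.
#' @param threshold_quantile,threshold_hr Planted-threshold parameters.
#' @return A list: `clinical` (tibble `sample_id`, `time_days`, `event`) and
#'   `truth` (threshold used, expression scale parameters).
#' @export
simulate_survival <- function(expr_tpm, gene_id, config,
                              mode = c("linear", "threshold"),
                              threshold_quantile = 0.5, threshold_hr = 3) {
  mode <- match.arg(mode)
  require_unit(expr_tpm, "tpm", "simulate_survival")
  stopifnot(inherits(config, "sim_config"))
  if (!gene_id %in% rownames(expr_tpm$values)) {
    abort(sprintf("gene '%s' absent from the expression matrix.", gene_id))
  }
  set.seed(derive_seed(config$seed, paste0("survival_", mode)))
  x <- log2(expr_tpm$values[gene_id, ] + 1)
  mu_x <- mean(x); sd_x <- sd(x)
  if (sd_x == 0) abort("gene expression is constant; cannot drive a hazard.")
  z <- (x - mu_x) / sd_x
  h0 <- config$survival_baseline_hazard
  if (mode == "linear") {
    rate <- h0 * exp(config$survival_log_hazard_per_sd * z)
    thr <- NA_real_
  } else {
    thr <- unname(quantile(x, threshold_quantile))
    rate <- h0 * exp(log(threshold_hr) * (x > thr))
  }
  t_event <- rexp(length(x), rate)
  horizon <- config$survival_horizon_days
  clinical <- tibble(
    sample_id = names(x),
    time_days = pmin(t_event, horizon),
    event = as.integer(t_event <= horizon)
  )
  list(clinical = clinical,
       truth = list(mode = mode, threshold = thr, expr_mean = mu_x,
                    expr_sd = sd_x,
                    slope = if (mode == "linear") config$survival_log_hazard_per_sd
                            else log(threshold_hr)))
}

#' Write a full synthetic study to a directory
#'
#' Generates the cohort, knockdown experiments, ChIP landscape and clinical
#' table under one config and writes every file in the package's external
#' formats, together with a JSON truth sidecar and a YAML config echo.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory objects and file paths.
#' @export
simulate_to_dir <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  cohort <- simulate_cohort(config)
  kd <- simulate_knockdown(config, cohort$truth)
  chip <- simulate_chip_landscape(config, cohort$truth)
  truth <- chip$truth
  surv <- simulate_survival(cohort$tpm, config$anchor_gene_id, config)
  truth$survival <- surv$truth

  write_expression_matrix(cohort$counts, p("cohort_counts.tsv"),
                          labels_path = p("cohort_labels.tsv"))
  write_expression_matrix(cohort$tpm, p("cohort_tpm.tsv"))
  for (cl in names(kd)) {
    write_expression_matrix(kd[[cl]], p(sprintf("kd_%s_counts.tsv", cl)),
                            labels_path = p(sprintf("kd_%s_labels.tsv", cl)))
  }
  for (i in seq_along(chip$tf_peaks)) {
    write_bed(chip$tf_peaks[[i]], p(sprintf("tf_peaks_rep%d.bed", i)))
  }
  write_bed(chip$h3k27ac_peaks, p("h3k27ac_peaks.bed"))
  for (mk in names(chip$histone_tracks)) {
    write_bedgraph(chip$histone_tracks[[mk]], p(sprintf("%s.bedgraph", mk)))
  }
  write_gene_models(chip$gene_models, p("gene_models.tsv"))
  write_clinical(surv$clinical, p("clinical.tsv"))

  truth_json <- truth
  truth_json$site_state_labels <- as.data.frame(truth$site_state_labels)
  truth_json$SE_regions <- as.data.frame(truth$SE_regions)
  truth_json$typical_regions <- as.data.frame(truth$typical_regions)
  truth_json$kd_responsive_map <- as.data.frame(truth$kd_responsive_map)
  jsonlite::write_json(truth_json, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  yaml::write_yaml(unclass(config), p("config_echo.yaml"))

  invisible(list(cohort = cohort, knockdown = kd, chip = chip,
                 clinical = surv$clinical, truth = truth, dir = outdir))
}
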