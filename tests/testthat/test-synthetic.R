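test_that("cohort simulation plants recoverable anchor coupling", {
  cfg <- small_config(seed = 1, anchor_coupling = 0.6)
  co <- simulate_cohort(cfg)
  expect_s3_class(co$counts, "expr_mat")
  expect_equal(co$counts$unit, "count")
  expect_equal(co$tpm$unit, "tpm")
  expect_equal(dim(co$counts), c(300L, 30L))
  # TPM columns each sum to 1e6
  expect_equal(unname(colSums(co$tpm$values)), rep(1e6, 30), tolerance = 1e-8)

  corr <- suppressMessages(correlate_to_anchor(co$tpm, cfg$anchor_gene_id))
  r_act <- corr$r[corr$gene_id %in% co$truth$activated_gene_ids]
  r_rep <- corr$r[corr$gene_id %in% co$truth$repressed_gene_ids]
  expect_gt(median(r_act), 0)
  expect_lt(median(r_rep), 0)
  sign_acc <- mean(c(r_act > 0, r_rep < 0))
  expect_gte(sign_acc, 0.95)
})

test_that("null coupling yields correlations centered near zero", {
  cfg <- small_config(seed = 5, anchor_coupling = 0,
                      target_log2fc_mean = 0, target_log2fc_sd = 0)
  co <- simulate_cohort(cfg)
  corr <- suppressMessages(correlate_to_anchor(co$tpm, cfg$anchor_gene_id))
  expect_lt(abs(median(corr$r, na.rm = TRUE)), 0.12)
})

test_that("simulation is bitwise deterministic under a fixed seed", {
  cfg <- small_config(seed = 3)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$counts$values, b$counts$values)
  expect_identical(a$tpm$values, b$tpm$values)
  kd_a <- simulate_knockdown(cfg, a$truth)
  kd_b <- simulate_knockdown(cfg, b$truth)
  expect_identical(kd_a$cellA$values, kd_b$cellA$values)
  chip_a <- simulate_chip_landscape(cfg, a$truth)
  chip_b <- simulate_chip_landscape(cfg, b$truth)
  expect_identical(chip_a$tf_peaks, chip_b$tf_peaks)
  expect_identical(chip_a$histone_tracks, chip_b$histone_tracks)
  # distinct seeds give distinct draws
  c2 <- simulate_cohort(small_config(seed = 4))
  expect_false(identical(a$counts$values, c2$counts$values))
})

test_that("knockdown effect sizes match their construction", {
  # equal library sizes so the raw count ratio isolates the planted effect
  cfg <- small_config(seed = 2, kd_effect_log2fc = 2,
                      library_size_range = c(1, 1))
  co <- simulate_cohort(cfg)
  kd <- simulate_knockdown(cfg, co$truth)
  expect_length(kd, 2)
  g <- co$truth$activated_gene_ids
  m <- kd$cellA$values[g, , drop = FALSE]
  labs <- sample_labels(kd$cellA)
  ratio <- rowMeans(m[, labs == "shControl"]) / rowMeans(m[, labs == "shKD"])
  # planted effect -2 log2 => control/KD count ratio ~ 4
  expect_equal(median(ratio), 4, tolerance = 0.15)
  expect_error(simulate_knockdown(sim_config(n_celllines = 0), co$truth),
               "n_celllines")
})

test_that("chip landscape plants stitched SEs and respects its geometry", {
  cfg <- small_config(seed = 1)
  co <- simulate_cohort(cfg)
  chip <- simulate_chip_landscape(cfg, co$truth)
  truth <- chip$truth
  expect_equal(nrow(truth$SE_regions), 3)
  # constituent gaps are under stitching reach, so each SE stitches whole
  st <- stitch(chip$h3k27ac_peaks)
  joined <- dplyr::inner_join(st, truth$SE_regions,
                              by = c("chrom", "start", "end"))
  expect_equal(nrow(joined), nrow(truth$SE_regions))
  expect_equal(joined$n_constituents, joined$n_peaks)
  # infeasible geometry errors
  tight <- small_config(seed = 1)
  tight$chrom_length <- 1e6
  expect_error(simulate_chip_landscape(tight, co$truth), "too small")
  # zero planted SEs -> caller finds none among uniform typicals
  cfg0 <- small_config(seed = 8, n_planted_SEs = 0)
  co0 <- simulate_cohort(cfg0)
  chip0 <- simulate_chip_landscape(cfg0, co0$truth)
  se0 <- call_superenhancers(chip0$h3k27ac_peaks,
                             chip0$histone_tracks$H3K27ac)
  expect_lte(sum(se0$is_SE), ceiling(0.05 * nrow(se0)))
})

test_that("survival generator: null slope is null, planted slope orders groups", {
  cfg <- small_config(seed = 6, survival_log_hazard_per_sd = 0)
  co <- simulate_cohort(cfg)
  # null: median-split log-rank non-significant in >= 90% of replicates
  n_sig <- 0L
  reps <- 40
  for (i in seq_len(reps)) {
    cfg_i <- small_config(seed = 100 + i, survival_log_hazard_per_sd = 0)
    sv <- simulate_survival(co$tpm, cfg$anchor_gene_id, cfg_i)
    x <- log2(co$tpm$values[cfg$anchor_gene_id, ] + 1)
    hi <- x > median(x)
    lr <- logrank_test(sv$clinical$time_days[hi], sv$clinical$event[hi],
                       sv$clinical$time_days[!hi], sv$clinical$event[!hi])
    if (lr$p < 0.05) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig / reps, 0.10)

  # strong positive slope: high-expression group dies earlier
  cfg2 <- small_config(seed = 2, survival_log_hazard_per_sd = log(3))
  sv2 <- simulate_survival(co$tpm, cfg$anchor_gene_id, cfg2)
  x <- log2(co$tpm$values[cfg$anchor_gene_id, ] + 1)
  hi <- x > median(x)
  expect_lt(median(sv2$clinical$time_days[hi]),
            median(sv2$clinical$time_days[!hi]))
  expect_error(simulate_survival(co$tpm, "no_such_gene", cfg2), "absent")

  sv3 <- simulate_survival(co$tpm, cfg$anchor_gene_id, cfg2)
  expect_identical(sv2$clinical, sv3$clinical)
})

test_that("simulate_to_dir writes a complete, reloadable study", {
  dir <- withr::local_tempdir()
  cfg <- small_config(seed = 9)
  sim <- simulate_to_dir(cfg, dir)
  expect_true(file.exists(file.path(dir, "truth.json")))
  back <- read_expression_matrix(file.path(dir, "cohort_counts.tsv"), "count",
                                 file.path(dir, "cohort_labels.tsv"))
  expect_identical(back$values, sim$cohort$counts$values)
  peaks <- read_bed(file.path(dir, "tf_peaks_rep1.bed"))
  expect_equal(nrow(peaks), nrow(sim$chip$tf_peaks[[1]]))
  track <- read_bedgraph(file.path(dir, "H3K27ac.bedgraph"))
  expect_equal(nrow(track), nrow(sim$chip$histone_tracks$H3K27ac))
})
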