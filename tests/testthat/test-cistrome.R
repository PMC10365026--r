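test_that("consensus peaks: identity, 1 bp boundary, and per-base oracle", {
  a <- tibble::tibble(chrom = "chr1", start = c(10L, 50L), end = c(20L, 60L),
                      name = c("p1", "p2"), score = c(5, 7))
  expect_equal(consensus_peaks(list(a, a))[, c("chrom", "start", "end")],
               a[, c("chrom", "start", "end")])

  # peaks overlapping by exactly 1 bp -> consensus is that 1 bp intersection
  b1 <- tibble::tibble(chrom = "chr1", start = 10L, end = 20L, score = 4)
  b2 <- tibble::tibble(chrom = "chr1", start = 19L, end = 30L, score = 6)
  cons <- consensus_peaks(list(b1, b2))
  expect_equal(cons$start, 19L)
  expect_equal(cons$end, 20L)
  expect_equal(cons$score, 5)

  expect_error(consensus_peaks(list(a), min_replicates = 2), ">= 2")

  set.seed(41)
  for (i in 1:60) {
    reps <- lapply(1:sample(2:4, 1), function(j) random_peakset(sample(3:10, 1)))
    minr <- sample(2:3, 1)
    if (length(reps) < minr) next
    got <- consensus_peaks(reps, min_replicates = minr)
    want <- oracle_consensus(reps, minr)
    expect_equal(as.data.frame(got[, c("chrom", "start", "end")]),
                 as.data.frame(want[, c("chrom", "start", "end")]))
    expect_equal(got$score, want$score, tolerance = 1e-9)
    # order independence
    got_rev <- consensus_peaks(rev(reps), min_replicates = minr)
    expect_equal(got[, c("chrom", "start", "end")],
                 got_rev[, c("chrom", "start", "end")])
  }
})

test_that("regulatory domains follow the basal-plus-extension rule", {
  # lone + gene: basal [tss-5k, tss+1k), extension out to 1 Mb, clipped at 0
  gm <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+",
                       tss = 100000L, tes = 105000L)
  d <- build_regulatory_domains(gm, chrom_sizes = c(chr1 = 5e6))
  expect_equal(d$basal_start, 95000)
  expect_equal(d$basal_end, 101000)
  expect_equal(d$ext_start, 0)          # tss - 1 Mb clips at chromosome start
  expect_equal(d$ext_end, 1100000)

  # two + genes 50 kb apart: extension stops at the neighbor's basal boundary
  gm2 <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                        strand = "+", tss = c(100000L, 150000L),
                        tes = c(105000L, 155000L))
  d2 <- build_regulatory_domains(gm2, chrom_sizes = c(chr1 = 5e6))
  expect_equal(d2$ext_start[d2$gene_id == "g2"], 101000)  # g1 basal end
  expect_equal(d2$ext_end[d2$gene_id == "g1"], 145000)    # g2 basal start
})

test_that("domains match the per-base walk oracle over random layouts", {
  set.seed(43)
  for (i in 1:40) {
    n <- sample(2:6, 1)
    gm <- tibble::tibble(
      gene_id = sprintf("g%d", 1:n), chrom = "c1",
      strand = sample(c("+", "-"), n, TRUE),
      tss = sort(sample.int(1800, n)), tes = 0L)
    got <- build_regulatory_domains(gm, basal_up = 50, basal_down = 10,
                                    max_extension = 300,
                                    chrom_sizes = c(c1 = 2000))
    want <- oracle_domains(gm, 50, 10, 300, 2000)
    got <- dplyr::arrange(got, gene_id)
    want <- dplyr::arrange(want, gene_id)
    expect_equal(got$basal_start, want$basal_start)
    expect_equal(got$basal_end, want$basal_end)
    expect_equal(got$ext_start, want$ext_start)
    expect_equal(got$ext_end, want$ext_end)
    # invariants: basal within extended; extension bounded
    expect_true(all(got$ext_start <= got$basal_start))
    expect_true(all(got$ext_end >= got$basal_end))
    expect_true(all(got$ext_end - got$ext_start <=
                      (got$basal_end - got$basal_start) + 2 * 300))
  }
})

test_that("peak assignment by midpoint containment matches brute force", {
  gm <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1", strand = "+",
                       tss = c(100000L, 150000L), tes = c(101000L, 151000L))
  d <- build_regulatory_domains(gm, chrom_sizes = c(chr1 = 5e6))
  # midpoint inside g1's basal only
  p1 <- tibble::tibble(chrom = "chr1", start = 99000L, end = 99400L)
  tm <- assign_peaks(p1, d)
  expect_equal(tm$gene_id, "g1")
  # midpoint in the shared extended gap -> both genes
  p2 <- tibble::tibble(chrom = "chr1", start = 120000L, end = 120400L)
  tm2 <- assign_peaks(p2, d)
  expect_setequal(tm2$gene_id, c("g1", "g2"))

  set.seed(47)
  for (i in 1:30) {
    n <- sample(3:6, 1)
    gm <- tibble::tibble(gene_id = sprintf("g%d", 1:n), chrom = "c1",
                         strand = sample(c("+", "-"), n, TRUE),
                         tss = sort(sample.int(1800, n)), tes = 0L)
    d <- build_regulatory_domains(gm, basal_up = 50, basal_down = 10,
                                  max_extension = 300, chrom_sizes = c(c1 = 2000))
    s <- sample.int(1900, 40, replace = TRUE)
    peaks <- tibble::tibble(chrom = "c1", start = s, end = s + sample.int(60, 40, TRUE))
    got <- assign_peaks(peaks, d)
    want <- oracle_assign(peaks, d)
    got_df <- data.frame(peak_idx = got$peak_idx, gene_id = got$gene_id)
    expect_equal(dplyr::arrange(got_df, peak_idx, gene_id),
                 dplyr::arrange(as.data.frame(want), peak_idx, gene_id))
  }
})

test_that("nearest-only assignment picks the single closest TSS", {
  gm <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1", strand = "+",
                       tss = c(100000L, 150000L), tes = c(101000L, 151000L))
  d <- build_regulatory_domains(gm, chrom_sizes = c(chr1 = 5e6))
  p <- tibble::tibble(chrom = "chr1", start = 120000L, end = 120400L)
  tm <- assign_peaks(p, d, rule = "nearest_only")
  expect_equal(tm$gene_id, "g1")   # 20.2 kb to g1, 29.8 kb to g2
})

test_that("bound_signature requires binding in every cell line's map", {
  sig <- knockdown_filter(
    tibble::tibble(gene_id = c("g1", "g2"), direction = "+",
                   r = 0.5, log2fc = 1, padj = 0.01),
    list(tibble::tibble(gene_id = c("g1", "g2"), log2fc = -2, stat = 0,
                        p = 0.001, padj = 0.01, direction = "-",
                        all_zero = FALSE)))
  tm1 <- structure(tibble::tibble(peak_idx = 1:2, gene_id = c("g1", "g2"),
                                  chrom = "c", start = 1L, end = 2L),
                   class = c("target_map", class(tibble::tibble())))
  tm2 <- structure(tibble::tibble(peak_idx = 1L, gene_id = "g1",
                                  chrom = "c", start = 1L, end = 2L),
                   class = c("target_map", class(tibble::tibble())))
  out <- bound_signature(sig, list(tm1, tm2))
  expect_equal(out$tf_bound, c(TRUE, FALSE))
})

test_that("planted bound genes are recovered through the full cistrome stage", {
  cfg <- small_config(seed = 1)
  co <- simulate_cohort(cfg)
  chip <- simulate_chip_landscape(cfg, co$truth)
  cons <- consensus_peaks(chip$tf_peaks)
  domains <- build_regulatory_domains(chip$gene_models,
                                      chrom_sizes = chip$chrom_sizes)
  tm <- assign_peaks(cons, domains)
  got_bound <- sort(unique(tm$gene_id))
  expect_setequal(got_bound, chip$truth$bound_gene_ids)
})
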