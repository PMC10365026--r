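random_corr_table <- function(genes) {
  tibble::tibble(gene_id = genes,
                 r = runif(length(genes), -1, 1),
                 p = runif(length(genes)),
                 n = 30L, constant = FALSE)
}

random_de_table <- function(genes) {
  p <- runif(length(genes))^2
  tibble::tibble(gene_id = genes,
                 log2fc = rnorm(length(genes), 0, 2),
                 stat = rnorm(length(genes)),
                 p = p, padj = bh_adjust(p),
                 direction = "0", all_zero = FALSE) |>
    dplyr::mutate(direction = ifelse(padj <= 0.1, ifelse(log2fc > 0, "+", "-"), "0"))
}

test_that("concordant overlap applies the sign rule and matches brute force", {
  corr <- tibble::tibble(gene_id = c("a", "b"), r = c(0.5, 0.5),
                         p = c(0.01, 0.01), n = 30L, constant = FALSE)
  de <- tibble::tibble(gene_id = c("a", "b"), log2fc = c(2, -2),
                       stat = 0, p = 0.001, padj = c(0.01, 0.01),
                       direction = c("+", "-"), all_zero = FALSE)
  out <- concordant_overlap(corr, de, fdr = 0.1)
  expect_equal(out$gene_id, "a")
  expect_equal(out$direction, "+")

  set.seed(17)
  for (i in 1:40) {
    genes <- sprintf("g%03d", 1:500)
    corr <- random_corr_table(sample(genes, 480))
    de <- random_de_table(sample(genes, 480))
    got <- suppressMessages(concordant_overlap(corr, de, fdr = 0.1))
    want <- oracle_concordant(corr, de, fdr = 0.1)
    expect_equal(dplyr::arrange(got[, c("gene_id", "direction")], gene_id),
                 dplyr::arrange(want, gene_id))
  }
})

test_that("raising the FDR threshold never shrinks the concordant set", {
  set.seed(23)
  genes <- sprintf("g%03d", 1:300)
  corr <- random_corr_table(genes)
  de <- random_de_table(genes)
  sizes <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.5),
                  function(f) nrow(concordant_overlap(corr, de, fdr = f)),
                  numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("knockdown filter enforces per-cell-line concordance", {
  cand <- tibble::tibble(gene_id = c("a", "b"), direction = c("+", "+"),
                         r = 0.5, log2fc = 2, padj = 0.01)
  kd1 <- tibble::tibble(gene_id = c("a", "b"), log2fc = c(-2, -2),
                        stat = 0, p = 0.001, padj = c(0.01, 0.01),
                        direction = c("-", "-"), all_zero = FALSE)
  kd2 <- kd1
  kd2$padj[2] <- 0.9; kd2$direction[2] <- "0"
  sig <- knockdown_filter(cand, list(c1 = kd1, c2 = kd2), require_all = TRUE)
  expect_equal(sig$gene_id, "a")   # b unchanged in one line -> dropped
  sig_any <- knockdown_filter(cand, list(c1 = kd1, c2 = kd2),
                              require_all = FALSE)
  expect_setequal(sig_any$gene_id, c("a", "b"))

  expect_warning(knockdown_filter(cand[0, ], list(kd1)), "Empty")

  # brute-force equivalence on random tables, both conventions
  set.seed(29)
  for (i in 1:40) {
    genes <- sprintf("g%03d", 1:200)
    cand <- suppressMessages(concordant_overlap(random_corr_table(genes),
                                                random_de_table(genes)))
    kds <- list(a = random_de_table(genes), b = random_de_table(genes))
    for (req in c(TRUE, FALSE)) {
      got <- knockdown_filter(cand, kds, fdr = 0.1, require_all = req)
      expect_setequal(got$gene_id,
                      oracle_kd_filter(cand, kds, 0.1, req))
    }
  }
})

test_that("signature recovery on the scaled-down planted cohort is near-perfect", {
  cfg <- small_config(seed = 1)
  co <- simulate_cohort(cfg)
  corr <- suppressMessages(correlate_to_anchor(co$tpm, cfg$anchor_gene_id))
  de <- differential_expression(co$counts, "normal", "tumor")
  cand <- suppressMessages(concordant_overlap(corr, de))
  kd_de <- lapply(simulate_knockdown(cfg, co$truth), differential_expression,
                  group_a = "shControl", group_b = "shKD")
  sig <- knockdown_filter(cand, kd_de)
  truth_set <- paste0(c(co$truth$activated_gene_ids, co$truth$repressed_gene_ids),
                      rep(c("+", "-"), c(20, 10)))
  got <- paste0(sig$gene_id, sig$direction)
  precision <- mean(got %in% truth_set)
  recall <- sum(got %in% truth_set) / length(truth_set)
  expect_gte(precision, 0.85)
  expect_gte(recall, 0.85)
  # provenance flags are monotone by construction
  expect_true(all(sig$correlated & sig$tumor_de & sig$kd_concordant))
})

test_that("stratification: duplicated blocks give ARI 1, shuffled labels ~0, planted cohort high", {
  # two exactly duplicated sample blocks
  set.seed(5)
  block <- matrix(runif(200, 0, 50), nrow = 20)
  m <- cbind(block + 40, block)
  dimnames(m) <- list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:20))
  labs <- setNames(rep(c("tumor", "normal"), each = 10), colnames(m))
  em <- expr_mat(m, labs, "tpm")
  rep1 <- stratify_cohort(em, rownames(m))
  expect_equal(rep1$ari, 1)
  expect_length(rep1$misassigned, 0)

  cfg <- small_config(seed = 1)
  co <- simulate_cohort(cfg)
  genes <- c(co$truth$activated_gene_ids, co$truth$repressed_gene_ids)
  rep2 <- stratify_cohort(co$tpm, genes)
  expect_gte(rep2$ari, 0.8)

  # shuffled labels: |ARI| small on average
  set.seed(7)
  aris <- replicate(20, {
    shuffled <- setNames(sample(sample_labels(co$tpm)),
                         colnames(co$tpm$values))
    stratify_cohort(co$tpm, genes, labels = shuffled)$ari
  })
  expect_lt(max(abs(aris)), 0.15)

  expect_error(stratify_cohort(co$tpm, "gene0001"), "Fewer than 2")

  g <- glance(rep2)
  expect_equal(g$ari, rep2$ari)
  expect_equal(nrow(tidy(rep2)), 30)
})

test_that("ARI agrees with the mclust reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(19)
  for (i in 1:50) {
    a <- sample(1:3, 40, replace = TRUE)
    b <- sample(1:3, 40, replace = TRUE)
    expect_equal(tfsig:::adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("hypergeometric ORA matches direct summation and degenerate cases", {
  universe <- sprintf("g%03d", 1:100)
  gs <- list(setA = universe[1:10])
  query <- c(universe[1:5], universe[50:54])
  out <- ora_enrichment(query, gs, universe)
  # direct summation of the hypergeometric mass for k in 5..10
  mass <- sum(dhyper(5:10, 10, 90, 10))
  expect_equal(out$p, mass, tolerance = 1e-12)
  expect_equal(out$overlap, 5)
  expect_equal(out$fold, 5 / (10 * 10 / 100))

  # query = set = universe
  out2 <- ora_enrichment(universe, list(all = universe), universe)
  expect_equal(out2$overlap, 100)
  expect_equal(out2$fold, 1)
  expect_equal(out2$p, 1)

  # disjoint query and set
  out3 <- ora_enrichment(universe[1:10], list(s = universe[90:100]), universe)
  expect_equal(out3$overlap, 0)
  expect_equal(out3$fold, 0)
  expect_equal(out3$p, 1)

  expect_error(ora_enrichment("x", list(a = "x"), character(0)), "universe")
  expect_error(ora_enrichment("not_there", list(a = universe[1:5]), universe),
               "outside")
})
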