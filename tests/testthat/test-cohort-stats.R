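test_that("correlation matches the textbook Pearson formula and handles edge cases", {
  em <- tiny_expr(10, 20, unit = "tpm", seed = 13)
  # plant: gene g02 identical to anchor, g03 = anti-monotone after log2
  em$values["g02", ] <- em$values["g01", ]
  em$values["g03", ] <- 2^(20 - log2(em$values["g01", ] + 1)) - 1
  res <- correlate_to_anchor(em, "g01")
  expect_equal(res$r[res$gene_id == "g02"], 1)
  expect_lt(res$p[res$gene_id == "g02"], 1e-12)
  expect_equal(res$r[res$gene_id == "g03"], -1)

  # formula oracle on random pairs
  set.seed(21)
  for (i in 1:25) {
    x <- runif(20, 0, 50); y <- runif(20, 0, 50)
    m <- rbind(a = x, b = y)
    colnames(m) <- sprintf("s%02d", 1:20)
    em2 <- expr_mat(m, setNames(rep("tumor", 20), colnames(m)), "tpm")
    res2 <- correlate_to_anchor(em2, "a", transform = "none")
    o <- oracle_pearson(x, y)
    expect_equal(res2$r, o$r, tolerance = 1e-12)
    expect_equal(res2$p, o$p, tolerance = 1e-12)
  }

  # constant gene flagged, not dropped
  em$values["g04", ] <- 7
  res3 <- suppressMessages(correlate_to_anchor(em, "g01"))
  expect_true(res3$constant[res3$gene_id == "g04"])
  expect_true(is.na(res3$r[res3$gene_id == "g04"]))

  # errors: too few samples; constant anchor
  em_small <- tiny_expr(3, 2, unit = "tpm")
  expect_error(correlate_to_anchor(em_small, "g01"), "3 samples")
  em$values["g01", ] <- 5
  expect_error(correlate_to_anchor(em, "g01"), "constant")
})

test_that("correlation is invariant to sample permutation and affine rescaling", {
  em <- tiny_expr(8, 15, unit = "tpm", seed = 3)
  base <- correlate_to_anchor(em, "g01", transform = "none")
  perm <- sample(colnames(em$values))
  em_p <- subset_expr(em, samples = perm)
  expect_equal(correlate_to_anchor(em_p, "g01", transform = "none")$r, base$r)
  em_s <- em
  em_s$values["g02", ] <- 3 * em_s$values["g02", ] + 10
  expect_equal(correlate_to_anchor(em_s, "g01", transform = "none")$r[1],
               base$r[1], tolerance = 1e-12)
})

test_that("bh_adjust matches hand application, brute force, and stats::p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.42), 0.42)
  set.seed(31)
  for (i in 1:200) {
    p <- runif(sample(1:30, 1))
    a <- bh_adjust(p)
    expect_equal(a, oracle_bh(p))
    expect_equal(a, stats::p.adjust(p, method = "BH"))
    expect_true(all(a >= p) && all(a <= 1))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("size factors recover exact library scalings", {
  m <- matrix(rpois(600, 50) + 1, nrow = 100,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%d", 1:6)))
  m[, 2] <- 2 * m[, 1]
  em <- expr_mat(m, setNames(rep("x", 6), colnames(m)), "count")
  sf <- median_of_ratios_size_factors(em)
  expect_equal(sf[["s2"]] / sf[["s1"]], 2, tolerance = 1e-12)

  same <- expr_mat(matrix(rep(m[, 1], 4), ncol = 4,
                          dimnames = list(rownames(m), paste0("t", 1:4))),
                   setNames(rep("x", 4), paste0("t", 1:4)), "count")
  expect_equal(unname(median_of_ratios_size_factors(same)),
               rep(1, 4), tolerance = 1e-12)

  # normalized per-gene ratios to the geometric mean have median ~ 1
  set.seed(8)
  m2 <- matrix(rnbinom(600, mu = 80, size = 10) + 1, nrow = 100,
               dimnames = dimnames(m))
  em2 <- expr_mat(m2, setNames(rep("x", 6), colnames(m2)), "count")
  sf2 <- median_of_ratios_size_factors(em2)
  norm <- sweep(m2, 2, sf2, "/")
  ratios <- norm / exp(rowMeans(log(norm)))
  expect_equal(median(apply(ratios, 2, median)), 1, tolerance = 0.02)

  zero <- m; zero[cbind(1:100, rep(1:6, length.out = 100))] <- 0
  em0 <- expr_mat(zero, setNames(rep("x", 6), colnames(zero)), "count")
  expect_error(median_of_ratios_size_factors(em0), "reference")
})

test_that("differential expression: nulls, planted effects, and label symmetry", {
  # identical groups (duplicated samples): no log2fc, nothing significant
  base <- matrix(rpois(400, 60), nrow = 100)
  m <- cbind(base, base)
  dimnames(m) <- list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:8))
  labs <- setNames(rep(c("a", "b"), each = 4), colnames(m))
  em <- expr_mat(m, labs, "count")
  de <- differential_expression(em, "a", "b")
  expect_equal(de$log2fc, rep(0, 100))
  expect_false(any(de$direction != "0"))

  # planted 4-fold shift at n=40 vs 40, dispersion 0.05 is recovered
  cfg <- sim_config(n_genes = 400, n_tumor = 40, n_normal = 40,
                    n_activated_targets = 20, n_repressed_targets = 10,
                    target_log2fc_mean = 2, target_log2fc_sd = 0, seed = 12)
  co <- simulate_cohort(cfg)
  de2 <- differential_expression(co$counts, "normal", "tumor", fdr = 0.1)
  idx <- match(co$truth$activated_gene_ids, de2$gene_id)
  expect_true(all(de2$direction[idx] == "+"))
  idx_r <- match(co$truth$repressed_gene_ids, de2$gene_id)
  expect_true(all(de2$direction[idx_r] == "-"))

  # swapping labels negates log2fc and keeps p
  de_swap <- differential_expression(co$counts, "tumor", "normal", fdr = 0.1)
  expect_equal(de_swap$log2fc, -de2$log2fc)
  expect_equal(de_swap$p, de2$p)

  # group with < 2 samples errors
  em3 <- tiny_expr(5, 3, unit = "count")
  expect_error(differential_expression(em3, "tumor", "normal"), ">= 2 samples")

  # all-zero gene flagged with p = 1
  m4 <- co$counts$values
  m4["gene0400", ] <- 0
  em4 <- expr_mat(m4, sample_labels(co$counts), "count")
  de4 <- differential_expression(em4, "normal", "tumor")
  row <- de4[de4$gene_id == "gene0400", ]
  expect_true(row$all_zero)
  expect_equal(row$log2fc, 0)
  expect_equal(row$p, 1)
})

test_that("Welch statistics agree with stats::t.test gene by gene", {
  cfg <- small_config(seed = 14)
  co <- simulate_cohort(cfg)
  sub <- co$counts
  sf <- median_of_ratios_size_factors(sub)
  lg <- log2(sweep(sub$values, 2, sf, "/") + 1)
  labs <- sample_labels(sub)
  de <- differential_expression(sub, "normal", "tumor")
  set.seed(2)
  for (g in sample(rownames(lg), 20)) {
    tt <- t.test(lg[g, labs == "tumor"], lg[g, labs == "normal"])
    i <- which(de$gene_id == g)
    expect_equal(de$stat[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(de$p[i], tt$p.value, tolerance = 1e-10)
  }
})
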