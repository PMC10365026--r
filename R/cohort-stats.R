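# Anchor-gene correlation and the defined differential-expression engine:
# median-of-ratios size factors, Welch t on log2(normalized count + 1), and
# Benjamini-Hochberg step-up adjustment.

#' Correlate every gene with an anchor gene
#'
#' Computes a per-gene correlation of expression with the anchor gene over
#' all samples pooled (normal and tumor together, so the normal samples set
#' the baseline). Default is Pearson on log2(TPM+1) with a two-sided
#' t-distribution p-value; Spearman and the untransformed scale are
#' available as options.
#'
#' @param expr_tpm An [expr_mat] tagged `"tpm"`.
#' @param anchor_gene_id Gene id of the anchor.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param transform `"log2p1"` (default) or `"none"`.
#' @return A tibble with one row per non-anchor gene: `gene_id`, `r`, `p`,
#'   `n`, `constant` (TRUE where the gene is constant across samples, in
#'   which case `r` and `p` are `NA` rather than silently dropped).
#' @export
correlate_to_anchor <- function(expr_tpm, anchor_gene_id,
                                method = c("pearson", "spearman"),
                                transform = c("log2p1", "none")) {
  method <- match.arg(method)
  transform <- match.arg(transform)
  require_unit(expr_tpm, "tpm", "correlate_to_anchor")
  m <- expr_tpm$values
  if (!anchor_gene_id %in% rownames(m)) {
    abort(sprintf("anchor gene '%s' not found.", anchor_gene_id))
  }
  n <- ncol(m)
  if (n < 3) abort("Need at least 3 samples for correlation.")
  if (transform == "log2p1") m <- log2(m + 1)
  if (method == "spearman") m <- t(apply(m, 1, rank))
  x <- m[anchor_gene_id, ]
  if (sd(x) == 0) abort("anchor gene is constant across samples.")
  y <- m[setdiff(rownames(m), anchor_gene_id), , drop = FALSE]
  constant <- apply(y, 1, sd) == 0
  r <- suppressWarnings(as.vector(cor(x, t(y))))
  r[constant] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 - 1e-15] <- 0
  n_const <- sum(constant)
  if (n_const > 0) {
    inform(sprintf("correlate_to_anchor: %d constant gene(s) flagged (r = NA).",
                   n_const))
  }
  tibble(gene_id = rownames(y), r = unname(r),
         p = unname(ifelse(constant, NA_real_, p)),
         n = n, constant = unname(constant))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' The step-up construction: sort p ascending, multiply by m/rank, enforce
#' monotonicity from the largest rank downwards, cap at 1.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\] (NA passed through).
#' @return Adjusted p-values, elementwise `>=` the input and `<=` 1.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  if (any(p < 0 | p > 1)) abort("p-values must lie in [0, 1].")
  m <- length(p)
  out <- rep(NA_real_, length(pvalues))
  if (m > 0) {
    o <- order(p)
    ranked <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(ranked)))
    adj <- pmin(adj, 1)
    res <- numeric(m)
    res[o] <- adj
    out[ok] <- res
  }
  out
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over reference-expressible genes (nonzero in
#' every sample) of the ratio of its count to the gene's geometric mean
#' across samples.
#'
#' @param expr_counts An [expr_mat] tagged `"count"`.
#' @return Named positive numeric vector, one factor per sample.
#' @export
median_of_ratios_size_factors <- function(expr_counts) {
  require_unit(expr_counts, "count", "median_of_ratios_size_factors")
  m <- expr_counts$values
  ref <- rowSums(m == 0) == 0
  if (!any(ref)) abort("No gene has a nonzero count in every sample; cannot form the reference.")
  logm <- log(m[ref, , drop = FALSE])
  geomean_log <- rowMeans(logm)
  sf <- apply(exp(sweep(logm, 1, geomean_log, "-")), 2, median)
  setNames(sf, colnames(m))
}

welch_t_rows <- function(a, b) {
  # a, b: matrices genes x samples per group; returns list(stat, df, p).
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, var); vb <- apply(b, 1, var)
  se2 <- va / na + vb / nb
  stat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  zero <- se2 == 0
  stat[zero] <- 0
  df[zero] <- na + nb - 2
  p <- 2 * pt(-abs(stat), df = df)
  p[zero] <- 1
  list(stat = stat, df = df, p = p)
}

#' Differential expression between two sample groups
#'
#' The package's defined DE engine: median-of-ratios normalization, Welch's
#' t-test per gene on log2(normalized count + 1), Benjamini-Hochberg
#' adjustment, and a signed call at `padj <= fdr`. Log2 fold changes are
#' group B over group A.
#'
#' @param expr_counts An [expr_mat] tagged `"count"`.
#' @param group_a,group_b Condition labels for the baseline (A) and contrast
#'   (B) groups; each must cover at least 2 samples.
#' @param fdr False-discovery-rate threshold for the signed call
#'   (default 0.1).
#' @return A tibble: `gene_id`, `log2fc`, `stat`, `p`, `padj`, `direction`
#'   (`"+"`, `"-"`, or `"0"`), `all_zero` (flag for genes with no counts in
#'   either group, reported with `log2fc = 0`, `p = 1`).
#' @export
differential_expression <- function(expr_counts, group_a, group_b, fdr = 0.1) {
  require_unit(expr_counts, "count", "differential_expression")
  labs <- sample_labels(expr_counts)
  ia <- which(labs == group_a); ib <- which(labs == group_b)
  if (length(ia) < 2 || length(ib) < 2) {
    abort(sprintf("Each group needs >= 2 samples (got %d '%s', %d '%s').",
                  length(ia), group_a, length(ib), group_b))
  }
  m <- expr_counts$values[, c(ia, ib), drop = FALSE]
  sub <- expr_mat(m, labs[c(ia, ib)], unit = "count")
  sf <- median_of_ratios_size_factors(sub)
  norm <- sweep(m, 2, sf, "/")
  lg <- log2(norm + 1)
  a <- lg[, seq_along(ia), drop = FALSE]
  b <- lg[, length(ia) + seq_along(ib), drop = FALSE]
  wt <- welch_t_rows(a, b)
  log2fc <- rowMeans(b) - rowMeans(a)
  all_zero <- rowSums(m) == 0
  log2fc[all_zero] <- 0
  wt$stat[all_zero] <- 0
  wt$p[all_zero] <- 1
  padj <- bh_adjust(wt$p)
  direction <- ifelse(padj <= fdr & log2fc > 0, "+",
                      ifelse(padj <= fdr & log2fc < 0, "-", "0"))
  tibble(gene_id = rownames(m), log2fc = unname(log2fc), stat = unname(wt$stat),
         p = unname(wt$p), padj = unname(padj), direction = direction,
         all_zero = unname(all_zero))
}
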