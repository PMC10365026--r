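# The core integration: sign-concordant overlap of correlation and tumor DE,
# knockdown-concordance filtering across cell lines, consensus signature
# assembly, cohort stratification, and hypergeometric over-representation.

new_signature <- function(tbl, thresholds = list()) {
  structure(tbl, class = c("consensus_signature", class(tibble())),
            thresholds = thresholds)
}

#' Sign-concordant overlap of correlation and differential expression
#'
#' A gene is kept with direction `"+"` iff its anchor correlation is positive
#' and it is significantly up in the contrast group (`padj <= fdr`,
#' `log2fc > 0`); with `"-"` iff correlation negative and significantly down.
#' Everything else, including genes missing from either table or flagged
#' constant, is excluded. By default only the correlation's sign is used; an
#' optional p-value cap on the correlation can be switched on.
#'
#' @param corr_results Tibble from [correlate_to_anchor()].
#' @param de_results Tibble from [differential_expression()].
#' @param fdr FDR threshold applied to the DE adjusted p-values.
#' @param corr_p_max Optional cap on the correlation p-value (default `NULL`:
#'   sign only).
#' @return A directed gene-set tibble: `gene_id`, `direction`, `r`, `log2fc`,
#'   `padj`.
#' @export
concordant_overlap <- function(corr_results, de_results, fdr = 0.1,
                               corr_p_max = NULL) {
  joined <- inner_join(corr_results, de_results, by = "gene_id",
                       suffix = c("_corr", "_de"))
  n_missing <- nrow(corr_results) + nrow(de_results) - 2 * nrow(joined)
  if (n_missing > 0) {
    inform(sprintf("concordant_overlap: %d gene(s) present in only one table were excluded.",
                   n_missing))
  }
  keep <- !is.na(joined$r) & joined$padj <= fdr &
    ((joined$r > 0 & joined$log2fc > 0) | (joined$r < 0 & joined$log2fc < 0))
  if (!is.null(corr_p_max)) {
    keep <- keep & !is.na(joined$p_corr) & joined$p_corr <= corr_p_max
  }
  out <- joined[keep, , drop = FALSE]
  tibble(gene_id = out$gene_id,
         direction = ifelse(out$r > 0, "+", "-"),
         r = out$r, log2fc = out$log2fc, padj = out$padj)
}

#' Knockdown-concordance filter and consensus signature assembly
#'
#' A `"+"` candidate (tumor-up, anchor-correlated) survives iff it goes
#' significantly *down* when the anchor is depleted, in every required cell
#' line; a `"-"` candidate iff it goes significantly up. This is the
#' anchor-as-activator reading; `convention = "inverse"` flips it.
#'
#' @param candidates Directed gene set from [concordant_overlap()].
#' @param kd_de_tables Named list of DE tibbles (control vs knockdown, log2fc
#'   knockdown over control), one per cell line.
#' @param fdr FDR threshold applied within each knockdown table.
#' @param require_all If `TRUE` (default) the gene must respond in every cell
#'   line; otherwise in at least one.
#' @param convention `"activator"` (default) or `"inverse"`.
#' @return A `consensus_signature` tibble: `gene_id`, `direction`, and
#'   provenance flags `correlated`, `tumor_de`, `kd_concordant` (all TRUE for
#'   surviving genes), `tf_bound`, `se_associated` (FALSE until set by the
#'   cistrome / super-enhancer stages).
#' @export
knockdown_filter <- function(candidates, kd_de_tables, fdr = 0.1,
                             require_all = TRUE,
                             convention = c("activator", "inverse")) {
  convention <- match.arg(convention)
  if (!length(kd_de_tables)) abort("Need at least one knockdown DE table.")
  if (!nrow(candidates)) {
    warn("Empty candidate set; returning an empty signature.")
    return(new_signature(tibble(gene_id = character(), direction = character(),
                                correlated = logical(), tumor_de = logical(),
                                kd_concordant = logical(), tf_bound = logical(),
                                se_associated = logical()),
                         thresholds = list(fdr = fdr, require_all = require_all)))
  }
  # Required knockdown response: activators' targets fall when the anchor is
  # depleted ("+"-candidates must be "-" in the knockdown tables).
  wanted <- if (convention == "activator") {
    ifelse(candidates$direction == "+", "-", "+")
  } else {
    candidates$direction
  }
  hits <- vapply(kd_de_tables, function(de) {
    idx <- match(candidates$gene_id, de$gene_id)
    resp <- de$direction[idx]
    !is.na(resp) & resp == wanted & de$padj[idx] <= fdr
  }, logical(nrow(candidates)))
  hits <- matrix(hits, nrow = nrow(candidates))
  ok <- if (require_all) rowSums(hits) == length(kd_de_tables) else rowSums(hits) >= 1
  out <- candidates[ok, c("gene_id", "direction"), drop = FALSE]
  new_signature(
    tibble(gene_id = out$gene_id, direction = out$direction,
           correlated = TRUE, tumor_de = TRUE, kd_concordant = TRUE,
           tf_bound = FALSE, se_associated = FALSE),
    thresholds = list(fdr = fdr, require_all = require_all,
                      convention = convention,
                      n_celllines = length(kd_de_tables))
  )
}

# Adjusted Rand index from the contingency-table closed form.
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

#' Stratify a cohort by a gene signature
#'
#' Standardises each signature gene (z-score of log2(TPM+1) over samples),
#' clusters the samples by average-linkage agglomerative clustering on
#' Euclidean distance, cuts the tree at `k`, and scores the agreement of the
#' cut with the condition labels by the adjusted Rand index.
#'
#' @param expr_tpm An [expr_mat] tagged `"tpm"`.
#' @param signature A `consensus_signature` or character vector of gene ids.
#' @param labels Optional named condition vector (defaults to the matrix's
#'   own sample labels).
#' @param k Number of clusters to cut (default 2, tumor vs normal).
#' @return A `stratification_report` list: `assignments` (tibble sample_id,
#'   cluster, condition), `ari`, `misassigned` (sample ids off the majority
#'   mapping), `linkage`, `n_genes_used`.
#' @export
stratify_cohort <- function(expr_tpm, signature, labels = NULL, k = 2) {
  require_unit(expr_tpm, "tpm", "stratify_cohort")
  genes <- if (is.character(signature)) signature else signature$gene_id
  genes <- intersect(genes, rownames(expr_tpm$values))
  if (length(genes) < 2) {
    abort("Fewer than 2 signature genes are present in the matrix.")
  }
  labels <- labels %||% sample_labels(expr_tpm)
  labels <- labels[colnames(expr_tpm$values)]
  lg <- log2(expr_tpm$values[genes, , drop = FALSE] + 1)
  sds <- apply(lg, 1, sd)
  lg <- lg[sds > 0, , drop = FALSE]
  z <- (lg - rowMeans(lg)) / apply(lg, 1, sd)
  hc <- hclust(dist(t(z), method = "euclidean"), method = "average")
  cl <- cutree(hc, k = k)
  ari <- adjusted_rand_index(cl, labels)
  # Misassigned samples under the cluster->label mapping that maximises
  # agreement (majority label per cluster).
  assign_tbl <- tibble(sample_id = names(cl), cluster = unname(cl),
                       condition = unname(labels))
  maj <- assign_tbl |>
    dplyr::count(.data$cluster, .data$condition) |>
    group_by(.data$cluster) |>
    dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select(cluster = "cluster", majority = "condition")
  mis <- assign_tbl |>
    left_join(maj, by = "cluster") |>
    filter(.data$condition != .data$majority)
  structure(list(assignments = assign_tbl, ari = ari,
                 misassigned = mis$sample_id,
                 linkage = "average-linkage hclust, Euclidean on gene-wise z-scores",
                 n_genes_used = nrow(z), k = k),
            class = "stratification_report")
}

#' @export
print.stratification_report <- function(x, ...) {
  cat(sprintf("<stratification_report> k = %d, %d genes, ARI = %.3f, %d misassigned\n",
              x$k, x$n_genes_used, x$ari, length(x$misassigned)))
  invisible(x)
}

#' @rdname stratify_cohort
#' @param x A `stratification_report`.
#' @param ... Unused.
#' @export
tidy.stratification_report <- function(x, ...) x$assignments

#' @rdname stratify_cohort
#' @export
glance.stratification_report <- function(x, ...) {
  tibble(k = x$k, n_genes_used = x$n_genes_used, ari = x$ari,
         n_misassigned = length(x$misassigned))
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper-tail hypergeometric probability of observing
#' at least the seen overlap between the query and the set within the
#' universe, with BH adjustment and fold enrichment (observed / expected
#' overlap).
#'
#' @param query_genes Character vector; must be a subset of `universe`.
#' @param gene_sets Named list of character vectors (intersected with the
#'   universe).
#' @param universe Character vector of all assayable genes.
#' @return A tibble: `set`, `set_size`, `overlap`, `expected`, `fold`,
#'   `p`, `q`.
#' @export
ora_enrichment <- function(query_genes, gene_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) abort("Empty universe.")
  query_genes <- unique(query_genes)
  outside <- setdiff(query_genes, universe)
  if (length(outside)) {
    abort(sprintf("Query gene(s) outside the universe: %s",
                  paste(head(outside, 5), collapse = ", ")))
  }
  n_u <- length(universe)
  n_q <- length(query_genes)
  rows <- purrr::imap(gene_sets, function(gs, nm) {
    gs <- intersect(unique(gs), universe)
    k <- length(intersect(query_genes, gs))
    expected <- n_q * length(gs) / n_u
    tibble(set = nm, set_size = length(gs), overlap = k,
           expected = expected,
           fold = if (expected > 0) k / expected else NA_real_,
           p = phyper(k - 1, length(gs), n_u - length(gs), n_q,
                      lower.tail = FALSE))
  })
  out <- bind_rows(rows)
  out$q <- bh_adjust(out$p)
  out
}
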