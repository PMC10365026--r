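#' Expression matrix container
#'
#' A light container for a genes x samples abundance matrix with per-sample
#' condition labels and an explicit unit tag. The unit tag (`"tpm"` or
#' `"count"`) travels with the object so that operations can declare which
#' unit they require instead of silently accepting the wrong one.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row and
#'   column names are the gene and sample identifiers and must be unique.
#' @param labels Named character vector mapping every sample id to a condition
#'   string (e.g. `"tumor"`, `"normal"`, `"shControl"`, `"shKD"`).
#' @param unit Either `"tpm"` or `"count"`.
#' @return An object of class `expr_mat`.
#' @examples
#' m <- matrix(1:6, nrow = 3, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' em <- expr_mat(m, c(s1 = "tumor", s2 = "normal"), unit = "count")
#' dim(em)
#' @export
expr_mat <- function(values, labels, unit = c("tpm", "count")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples).")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry gene ids as rownames and sample ids as colnames.")
  }
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g)) {
    abort(sprintf("Duplicated gene id(s): %s", paste(head(dup_g, 5), collapse = ", ")))
  }
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s)) {
    abort(sprintf("Duplicated sample id(s): %s", paste(head(dup_s, 5), collapse = ", ")))
  }
  if (any(!is.finite(values))) abort("All expression values must be finite.")
  if (any(values < 0)) abort("All expression values must be >= 0.")
  labels <- labels[colnames(values)]
  if (any(is.na(labels)) || is.null(names(labels))) {
    abort("`labels` must name a condition for every sample id.")
  }
  structure(
    list(values = values, labels = as.character(setNames(labels, colnames(values))),
         unit = unit),
    class = "expr_mat"
  )
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  cat("conditions:", paste(sprintf("%s=%d", names(table(x$labels)),
                                   table(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' Gene and sample accessors for `expr_mat`
#'
#' @param x An `expr_mat`.
#' @return Character vectors of identifiers.
#' @export
gene_ids <- function(x) {
  stopifnot(inherits(x, "expr_mat"))
  rownames(x$values)
}

#' @rdname gene_ids
#' @export
sample_ids <- function(x) {
  stopifnot(inherits(x, "expr_mat"))
  colnames(x$values)
}

#' Condition labels of an `expr_mat`
#'
#' @param x An `expr_mat`.
#' @return Named character vector, one condition per sample.
#' @export
sample_labels <- function(x) {
  stopifnot(inherits(x, "expr_mat"))
  setNames(x$labels, colnames(x$values))
}

# Internal: check the unit tag of an expr_mat before a unit-sensitive step.
require_unit <- function(x, unit, op) {
  if (!inherits(x, "expr_mat")) abort(sprintf("`%s` expects an `expr_mat`.", op))
  if (!identical(x$unit, unit)) {
    abort(sprintf("`%s` requires unit '%s' but the matrix is tagged '%s'.",
                  op, unit, x$unit))
  }
  invisible(x)
}

#' Tidy an expression matrix into long form
#'
#' @param x An `expr_mat`.
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `sample_id`, `value`, `condition`,
#'   `unit`.
#' @export
tidy.expr_mat <- function(x, ...) {
  labs <- sample_labels(x)
  tibble(
    gene_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values),
    condition = rep(unname(labs), each = nrow(x$values)),
    unit = x$unit
  )
}

#' Subset an `expr_mat` by genes and/or samples
#'
#' @param x An `expr_mat`.
#' @param genes,samples Character vectors of ids to keep (default: all).
#' @return A new `expr_mat`.
#' @export
subset_expr <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "expr_mat"))
  g <- genes %||% rownames(x$values)
  s <- samples %||% colnames(x$values)
  missing_g <- setdiff(g, rownames(x$values))
  if (length(missing_g)) {
    abort(sprintf("Gene id(s) not present: %s", paste(head(missing_g, 5), collapse = ", ")))
  }
  missing_s <- setdiff(s, colnames(x$values))
  if (length(missing_s)) {
    abort(sprintf("Sample id(s) not present: %s", paste(head(missing_s, 5), collapse = ", ")))
  }
  expr_mat(x$values[g, s, drop = FALSE], sample_labels(x)[s], unit = x$unit)
}

#' Convert raw counts to transcripts per million
#'
#' Length-normalises each gene then rescales every sample to sum to one
#' million, the standard TPM construction.
#'
#' @param x An `expr_mat` tagged `"count"`.
#' @param gene_lengths Named numeric vector of effective gene lengths in bp,
#'   covering every gene in `x`.
#' @return An `expr_mat` tagged `"tpm"`.
#' @export
counts_to_tpm <- function(x, gene_lengths) {
  require_unit(x, "count", "counts_to_tpm")
  len <- gene_lengths[rownames(x$values)]
  if (any(is.na(len)) || any(len <= 0)) {
    abort("`gene_lengths` must provide a positive length for every gene.")
  }
  rate <- x$values / len
  tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6
  tpm[is.nan(tpm)] <- 0
  expr_mat(tpm, sample_labels(x), unit = "tpm")
}
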