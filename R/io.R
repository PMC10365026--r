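# Readers and writers for every external file the pipeline touches.
# All interval files use the 0-based half-open convention (BED-native).

read_tsv_strict <- function(path, col_types) {
  out <- readr::read_tsv(path, col_types = col_types, progress = FALSE,
                         na = character())
  probs <- readr::problems(out)
  if (nrow(probs)) {
    abort(sprintf("Parse error in '%s' at line %d: %s",
                  path, probs$row[1] + 1L, probs$expected[1]))
  }
  out
}

#' Read / write a tab-separated expression matrix
#'
#' The file has gene ids in the first column and sample ids in the header.
#' Condition labels are supplied separately, either as a named character
#' vector or as a path to a two-column tab-separated file
#' (`sample_id`, `condition`).
#'
#' @param path File path.
#' @param unit Unit tag for the values, `"tpm"` or `"count"`.
#' @param labels Named character vector or path to a labels file.
#' @return An [expr_mat].
#' @export
read_expression_matrix <- function(path, unit = c("tpm", "count"), labels) {
  unit <- match.arg(unit)
  df <- read_tsv_strict(path, readr::cols(.default = readr::col_double(),
                                          gene_id = readr::col_character()))
  if (names(df)[1] != "gene_id") {
    abort(sprintf("'%s': first column must be named 'gene_id'.", path))
  }
  ids <- df$gene_id
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    abort(sprintf("'%s': duplicated gene id(s): %s", path,
                  paste(head(dup, 5), collapse = ", ")))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    abort(sprintf("'%s': non-finite value at gene '%s', sample '%s'.",
                  path, ids[bad[1]], colnames(m)[bad[2]]))
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("'%s': negative value at gene '%s', sample '%s'.",
                  path, ids[bad[1]], colnames(m)[bad[2]]))
  }
  rownames(m) <- ids
  if (is.character(labels) && length(labels) == 1L && is.null(names(labels)) &&
      file.exists(labels)) {
    lab_df <- read_tsv_strict(labels, readr::cols(
      sample_id = readr::col_character(), condition = readr::col_character()))
    labels <- setNames(lab_df$condition, lab_df$sample_id)
  }
  expr_mat(m, labels, unit = unit)
}

#' @rdname read_expression_matrix
#' @param x An [expr_mat] to write.
#' @param labels_path Optional path for the sample/condition table.
#' @export
write_expression_matrix <- function(x, path, labels_path = NULL) {
  stopifnot(inherits(x, "expr_mat"))
  df <- tibble(gene_id = rownames(x$values))
  df <- dplyr::bind_cols(df, as_tibble(x$values))
  readr::write_tsv(df, path)
  if (!is.null(labels_path)) {
    readr::write_tsv(tibble(sample_id = colnames(x$values),
                            condition = unname(sample_labels(x))), labels_path)
  }
  invisible(path)
}

validate_intervals <- function(x, path = "<intervals>") {
  if (any(x$start < 0)) {
    abort(sprintf("'%s': negative start coordinate (row %d).",
                  path, which(x$start < 0)[1]))
  }
  bad <- which(x$end <= x$start)
  if (length(bad)) {
    abort(sprintf("'%s': end <= start at row %d (%s:%d-%d); intervals are 0-based half-open and must be non-empty.",
                  path, bad[1], x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]]))
  }
  invisible(x)
}

#' Read / write BED intervals
#'
#' Accepts BED3 (chrom, start, end) optionally followed by name and score
#' columns. Coordinates are 0-based half-open; record order is preserved.
#'
#' @param path File path.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`.
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (ncol(raw) < 3) abort(sprintf("'%s': BED needs at least 3 columns.", path))
  out <- tibble(
    chrom = raw[[1]],
    start = suppressWarnings(as.integer(raw[[2]])),
    end = suppressWarnings(as.integer(raw[[3]])),
    name = if (ncol(raw) >= 4) raw[[4]] else NA_character_,
    score = if (ncol(raw) >= 5) suppressWarnings(as.numeric(raw[[5]])) else NA_real_
  )
  if (anyNA(out$start) || anyNA(out$end)) {
    abort(sprintf("'%s': non-integer coordinate at line %d.",
                  path, which(is.na(out$start) | is.na(out$end))[1]))
  }
  validate_intervals(out, path)
  if (any(!is.na(out$score) & out$score < 0)) {
    abort(sprintf("'%s': negative score.", path))
  }
  out
}

#' @rdname read_bed
#' @param x Interval tibble (`chrom`, `start`, `end`, optional `name`, `score`).
#' @export
write_bed <- function(x, path) {
  validate_intervals(x, path)
  cols <- c("chrom", "start", "end")
  if ("name" %in% names(x) && any(!is.na(x$name))) cols <- c(cols, "name")
  if ("score" %in% names(x) && any(!is.na(x$score))) {
    cols <- unique(c(cols, "name", "score"))
  }
  out <- x[, cols, drop = FALSE]
  if ("name" %in% cols) out$name[is.na(out$name)] <- "."
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read / write a bedGraph signal track
#'
#' Four columns (chrom, start, end, value); values must be non-negative and
#' constant over each record. Records are sorted per chromosome on read;
#' overlapping records within a chromosome are rejected. Gaps mean value 0.
#'
#' @param path File path.
#' @return A tibble (`chrom`, `start`, `end`, `value`) sorted by
#'   chromosome and start.
#' @export
read_bedgraph <- function(path) {
  raw <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                         progress = FALSE,
                         col_types = readr::cols(
                           chrom = readr::col_character(),
                           start = readr::col_integer(),
                           end = readr::col_integer(),
                           value = readr::col_double()))
  probs <- readr::problems(raw)
  if (nrow(probs)) {
    abort(sprintf("'%s': parse error at line %d.", path, probs$row[1]))
  }
  validate_intervals(raw, path)
  if (any(raw$value < 0)) abort(sprintf("'%s': negative signal value.", path))
  out <- dplyr::arrange(raw, .data$chrom, .data$start)
  ovl <- out |>
    group_by(.data$chrom) |>
    mutate(prev_end = dplyr::lag(.data$end)) |>
    ungroup() |>
    filter(!is.na(.data$prev_end) & .data$start < .data$prev_end)
  if (nrow(ovl)) {
    abort(sprintf("'%s': overlapping records on %s (record ending %d overlaps record starting %d).",
                  path, ovl$chrom[1], ovl$prev_end[1], ovl$start[1]))
  }
  out$prev_end <- NULL
  out
}

#' @rdname read_bedgraph
#' @param x Signal tibble (`chrom`, `start`, `end`, `value`).
#' @export
write_bedgraph <- function(x, path) {
  validate_intervals(x, path)
  readr::write_tsv(x[, c("chrom", "start", "end", "value")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read / write gene models
#'
#' A minimal tab-separated table (`gene_id`, `chrom`, `strand`, `tss`, `tes`)
#' carrying just what regulatory-domain construction needs. `strand` must be
#' `+` or `-`; for `-` genes "upstream" is the numerically increasing side.
#'
#' @param path File path.
#' @return A tibble of gene models.
#' @export
read_gene_models <- function(path) {
  df <- read_tsv_strict(path, readr::cols(
    gene_id = readr::col_character(), chrom = readr::col_character(),
    strand = readr::col_character(), tss = readr::col_integer(),
    tes = readr::col_integer()))
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad)) {
    abort(sprintf("'%s': unknown strand '%s' for gene '%s'.",
                  path, df$strand[bad[1]], df$gene_id[bad[1]]))
  }
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup)) {
    abort(sprintf("'%s': duplicated gene id(s): %s", path,
                  paste(head(dup, 5), collapse = ", ")))
  }
  if (any(df$tss < 0)) abort(sprintf("'%s': negative TSS.", path))
  df
}

#' @rdname read_gene_models
#' @param x Gene-model tibble.
#' @export
write_gene_models <- function(x, path) {
  readr::write_tsv(x[, c("gene_id", "chrom", "strand", "tss", "tes")], path)
  invisible(path)
}

#' Read / write a clinical survival table
#'
#' Columns `sample_id`, `time_days` (> 0, finite) and `event` (0 censored,
#' 1 event), one row per sample.
#'
#' @param path File path.
#' @return A tibble (`sample_id`, `time_days`, `event`).
#' @export
read_clinical <- function(path) {
  df <- read_tsv_strict(path, readr::cols(
    sample_id = readr::col_character(),
    time_days = readr::col_double(),
    event = readr::col_integer()))
  if (any(duplicated(df$sample_id))) {
    abort(sprintf("'%s': duplicated sample id.", path))
  }
  if (any(!is.finite(df$time_days)) || any(df$time_days <= 0)) {
    abort(sprintf("'%s': survival times must be finite and > 0 (row %d).",
                  path, which(!is.finite(df$time_days) | df$time_days <= 0)[1]))
  }
  if (any(!df$event %in% c(0L, 1L))) {
    abort(sprintf("'%s': event must be 0 or 1 (row %d has %s).",
                  path, which(!df$event %in% c(0L, 1L))[1],
                  df$event[which(!df$event %in% c(0L, 1L))[1]]))
  }
  df
}

#' @rdname read_clinical
#' @param x Clinical tibble.
#' @export
write_clinical <- function(x, path) {
  readr::write_tsv(x[, c("sample_id", "time_days", "event")], path)
  invisible(path)
}
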