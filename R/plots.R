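# ggplot2 autoplot methods for the package's result objects.

#' Hockey-stick plot of super-enhancer calls
#'
#' Regions ordered by ascending signal with the cutpoint marked; the classic
#' visual for rank-based super-enhancer calling.
#'
#' @param object An `se_calls` tibble from [call_superenhancers()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.se_calls <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[order(df$signal), ]
  df$idx <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = .data$signal,
                                   colour = .data$is_SE)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = nrow(df) - attr(object, "cutpoint_index") + 0.5,
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "enhancer regions ranked by signal",
                  y = "background-corrected signal",
                  colour = "super-enhancer") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier step curve
#'
#' @param object A `km_curve` from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- bind_rows(tibble(time = 0, surv = 1),
                  as_tibble(object)[, c("time", "surv")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves of the two cutpoint strata
#'
#' @param object A `surv_cutpoint_fit` from [optimal_cutpoint()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.surv_cutpoint_fit <- function(object, ...) {
  df <- tidy.surv_cutpoint_fit(object)
  df0 <- bind_rows(tibble(time = 0, surv = 1, stratum = "high"),
                   tibble(time = 0, surv = 1, stratum = "low"),
                   df[, c("time", "surv", "stratum")])
  ggplot2::ggplot(df0, ggplot2::aes(x = .data$time, y = .data$surv,
                                    colour = .data$stratum)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "survival probability",
                  subtitle = sprintf("threshold %.3g; naive log-rank p = %.3g (selection uncorrected)",
                                     object$threshold, object$p_naive)) +
    ggplot2::theme_minimal()
}

#' Signature expression heat map data
#'
#' Tidy helper for plotting the signature across a cohort: z-scored
#' log2(TPM+1) in long form, ready for `geom_tile()`.
#'
#' @param expr_tpm An [expr_mat] tagged `"tpm"`.
#' @param signature A `consensus_signature` or character vector of gene ids.
#' @return A ggplot of the signature-by-sample z-score matrix.
#' @export
plot_signature_heatmap <- function(expr_tpm, signature) {
  genes <- if (is.character(signature)) signature else signature$gene_id
  genes <- intersect(genes, rownames(expr_tpm$values))
  lg <- log2(expr_tpm$values[genes, , drop = FALSE] + 1)
  zm <- t(scale(t(lg)))
  df <- tibble(
    gene_id = rep(rownames(zm), ncol(zm)),
    sample_id = rep(colnames(zm), each = nrow(zm)),
    z = as.vector(zm),
    condition = rep(unname(sample_labels(expr_tpm)), each = nrow(zm))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$gene_id,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", high = "firebrick",
                                  mid = "white") +
    ggplot2::facet_grid(. ~ condition, scales = "free_x", space = "free_x") +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "z")
}
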