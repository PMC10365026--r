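# Shared fixture builders: a scaled-down simulation config for module tests
# (the full default config is exercised in the acceptance suite) and a tiny
# expression matrix.

small_config <- function(seed = 1, ...) {
  args <- list(n_genes = 300, n_tumor = 15, n_normal = 15,
               n_activated_targets = 20, n_repressed_targets = 10,
               n_celllines = 2, n_chroms = 2, chrom_length = 1.2e7,
               n_planted_SEs = 3, n_planted_typical_enhancers = 40,
               n_distal_sites = 30, seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

tiny_expr <- function(n_genes = 6, n_samples = 4, unit = "tpm", seed = 42) {
  set.seed(seed)
  m <- matrix(round(runif(n_genes * n_samples, 0, 100), 3), nrow = n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  labs <- setNames(rep(c("tumor", "normal"), length.out = n_samples),
                   colnames(m))
  expr_mat(m, labs, unit = unit)
}
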