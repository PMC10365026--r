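# tfsig

Deriving a transcription-factor-driven oncogenic gene signature from three
lines of evidence — cohort expression, knockdown experiments, and the
factor's regulatory landscape — is a common integrative design in cancer
genomics: correlate every gene with a driver ("anchor") transcription factor
across tumors and matched normals, keep genes whose tumor-vs-normal fold
change agrees in sign with that correlation, require the concordant
knockdown response in every cell-line model, and then annotate the surviving
signature with binding and super-enhancer evidence before testing its
clinical value. `tfsig` implements that whole pipeline as composable,
tested R functions, together with a synthetic-data generator that plants
ground truth at every stage so the pipeline's recovery behaviour is
measurable without any external download.

The package is aimed at computational biologists who want either the
individual primitives (a defined differential-expression engine,
replicate-consensus peaks, GREAT-style basal-plus-extension regulatory
domains, ROSE-style super-enhancer calling, k-means chromatin states,
maximally selected survival cutpoints) or the orchestrated end-to-end run.

## The statistics at the core

* **Anchor correlation.** For each gene *g*, Pearson's *r* between
  log2(TPM+1) of *g* and of the anchor over all samples pooled (normals set
  the baseline), with the two-sided t-distribution p-value
  *t = r sqrt((n-2)/(1-r²))*.
* **Differential expression.** Median-of-ratios size factors
  *s_j = median_g (c_gj / (∏_k c_gk)^{1/n})*, Welch's t per gene on
  log2(normalized count + 1), Benjamini–Hochberg step-up control, signed
  call at padj ≤ 0.1.
* **Sign-concordant integration.** Keep gene *g* with direction `+` iff
  *r_g > 0* and log2FC_g > 0 at padj ≤ FDR (mirrored for `-`), then require
  the opposite-signed significant response upon anchor knockdown in every
  cell line (activator convention).
* **Super-enhancers.** Stitch H3K27ac peaks whose gaps are < 12.5 kb, rank
  stitched regions by background-corrected signal, scale ranks and signals
  to [0,1], and cut where the curve's slope reaches 1 (the hockey-stick
  tangent, discretised as the maximal gap to the diagonal).
* **Regulatory domains.** Strand-aware basal domain (5 kb up / 1 kb down of
  the TSS) extended up to 1 Mb but never into a neighboring basal domain;
  peaks assign to every domain containing their midpoint.
* **Chromatin states.** k-means (k = 3) on per-mark mean signal in ±2.5 kb
  windows around binding sites; the cluster highest in H3K4me3 is the
  promoter state, then H3K27ac separates active from poised enhancers.
* **Survival cutpoint.** The expression threshold maximising the
  standardized log-rank statistic |O−E|/√V over all splits leaving ≥ 10% of
  subjects on each side, reported with an explicit selection caveat on the
  naive p-value.

## Worked example

```r
library(tfsig)

cfg <- sim_config(seed = 1)              # the package's default study conditions
co  <- simulate_cohort(cfg)              # 2,000 genes; 40 tumor + 40 normal

corr <- correlate_to_anchor(co$tpm, cfg$anchor_gene_id)
de   <- differential_expression(co$counts, "normal", "tumor", fdr = 0.1)
cand <- concordant_overlap(corr, de, fdr = 0.1)
kd   <- lapply(simulate_knockdown(cfg, co$truth), differential_expression,
               group_a = "shControl", group_b = "shKD", fdr = 0.1)
sig  <- knockdown_filter(cand, kd)
nrow(sig)
#> [1] 149

strat <- stratify_cohort(co$tpm, sig)
strat
#> <stratification_report> k = 2, 149 genes, ARI = 1.000, 0 misassigned
```

The 149-gene signature recovers the planted 150 directed targets with
precision 1.00 and recall 0.99 (one planted gene narrowly misses the
knockdown FDR), and the signature separates tumor from normal samples
perfectly (adjusted Rand index 1 against the condition labels).

The regulatory stages run the same way:

```r
chip <- simulate_chip_landscape(cfg, co$truth)
se <- call_superenhancers(chip$h3k27ac_peaks, chip$histone_tracks$H3K27ac,
                          gene_models = chip$gene_models)
sum(se$is_SE)
#> [1] 8        # exactly the eight planted super-enhancers
autoplot(se)   # hockey-stick plot
```

Or run everything from one config with a manifest of output digests:

```r
manifest <- run_pipeline(default_config(seed = 1), outdir = "run1")
manifest$counts$signature
#> [1] 149
```

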