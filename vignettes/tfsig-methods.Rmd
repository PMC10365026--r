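---
title: "Methods: integrative TF target signatures with planted-truth validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative TF target signatures with planted-truth validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tfsig)
```

## What the package models

`tfsig` implements the integrative design used to nominate downstream
targets of an oncogenic transcription factor from patient cohorts and cell
line models. Three orthogonal filters are intersected:

1. **Cohort correlation** — genes whose expression tracks the anchor factor
   across tumors and matched normal tissue;
2. **Tumor differential expression** — genes deregulated in tumors, in the
   direction their correlation sign predicts;
3. **Knockdown concordance** — genes that respond in the opposite direction
   when the factor is depleted, in every cell-line model.

The surviving directed gene set (the *consensus signature*) is then
annotated with regulatory evidence — factor binding via consensus ChIP-seq
peaks assigned through basal-plus-extension regulatory domains,
super-enhancer association, and the chromatin state of bound sites — and
evaluated clinically via cohort stratification and an optimal survival
cutpoint. Every stage operates on plain tabular data (tibbles in and out)
and the whole flow is reproducible from one seed.

## Statistical engines and the choices behind them

### Correlation

Pearson on log2(TPM+1) over all samples pooled, normals and tumors
together: pooling lets the normal tissue set the baseline, so a gene that is
high only in anchor-high tumors still correlates. The p-value is the exact
two-sided t-distribution transform of *r*. Spearman and the untransformed
scale are switches (`method`, `transform`), because the choice between them
is a matter of taste in heavy-tailed TPM data; the default (Pearson,
log2p1) stabilises the tails while keeping effect sizes interpretable.
Constant genes are flagged (`constant = TRUE`, `r = NA`), never silently
dropped.

### Differential expression

A deliberately *defined* engine rather than a black box: median-of-ratios
size factors (the reference is every gene with nonzero counts in all
samples), Welch's t on log2(normalized count + 1), Benjamini–Hochberg
step-up, and a signed call at `padj <= fdr` (default 0.1). This engine has
no information sharing across genes, which makes it exactly
oracle-testable: every piece is checked against independent brute-force
reimplementations in the test suite. The cost is power at very small n: with
3 replicates per arm, the Welch–Satterthwaite degrees of freedom can fall to
2, so only well-expressed genes are reliably detectable — a constraint the
synthetic generator respects (below). Moderated engines would buy power at
small n in exchange for a contract that cannot be verified by direct
enumeration.

### Sign-concordant integration and the knockdown convention

A candidate enters with direction `+` iff `r > 0`, `log2FC > 0` and
`padj <= fdr`; only the *sign* of the correlation is used (an optional
p-value cap exists but is off by default — with 80 pooled samples even weak
correlations are individually "significant", so the sign is the meaningful
datum). The knockdown filter then treats the anchor as an activator:
`+`-candidates must fall significantly when the anchor is depleted, in
*every* cell line (`require_all = TRUE`); the inverse convention and
any-cell-line mode are flags. Raising the FDR can only grow the concordant
set (monotonicity is property-tested).

### Regulatory domains and peak assignment

Basal domain: 5 kb upstream / 1 kb downstream of the TSS, strand-aware (for
minus-strand genes upstream is the numerically increasing side). Each side
extends to the nearer of 1 Mb from the TSS or the nearest *other* gene's
basal boundary, and never into a foreign basal domain; chromosome ends
clip. A peak is assigned to every gene whose extended domain contains the
peak midpoint — so an intergenic peak typically maps to both flanking genes.
A `nearest_only` rule (single closest TSS) is provided, since both
conventions are common in practice; the default is the basal-plus-extension
rule. All four numbers are arguments.

Consensus peaks across replicates are maximal segments supported by at
least `min_replicates` distinct replicates (one bp of overlap counts); for
two replicates this is the pairwise intersection. This deterministic
overlap-support rule deliberately replaces reproducibility-model approaches
(IDR): its output is a reproducible peak list, which is all the downstream
stages consume, and it is exactly checkable against a per-base scan.

### Super-enhancers

H3K27ac peaks are stitched when gaps are strictly under 12.5 kb, scored by
the integral of signal over the stitched region (minus an optional input
control, floored at zero), and ranked. With ranks and signals scaled to
[0, 1], the cutpoint sits where the ascending convex curve's slope reaches
1; discretely, the index maximising the gap between the diagonal and the
curve. Ties break toward the higher-signal index, so a perfectly linear
(or constant) profile yields zero super-enhancers rather than an arbitrary
split. TSS exclusion before stitching is off by default and available as a
radius argument. Classification is invariant to affine rescaling of all
signals, which the scaled-curve construction guarantees.

### Chromatin states

Per site: mean signal of H3K27ac, H3K4me1 and H3K4me3 in 100-bp bins over a
±2.5 kb window centered on the site midpoint (window and bin are
arguments; the window covers the typical lateral spread of enhancer marks
around a focal binding site). The default clustering feature is the
three per-mark window means — low-dimensional, interpretable and robust —
with the full concatenated profile behind a flag; per-site total-signal
normalization is also a flag, off by default. k-means runs with 50 restarts
under a fixed seed and k fixed at 3. Labels are relative: highest H3K4me3
cluster is the promoter state; of the rest, the higher H3K27ac cluster is
the active enhancer and the other the poised enhancer. Being relative, the
labels survive cluster-index permutation and rescaling of any one mark;
degenerate inputs (all-zero H3K4me3) still label, with a warning.

### Survival

Kaplan–Meier product-limit and the standard two-group log-rank
(hypergeometric variance per distinct event time, chi-square with 1 df) are
implemented directly and cross-checked against the `survival` package in
the tests. The optimal cutpoint scans every observed expression value whose
split leaves at least `minprop` (default 0.1) of subjects on each side and
maximises the standardized statistic |O−E|/√V; ties take the lower
threshold. Because the scan selects the best of many correlated tests, the
log-rank p-value at the chosen cutpoint is anti-conservative; it is
reported as `p_naive` with `selection_caveat = TRUE` rather than silently
corrected, and the number of candidates is recorded so users can apply
their preferred selection adjustment.

## The synthetic-data generator: what it emulates

The generator produces the full input set of the pipeline with recorded
ground truth: a tumor/normal count + TPM cohort, per-cell-line knockdown
count matrices, TF peak replicates, histone bedGraph tracks, gene models,
and a clinical table.

**Cohort.** Counts are negative binomial (dispersion 0.05,
patient-to-patient scale). A per-sample latent anchor activity *z* scales
the anchor gene (loading 1) and the planted targets; `anchor_coupling` is
specified as the target–anchor *correlation magnitude*, and the latent
loading is derived as `r/sqrt(1-r²) · σ_ε`, with σ_ε the log2-scale
counting-noise sd, so the realised Pearson correlation matches the
parameter. Tumor samples add the planted log2 fold changes
(|LFC| ~ N(1.5, 0.3²) by default; activated up, repressed down). TPM is
computed from the counts with simulated gene lengths, so correlation runs
on the same unit as in real cohorts.

**Expression range of planted targets.** Planted targets draw their
baseline log2 mean from U(8, 10) — the robustly expressed range — and
knockdown replicates use dispersion 0.005 (isogenic cell lines are far less
dispersed than patient cohorts). Both choices encode what signature
membership *means* in this design: a consensus target must be detectable in
the cohort and significant in every 3-vs-3 knockdown comparison, and an
unshrunk per-gene test simply has no power on near-silent genes at n = 3 —
a regime the emulated design excludes by construction. Background genes
span the full U(3, 9) expression range.

**Regulatory landscape.** Two 60-Mb chromosomes are divided into 50-kb
slots; every planted object — gene, super-enhancer, typical enhancer,
distal TF site — occupies its own slot. This guarantees by construction
that distinct entities can never fall within the 12.5-kb stitching reach of
each other and that no histone window contaminates a scored enhancer
region. Super-enhancers are clusters of 4–10 peaks (gaps 0.8–2 kb) with
H3K27ac heights 20–40; typical enhancers are single peaks whose summed
signal is drawn left-skewed around a modest plateau (1 + 2·Beta(5,1), in
kb-scaled units), an order of magnitude below any super-enhancer. The
left-skewed null matters: it makes a landscape *without* planted
super-enhancers produce a concave rank curve on which the tangent rule
correctly calls ~0 regions. TF sites come in three flavours —
promoter-proximal (at the TSS of planted bound genes), super-enhancer
resident, and distal slot sites whose states follow
`histone_state_fractions`; promoter-proximal and SE-resident sites get
their states (promoter, active enhancer) by construction. Each state
elevates its characteristic marks in a ±1-kb window with additive uniform
noise, binned at 200 bp.

**Survival.** Event times are exponential with log hazard either linear in
the standardized expression of a chosen gene or stepped at a planted
threshold (for cutpoint-recovery experiments), with administrative
censoring at 10 years.

**What the generator does not emulate.** Real library-composition biases
beyond global size factors, batch effects, correlated gene–gene noise,
read-level artifacts, peak-calling uncertainty, and tied or interval-censored
survival times. Passing recovery tests on these simulations therefore
demonstrates that the *integration logic* is correct and calibrated — not
that any particular biological dataset will yield a signature of a given
size.

## Determinism

Every stochastic stage derives its own 32-bit seed from the global seed and
a stage name (`derive_seed`), so stages can be rerun independently and the
full pipeline is bitwise reproducible: `run_pipeline()` writes an md5
digest per output file into its manifest, and two runs under an identical
config produce identical digests.

## Problem sizes used in validation

The bundled default conditions (2,000 genes, 40+40 cohort, two 3-vs-3 cell
lines, 8 super-enhancers among 200 typical enhancers on a 120-Mb toy
genome, ~330 TF sites, 300 survival subjects) keep a full end-to-end run
within seconds on a single core while leaving every recovery margin
meaningful; the module tests use a further scaled-down config (300 genes,
15+15) for speed. Randomized oracle-equivalence checks run at 1,000
instances per operation.

## Known limitations

* The DE engine is intentionally unmoderated; do not expect DESeq2/edgeR
  parity on real small-n data.
* The cutpoint's naive p-value must not be read as a hypothesis test; use
  the selection caveat.
* Regulatory-domain construction assumes one TSS per gene id; ties on TSS
  position are broken by gene id and logged.
* ORA is plain hypergeometric over-representation on user-supplied sets; no
  ranked or weighted enrichment.
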