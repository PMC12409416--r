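---
title: "Methods: the heterogeneity index, its quantification pipeline, and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the heterogeneity index, its quantification pipeline, and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(schet)
```

# The problem

Bulk measurements of hypoxia-inducible factor (HIF) target genes hide a
strongly bimodal single-cell reality: under hypoxia, a typical HIF-2
target transcript is absent from the vast majority of cells while a small
minority carries nearly all of it. `schet` provides the statistic used to
quantify that inequality, the image-quantification conventions needed to
compute it reproducibly from per-cell intensity tables, single-cell
co-expression analysis, a scaled-down scRNA-seq stage, and — because the
original imaging and sequencing data are external deposits — a generative
model rich enough to exercise and test every stage.

# The heterogeneity index

Given per-cell signals $v_1,\dots,v_n \ge 0$ with positive total, cells
are sorted by **descending** signal and the cumulative signal fraction is
plotted against the cumulative cell fraction, origin $(0,0)$ prepended.
With $A$ the trapezoid-rule area under this curve,

$$ h_i = 2A - 1 .$$

Two anchors pin the affine map: equal contribution by all cells gives
$A = 1/2$, $h_i = 0$; a single contributing cell gives $h_i = 1 - 1/n \to 1$.
On the descending-sorted curve this is algebraically identical to the
Gini coefficient in mean-absolute-difference form,
$h_i = \sum_{i,j}|v_i - v_j| / (2n^2\bar v)$ — the test suite holds the
two routes together to $10^{-12}$ on a thousand random vectors, and the
closed form $h_i = 1 - k/n$ for $k$ equal contributors among $n$ is exact.

Conventions worth stating:

* **Ties** are broken by a stable sort; they cannot change the curve, the
  area, or the smallest-$k$ statistic.
* **`pct_contributing`** (the "% of cells contributing 50%" number) uses
  the discrete smallest-$k$ rule with no interpolation; at the
  10,000–20,000 cells of a typical imaging experiment the granularity
  ($\le 0.01$ percentage points) is below reporting precision.
* **Zero total is an error**, not $h_i = 0$: contribution shares are
  undefined without signal.
* $h_i$ is scale invariant, so it does not matter whether it is computed
  before or after housekeeping normalization; `pct_zero` does depend on
  the thresholding convention, which is why that convention is fixed
  below.

# Quantification conventions

* **Detection thresholds** are empirical quantiles of a negative-control
  sample's per-cell intensities, default quantile 0.99 — robust to a
  single bright speck; quantile 1 (the maximum) is available and is what
  the parameter-recovery acceptance test uses, because at
  $p_\text{on} = 0.01$ a 1% false-positive rate would swamp the signal.
  Quantiles use linear interpolation between order statistics (R type 7),
  which only matters for small control samples (fewer than 30 control
  cells additionally triggers a warning).
* **Positivity is strict**: a cell exactly at the detection limit is
  below it. For counts, one read suffices (`count >= 1`).
* **Background subtraction** is a per-channel scalar clipped at zero; the
  package ingests segmented per-cell totals, so pixel-level masking is
  upstream of it.
* **Housekeeping normalization** divides a gene channel by the mean over
  all cells of a housekeeping channel carried by the *same fluorophore*,
  so dye gain cancels; a fluorophore mismatch is an error unless forced.
* **Thresholding happens on (background-subtracted) intensities,
  normalization afterwards.** Whether the original analysis thresholded
  before or after normalization is not documented; this package fixes the
  former and the invariance test shows positivity calls are unchanged
  when values and threshold are normalized alike.

# The synthetic world

Each gene in a cell follows a collapsed telegraph model: on with
probability $p_\text{on}$ (resolved per condition and genotype), and when
on its signal is log-normal, scaled by a shared per-cell size factor
$s_c = e^{N(0,\sigma_s)}$ and a channel brightness. Channels additionally
receive additive log-normal background; a pure-background
negative-control "gene" anchors detection thresholds. Counts are rendered
from the same latent truth by Poisson thinning:
$\text{counts} \sim \text{Pois}(\varepsilon \cdot s_c \cdot \text{burst})$
with capture efficiency $\varepsilon$. There is no zero inflation beyond
the on/off state — dropout emerges from thinning alone.

Defaults are the stated world, chosen once from the printed regimes of
the motivating experiments and not revisited:

| parameter | default | why |
|---|---|---|
| housekeeping $p_\text{on}$ | 0.98 | near-ubiquitous expression, ~2% below detection |
| housekeeping burst sd / $\sigma_s$ | 0.4 / 0.45 | total log-sd ≈ 0.6 gives $h_i \approx 0.34$ and inter-probe Spearman $\rho \approx 0.5$, the published housekeeping reference values |
| HIF-1 target $p_\text{on}$ (hypoxia) | 0.30–0.36 | ~64% of hypoxic cells negative for a CAIX-like target |
| HIF-2 target $p_\text{on}$ (hypoxia) | 0.05–0.06 | ~95% negative, ≲1% of cells carrying half the signal |
| regulator mRNA $p_\text{on}$ | 0.58 / 0.45 | ~42% of cells negative for the HIF-1α-like mRNA |
| `mutual_inhibition` | 2 | losing one HIF isoform roughly doubles the other's target on-probability (capped at 1) — a single factor on $p_\text{on}$, the simplest mechanism consistent with the observed boost |
| background | LogNormal(log 5, 0.5) | ~1/100 of a typical on-state intensity |
| `capture_efficiency` | 0.05 | the regime in which sequencing calls >90% of cells negative for genes FISH finds in 30%+ |
| `protein_decoupling` | 0.5 | intermediate coupling for the paired mRNA/protein channel |
| FISH `n_cells` | 10,000 | one imaging experiment's scale |
| scRNA-seq `n_cells` | 200/sample | desk-scale stand-in for ~1,100-cell libraries |

Two modeling decisions deserve their own paragraph:

* **The protein channel draws its own per-cell scale factor.** Nuclear
  protein content is not tied to the transcriptional size factor, and if
  it were shared, full decoupling (`protein_decoupling = 1`) could never
  yield the observed *absence* of mRNA–protein correlation — the latent
  size factor alone would correlate the channels. With an independent
  scale, decoupling = 1 gives exactly independent channels, and the
  positive-overlap fraction under partial decoupling follows the
  closed-form mixture $(1-d)p + dp^2$ that the tests check.
* **The default scRNA-seq gene set separates structure from the panel.**
  Six samples (two oxygen conditions × three genotypes) are separable
  through dense global programs — a hypoxia-induced program, per-clone
  marker genes, and 15 abundant strongly induced genes that give the
  pseudobulk DE stage a nonempty pass set, as the real experiment's 55
  genes did — while the 70 HIF panel genes are sparse
  ($p_\text{on} \le 0.08$) and heavily thinned. That is precisely the
  regime in which unsupervised feature selection recovers the samples
  (ARI ≈ 1) and the supervised HIF panel does not (ARI ≈ 0.1), the
  package's quantitative restatement of the published supervised-vs-
  unsupervised embedding contrast.

Seeding: one root seed; every (condition, genotype, stage) draws from a
substream derived by Lehmer-mixing the root and hashing the key, so
adding a sample never perturbs another, and nearby root seeds land on
distant streams (all hash arithmetic stays below $2^{53}$ and is exact).

What the generator does **not** emulate: spatial structure and
segmentation error, cell-cycle phase, oscillatory HIF dynamics,
amplification noise beyond Poisson thinning, ambient RNA, or doublets
(the filter's doublet stage is a pass-through accepting external labels).
A green test therefore establishes correctness of the *statistics and
pipeline contracts* under a plausible bursting world — not biological
validity of any particular parameter value, which would require the
original deposited data.

# scRNA-seq stage conventions

* The QC cascade applies, in order: a hard floor on total counts
  (default 1000), MAD outlier removal at `nmads = 3` on log1p totals and
  log1p feature counts (two-sided) and mitochondrial fraction
  (upper-sided) computed **within each sample**, a riboprotein-fraction
  ceiling (0.7), and the doublet stub. Zero MAD flags nothing. Threshold
  stages are idempotent; MAD stages may re-trigger on their own output,
  which is inherent to quantile-type filters and documented rather than
  hidden.
* Clustering replaces UMAP + graph Louvain with PCA (default 19
  components, on log1p counts-per-10k, standardized per gene) + k-means
  with $k$ set to the number of true samples; the claim under test is
  separability under a feature set, which the adjusted Rand index against
  sample identity captures for any reasonable clusterer. ARI's degenerate
  case (both partitions trivial) is defined as 1 if identical else 0.
* Pseudobulk DE normalizes per-cell values to counts-per-**million** — a
  fixed scale, chosen because the thresholds it applies (log2FC > 2, base
  mean > 350; supervised mode 1.5/50; total-count > 50 prefilter with
  strict inequalities throughout) are quoted in a per-million idiom, and
  because a fixed scale makes the pass set exactly invariant to global
  depth rescaling. This is a deliberately transparent simplification: no
  dispersion model, no test statistic — genes are *thresholded*, not
  tested, and the module says so.

# Numerical edge cases

* Constant input to Spearman's $\rho$ is flagged `NA` (undefined), never
  silently 0; ties get average ranks; $n \le 10$ uses an exact
  permutation p-value by full enumeration, larger $n$ the t
  approximation.
* `embed_and_cluster` errors on all-constant features ("degenerate") and
  on `n_pcs` beyond the usable rank; k-means is seeded explicitly, so
  fixed input and seed give identical labels.
* The filter cascade errors (with the partial report attached) if any
  stage empties the matrix.
* MTX files are written as MatrixMarket *coordinate integer* with
  1-based indices; the reader rejects 0-based indices, non-integer
  counts, and count/declaration mismatches with line numbers.

# Limitations

The h_i confidence interval (bootstrap) is a documented extension, not
implemented. The clustering stage does not integrate across samples
(anchor-based integration is out of scope), so whether six-sample
recovery survives integration cannot be asserted here. Generator
parameters are calibrated qualitatively to printed regimes and must not
be read as fitted values.
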