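# schet — single-cell heterogeneity of the hypoxia response

`schet` quantifies how unevenly a transcript (or protein) is distributed
across single cells, for people analyzing per-cell image-quantification
tables (smFISH/RNAscope, immunofluorescence) or single-cell RNA-seq count
matrices. It was built around a striking biological observation: canonical
hypoxia-inducible factor (HIF) target genes such as *CAIX* and *PAI-1*,
usually treated as uniform markers of hypoxic cells, are in fact expressed
in a bursting, all-or-nothing fashion — under hypoxia most cells express
none of the transcript while a small minority carries almost all of it.

## The statistic

For per-cell signals \(v_1, \dots, v_n \ge 0\), sort cells by descending
signal and plot the cumulative fraction of total signal against the
cumulative fraction of cells (a Lorenz curve read from the top). With
\(A\) the area under that curve (trapezoid rule, origin included), the
heterogeneity index is

\[ h_i = 2A - 1 \in [0, 1), \]

which is exactly the Gini coefficient in its mean-absolute-difference
form, \(h_i = \sum_{i,j} |v_i - v_j| / (2 n^2 \bar v)\): 0 when every cell
contributes equally, \(1 - 1/n \to 1\) when a single cell carries all
signal. Alongside `h_i` the package reports the two companion numbers the
field prints next to it: the percentage of (top-ranked) cells contributing
50% of the total, and the percentage of cells at or below the detection
limit derived from a negative-control sample.

Supporting stages mirror a full analysis: detection thresholds from
negative controls (empirical quantile, default 0.99), per-channel scalar
background subtraction, normalization to a housekeeping probe carried by
the same fluorophore (dye gains cancel), Spearman correlation and 2×2
positivity-overlap tables between channels, and a scaled-down scRNA-seq
stage (QC filter cascade with MAD outlier removal, supervised-vs-
unsupervised feature selection, PCA + k-means scored by adjusted Rand
index against sample identity, and thresholded pseudobulk differential
expression). A telegraph-model generator with full ground truth makes all
of it testable offline.

## Worked example

Simulate one hypoxic sample of 10,000 cells under the default panel
(housekeeping *POLR2A*/*UBC*; HIF-1 targets *CAIX*/*BNIP3*; HIF-2 targets
*SERPINE1* (PAI-1)/*EGFR*; regulator mRNAs; a pure-background negative
control), derive the detection limit from the negative control, and
summarize heterogeneity per channel:

```r
library(schet)

cfg <- default_fish_config(n_cells = 10000, seed = 1)
sim <- simulate_fish(cfg, "hypoxia", "NTC")
tab <- sim$table

thr <- detection_threshold(tab, "NEG_CTRL@Opal570", 0.99)
#> detection_threshold: channel NEG_CTRL@Opal570, threshold 16.22 (q = 0.99)

for (ch in c("POLR2A@Opal570", "UBC@Opal650", "HIF1A@Opal570",
             "CAIX@Opal570", "SERPINE1@Opal650")) {
  s <- lorenz_summary(tab[[ch]], threshold = thr)
  cat(sprintf("%-18s h_i = %.3f  pct_half = %5.2f  pct_zero = %5.2f\n",
              ch, s$h_i, s$pct_half, s$pct_zero))
}
#> POLR2A@Opal570     h_i = 0.339  pct_half = 27.00  pct_zero =  1.84
#> UBC@Opal650        h_i = 0.337  pct_half = 27.20  pct_zero =  2.02
#> HIF1A@Opal570      h_i = 0.671  pct_half = 12.03  pct_zero = 42.00
#> CAIX@Opal570       h_i = 0.808  pct_half =  6.57  pct_zero = 63.23
#> SERPINE1@Opal650   h_i = 0.962  pct_half =  0.79  pct_zero = 93.93

spearman_rho(tab[["POLR2A@Opal570"]], tab[["UBC@Opal650"]])
#> Spearman rho = 0.4960 (n = 10000, p = 2.23e-308, t approximation)
```

Read: the housekeeping channels behave like a well-mixed population
(h_i ≈ 0.34, ~27% of cells account for half the signal, ~2% below the
detection limit, and the two probes correlate at ρ ≈ 0.5 through the
shared per-cell size factor). The HIF-2 target channel is the opposite
extreme — 94% of cells are negative and under 1% of cells carry half of
all signal (h_i ≈ 0.96). These are the expression regimes the generator
is parameterized to emulate.

The end-to-end pipeline (simulation → thresholds → heterogeneity →
correlation → scRNA-seq QC/clustering/DE, with a manifest of every
output) runs with:

```r
run_pipeline(default_run_config(seed = 1), "out/")
```

or from the command line via the shipped script:

```sh
Rscript inst/exec/schet reproduce --seed 1 --out-dir out/
```

## Documentation

The methods vignette (`vignettes/heterogeneity-methods.Rmd`) describes
the model, every tunable parameter with its default and rationale, what
the synthetic world does and does not emulate, and numerical conventions
(quantile type, strict thresholds, tie handling, degenerate inputs).
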