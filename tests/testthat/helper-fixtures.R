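# Fixture builders shared across test files. Everything is generated in
# code; no binary data ships with the package.

# Minimal intensity table: channels passed as a named list of vectors.
toy_intensity_table <- function(channels, sample = "s1", condition = "hypoxia",
                                genotype = "NTC") {
  n <- length(channels[[1L]])
  cell_intensity_table(sprintf("c%03d", seq_len(n)), sample, condition, genotype,
                       as.data.frame(channels, check.names = FALSE))
}

# Pairwise mean-absolute-difference Gini: the independent oracle for the
# trapezoid heterogeneity index.
gini_pairwise <- function(v) {
  n <- length(v)
  sum(abs(outer(v, v, "-"))) / (2 * n^2 * mean(v))
}

# 10-cell QC fixture with exactly one violation class per filter stage:
#   c01 fails the hard total-count floor (total 500);
#   c02 is a MAD outlier on log1p total counts (total 200000);
#   c03 is a MAD outlier on mitochondrial fraction (0.5);
#   c04 exceeds the riboprotein ceiling (0.882);
#   c05 is an externally labeled doublet;
#   c06..c10 survive everything.
qc_fixture <- function() {
  cells <- c("c01", "c02", "c03", "c04", "c05", "c06", "c07", "c08", "c09", "c10")
  #              GA      GB   MT-1  RPS1
  counts <- rbind(
    GA   = c(300, 150000,  500,  140, 1000, 1000, 1000, 1020,  970, 1030),
    GB   = c(100,  40000,  400,   50,  810,  790,  800,  800,  800,  800),
    `MT-1` = c(50,   5000, 1000,   50,  100,  100,  100,  100,  100,  100),
    RPS1 = c(50,    5000,  100, 1800,  100,  100,  100,  100,  100,  100)
  )
  colnames(counts) <- cells
  count_matrix(counts,
               gene_info = data.frame(gene = rownames(counts)),
               cell_info = data.frame(cell_id = cells, sample = "s1",
                                      condition = "hypoxia", genotype = "NTC"))
}

# DEG fixture: 2 cells per group, every cell's library totals exactly 1e6
# via a filler gene, so per-million normalization is the identity and all
# expected values are exact by hand:
#   D1 passes (log2FC 3.894, base mean 800);
#   D2 fails the fold-change threshold (log2FC 1.580);
#   D3 fails the base-mean threshold (55) but passes the supervised one;
#   D4 fails the total-count prefilter (total 30);
#   D5 passes just above both thresholds (log2FC 2.807, base mean 351);
#   D6 sits exactly at base mean 350 (strict ">", fails);
#   D7 sits exactly at log2FC 2 (strict ">", fails).
deg_fixture <- function() {
  counts <- rbind(
    D1 = c(100, 100, 1500, 1500),
    D2 = c(200, 200, 600, 600),
    D3 = c(10, 10, 100, 100),
    D4 = c(5, 5, 10, 10),
    D5 = c(87, 87, 615, 615),
    D6 = c(100, 100, 600, 600),
    D7 = c(199, 199, 799, 799)
  )
  filler <- 1e6 - colSums(counts)
  counts <- rbind(counts, FILLER = filler)
  cells <- c("a1", "a2", "b1", "b2")
  colnames(counts) <- cells
  cm <- count_matrix(counts,
                     gene_info = data.frame(gene = rownames(counts)),
                     cell_info = data.frame(cell_id = cells, sample = "s1",
                                            condition = rep(c("normoxia", "hypoxia"), each = 2),
                                            genotype = "NTC"))
  list(cm = cm, groups = factor(rep(c("A", "B"), each = 2), levels = c("A", "B")))
}

# Reorder/subset cells of a count_matrix (tests only use exported API).
subset_cells_for_test <- function(cm, idx) {
  count_matrix(cm$counts[, idx, drop = FALSE], cm$gene_info,
               cm$cell_info[idx, , drop = FALSE])
}

# Tiny generator config: a handful of genes, quick to simulate.
tiny_config <- function(n_cells = 500, seed = 42L, ...) {
  generator_config(
    n_cells = n_cells,
    genes = list(
      gene_spec("HK1", "housekeeping", 0.98, log(2000), 0.4, "Opal570"),
      gene_spec("HK2", "housekeeping", 0.98, log(2000), 0.4, "Opal650"),
      gene_spec("T1", "hif1_target", c(normoxia = 0.02, hypoxia = 0.3),
                log(1500), 0.8, "Opal570"),
      gene_spec("NEG", "negative_control", 0, 0, 0, "Opal570")
    ),
    seed = seed, ...
  )
}

tmp_file <- function() tempfile(fileext = ".tsv")
tmp_dir <- function() {
  d <- tempfile()
  dir.create(d)
  d
}
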