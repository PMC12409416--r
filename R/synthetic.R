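#' Gene specification for the synthetic generator
#'
#' Describes one gene of the simulated panel under the collapsed telegraph
#' (two-state) model: in each cell the gene is "on" with probability
#' `p_on` (which may depend on condition and genotype), and when on its
#' signal is log-normally distributed, scaled by a shared per-cell size
#' factor and a channel brightness.
#'
#' `p_on` is a named numeric vector resolved most-specific-first:
#' `"condition:genotype"`, then `"condition"`, then an unnamed (or
#' `"default"`-named) fallback.
#'
#' @param name gene symbol.
#' @param role one of `housekeeping`, `hif1_target`, `hif2_target`,
#'   `hif1a_mrna`, `hif2a_mrna`, `negative_control`.
#' @param p_on on-probability map (see above); every value in \[0, 1\].
#'   Negative controls must have `p_on = 0` for all keys.
#' @param burst_log_mean,burst_log_sd log-scale location and spread
#'   (`>= 0`) of the on-state signal.
#' @param fluorophore dye label, e.g. `"Opal570"`.
#' @param brightness multiplicative channel gain, `> 0`.
#' @return object of class `gene_spec`.
#' @export
gene_spec <- function(name, role, p_on, burst_log_mean, burst_log_sd,
                      fluorophore = "Opal570", brightness = 1) {
  role <- match.arg(role, c("housekeeping", "hif1_target", "hif2_target",
                            "hif1a_mrna", "hif2a_mrna", "negative_control"))
  if (!is.numeric(p_on) || any(p_on < 0 | p_on > 1) || anyNA(p_on)) {
    stop(sprintf("gene %s: p_on values must lie in [0, 1]", name), call. = FALSE)
  }
  if (role == "negative_control" && any(p_on != 0)) {
    stop(sprintf("gene %s: a negative control must have p_on = 0", name), call. = FALSE)
  }
  if (burst_log_sd < 0) stop("burst_log_sd must be >= 0", call. = FALSE)
  if (brightness <= 0) stop("brightness must be > 0", call. = FALSE)
  structure(list(name = name, role = role, p_on = p_on,
                 burst_log_mean = burst_log_mean, burst_log_sd = burst_log_sd,
                 fluorophore = fluorophore, brightness = brightness),
            class = "gene_spec")
}

#' Resolve a gene's on-probability for a (condition, genotype) pair
#'
#' Applies the lookup order `"condition:genotype"` > `"condition"` >
#' unnamed fallback, then the mutual-inhibition adjustment: losing one HIF
#' isoform raises the on-probability of the *other* isoform's targets by a
#' multiplicative factor (capped at 1) — HIF-2 targets under `HIF1A_KO`,
#' HIF-1 targets under `EPAS1_KO`.
#'
#' @param gene a `gene_spec`.
#' @param condition,genotype sample labels.
#' @param mutual_inhibition factor `>= 1`.
#' @return probability in \[0, 1\].
#' @export
resolve_p_on <- function(gene, condition, genotype, mutual_inhibition = 1) {
  p <- gene$p_on
  keys <- names(p)
  if (is.null(keys)) keys <- rep("", length(p))
  pick <- function(key) {
    i <- match(key, keys)
    if (is.na(i)) NA_real_ else unname(p[i])
  }
  val <- pick(paste(condition, genotype, sep = ":"))
  if (is.na(val)) val <- pick(condition)
  if (is.na(val)) val <- pick("default")
  if (is.na(val)) {
    unnamed <- p[keys == ""]
    if (length(unnamed)) val <- unname(unnamed[1L])
  }
  if (is.na(val)) {
    stop(sprintf("gene %s: no p_on entry for (%s, %s)", gene$name, condition, genotype),
         call. = FALSE)
  }
  boosted <- (gene$role == "hif2_target" && genotype == "HIF1A_KO") ||
             (gene$role == "hif1_target" && genotype == "EPAS1_KO")
  if (boosted) val <- min(1, val * mutual_inhibition)
  val
}

#' Generator configuration
#'
#' @param n_cells number of cells per simulated sample, `>= 1`.
#' @param genes list of [gene_spec()] objects.
#' @param conditions,genotypes admissible sample labels.
#' @param size_factor_log_sd log-sd of the shared per-cell size factor
#'   `s_c = exp(N(0, sd))`; this single latent variable is what makes
#'   housekeeping channels correlate across cells.
#' @param background_log_mean,background_log_sd log-normal additive
#'   background per channel; `background_log_mean = -Inf` means no
#'   background.
#' @param mutual_inhibition factor `>= 1`, see [resolve_p_on()].
#' @param protein_decoupling probability in \[0, 1\] that the protein
#'   channel of [simulate_paired_protein()] redraws its on-state
#'   independently of the mRNA.
#' @param capture_efficiency probability in (0, 1\] that thins latent
#'   transcript means into observed UMI counts (Poisson thinning).
#' @param seed root seed; per-(condition, genotype, stage) substreams are
#'   derived by hashing, so adding a sample never perturbs another.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_cells, genes,
                             conditions = c("normoxia", "hypoxia"),
                             genotypes = c("NTC", "HIF1A_KO", "EPAS1_KO"),
                             size_factor_log_sd = 0.45,
                             background_log_mean = log(5),
                             background_log_sd = 0.5,
                             mutual_inhibition = 2,
                             protein_decoupling = 0.5,
                             capture_efficiency = 0.05,
                             seed = 1L) {
  if (!is.numeric(n_cells) || n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  if (!length(genes) || !all(vapply(genes, inherits, logical(1), "gene_spec"))) {
    stop("`genes` must be a non-empty list of gene_spec objects", call. = FALSE)
  }
  if (size_factor_log_sd < 0 || background_log_sd < 0) {
    stop("log-sd parameters must be >= 0", call. = FALSE)
  }
  if (mutual_inhibition < 1) stop("mutual_inhibition must be >= 1", call. = FALSE)
  if (protein_decoupling < 0 || protein_decoupling > 1) {
    stop("protein_decoupling must be in [0, 1]", call. = FALSE)
  }
  if (capture_efficiency <= 0 || capture_efficiency > 1) {
    stop("capture_efficiency must be in (0, 1]", call. = FALSE)
  }
  names(genes) <- vapply(genes, `[[`, character(1), "name")
  structure(list(n_cells = as.integer(n_cells), genes = genes,
                 conditions = conditions, genotypes = genotypes,
                 size_factor_log_sd = size_factor_log_sd,
                 background_log_mean = background_log_mean,
                 background_log_sd = background_log_sd,
                 mutual_inhibition = mutual_inhibition,
                 protein_decoupling = protein_decoupling,
                 capture_efficiency = capture_efficiency,
                 seed = as.integer(seed)),
            class = "generator_config")
}

check_sample_key <- function(config, condition, genotype) {
  if (!condition %in% config$conditions) {
    stop(sprintf("unknown condition '%s'", condition), call. = FALSE)
  }
  if (!genotype %in% config$genotypes) {
    stop(sprintf("unknown genotype '%s'", genotype), call. = FALSE)
  }
}

#' Deterministic substream seed from a root seed and a key
#'
#' Hashes the key strings so that each (condition, genotype, stage) gets
#' its own reproducible stream below 2^31.
#' @param seed root integer seed.
#' @param ... key components (coerced to character).
#' @return integer seed.
#' @export
substream_seed <- function(seed, ...) {
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  # Lehmer-style mixing so that nearby root seeds land on distant streams;
  # all intermediates stay below 2^53, so the arithmetic is exact
  h <- as.numeric(seed) %% 2147483647
  h <- (h * 48271) %% 2147483647
  h <- (h * 48271) %% 2147483647
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Draw the latent ground truth for one sample
#'
#' Size factors and binary on/off states only — the part of the simulation
#' shared between the FISH and scRNA-seq renderings of the same cells.
#'
#' @param config a [generator_config()].
#' @param condition,genotype sample labels present in the config.
#' @return object of class `simulation_truth`: list with `s` (per-cell
#'   size factors), `on` (cells x genes logical matrix), `p_on` (resolved
#'   per-gene on-probabilities), `realized_fraction`, `condition`,
#'   `genotype` and the echoed gene specs.
#' @export
simulate_truth <- function(config, condition, genotype) {
  check_sample_key(config, condition, genotype)
  n <- config$n_cells
  gene_names <- names(config$genes)
  p_on <- vapply(config$genes, resolve_p_on, numeric(1),
                 condition = condition, genotype = genotype,
                 mutual_inhibition = config$mutual_inhibition)
  with_seed(substream_seed(config$seed, condition, genotype, "truth"), {
    s <- exp(stats::rnorm(n, 0, config$size_factor_log_sd))
    on <- matrix(stats::runif(n * length(p_on)) < rep(p_on, each = n),
                 nrow = n, dimnames = list(NULL, gene_names))
  })
  structure(list(s = s, on = on, p_on = p_on,
                 realized_fraction = colMeans(on),
                 condition = condition, genotype = genotype,
                 genes = config$genes),
            class = "simulation_truth")
}

draw_background <- function(config, n) {
  if (!is.finite(config$background_log_mean)) return(numeric(n))
  stats::rlnorm(n, config$background_log_mean, config$background_log_sd)
}

#' Simulate a FISH-like per-cell intensity table
#'
#' Renders one sample's latent truth as integrated fluorescence
#' intensities: `intensity = s_c * brightness_g * LogNormal(mu_g, sd_g)`
#' when the gene is on in that cell, 0 otherwise, plus an additive
#' log-normal background in every channel — including the pure-background
#' negative-control channel that downstream thresholding relies on.
#'
#' @inheritParams simulate_truth
#' @param truth optionally, a precomputed [simulate_truth()] object for
#'   this sample, so the same latent cells can be rendered by several
#'   modalities.
#' @return list with `table` (a [cell_intensity_table()]) and `truth`.
#' @export
simulate_fish <- function(config, condition, genotype, truth = NULL) {
  check_sample_key(config, condition, genotype)
  if (is.null(truth)) truth <- simulate_truth(config, condition, genotype)
  n <- nrow(truth$on)
  genes <- config$genes
  intens <- with_seed(substream_seed(config$seed, condition, genotype, "fish"), {
    cols <- lapply(genes, function(g) {
      burst <- exp(stats::rnorm(n, g$burst_log_mean, g$burst_log_sd))
      signal <- ifelse(truth$on[, g$name], truth$s * g$brightness * burst, 0)
      signal + draw_background(config, n)
    })
    as.data.frame(cols, check.names = FALSE)
  })
  names(intens) <- vapply(genes, function(g) paste0(g$name, "@", g$fluorophore),
                          character(1))
  sample_id <- paste(genotype, condition, sep = "_")
  tab <- cell_intensity_table(
    cell_id = sprintf("%s_c%05d", sample_id, seq_len(n)),
    sample = sample_id, condition = condition, genotype = genotype,
    intensities = intens,
    channels = data.frame(channel = names(intens),
                          gene = vapply(genes, `[[`, character(1), "name"),
                          fluorophore = vapply(genes, `[[`, character(1), "fluorophore"))
  )
  list(table = tab, truth = truth)
}

#' Simulate a scRNA-seq-like UMI count matrix
#'
#' Renders the same latent truth as integer counts: each cell's latent
#' transcript mean for a gene is `s_c * LogNormal(mu_g, sd_g)` when on
#' (0 when off), and observed counts are Poisson with that mean thinned by
#' the capture efficiency. Low capture efficiency is what makes sparse
#' genes look far more negative by sequencing than by FISH.
#'
#' @inheritParams simulate_fish
#' @return list with `counts` (a [count_matrix()], genes x cells) and
#'   `truth`.
#' @export
simulate_scrnaseq <- function(config, condition, genotype, truth = NULL) {
  check_sample_key(config, condition, genotype)
  if (config$capture_efficiency <= 0) stop("capture_efficiency must be > 0", call. = FALSE)
  if (is.null(truth)) truth <- simulate_truth(config, condition, genotype)
  n <- nrow(truth$on)
  genes <- config$genes
  counts <- with_seed(substream_seed(config$seed, condition, genotype, "scrnaseq"), {
    m <- vapply(genes, function(g) {
      lambda <- ifelse(truth$on[, g$name],
                       truth$s * exp(stats::rnorm(n, g$burst_log_mean, g$burst_log_sd)),
                       0)
      stats::rpois(n, config$capture_efficiency * lambda)
    }, integer(n))
    t(m)  # genes x cells
  })
  sample_id <- paste(genotype, condition, sep = "_")
  cm <- count_matrix(
    counts = counts,
    gene_info = data.frame(gene = names(genes),
                           role = vapply(genes, `[[`, character(1), "role")),
    cell_info = data.frame(cell_id = sprintf("%s_c%05d", sample_id, seq_len(n)),
                           sample = sample_id, condition = condition,
                           genotype = genotype)
  )
  list(counts = cm, truth = truth)
}

#' Simulate paired mRNA / nuclear-protein channels for one gene
#'
#' Emits a two-channel intensity table for a single gene: an mRNA channel
#' generated as in [simulate_fish()], and a protein channel whose on-state
#' copies the mRNA on-state with probability `1 - protein_decoupling` and
#' is otherwise redrawn independently at the same on-probability. The
#' protein channel draws its own per-cell scale (nuclear protein content is
#' not tied to the transcriptional size factor), so full decoupling yields
#' channels with no correlation at all.
#'
#' @inheritParams simulate_fish
#' @param gene name of the gene to render (must be in the config panel).
#' @return a [cell_intensity_table()] with channels `<gene>_mRNA` and
#'   `<gene>_protein`; the latent truth is attached as attribute `"truth"`.
#' @export
simulate_paired_protein <- function(config, condition, genotype, gene,
                                    truth = NULL) {
  check_sample_key(config, condition, genotype)
  if (!gene %in% names(config$genes)) {
    stop(sprintf("gene '%s' not in the configured panel", gene), call. = FALSE)
  }
  if (is.null(truth)) truth <- simulate_truth(config, condition, genotype)
  g <- config$genes[[gene]]
  n <- nrow(truth$on)
  p_on <- truth$p_on[[gene]]
  res <- with_seed(substream_seed(config$seed, condition, genotype, "protein", gene), {
    on_mrna <- truth$on[, gene]
    copy <- stats::runif(n) >= config$protein_decoupling
    on_prot <- ifelse(copy, on_mrna, stats::runif(n) < p_on)
    s_prot <- exp(stats::rnorm(n, 0, config$size_factor_log_sd))
    mrna <- ifelse(on_mrna,
                   truth$s * g$brightness * exp(stats::rnorm(n, g$burst_log_mean, g$burst_log_sd)),
                   0) + draw_background(config, n)
    prot <- ifelse(on_prot,
                   s_prot * g$brightness * exp(stats::rnorm(n, g$burst_log_mean, g$burst_log_sd)),
                   0) + draw_background(config, n)
    list(mrna = mrna, prot = prot, on_prot = on_prot)
  })
  intens <- stats::setNames(data.frame(res$mrna, res$prot),
                            paste0(gene, c("_mRNA@", "_protein@"), g$fluorophore))
  sample_id <- paste(genotype, condition, sep = "_")
  tab <- cell_intensity_table(
    cell_id = sprintf("%s_c%05d", sample_id, seq_len(n)),
    sample = sample_id, condition = condition, genotype = genotype,
    intensities = intens
  )
  attr(tab, "truth") <- c(truth, list(on_protein = res$on_prot, gene = gene))
  tab
}

#' Default FISH panel emulating the measured expression regimes
#'
#' Housekeeping probes are near-ubiquitous with moderate log-normal spread
#' (heterogeneity index around 0.3); HIF-1 targets are induced in a graded
#' on/off fashion under hypoxia (roughly a third of cells on); HIF-2
#' targets are extremely sparse (a few percent of cells on even under
#' hypoxia); regulator mRNAs sit in between and vanish in their own
#' knockout; a pure-background negative control anchors detection
#' thresholds. Two Opal dyes with different gains motivate the
#' housekeeping normalization.
#'
#' @return named list of [gene_spec()] objects.
#' @export
default_fish_panel <- function() {
  list(
    gene_spec("POLR2A", "housekeeping", 0.98,
              burst_log_mean = log(2000), burst_log_sd = 0.4,
              fluorophore = "Opal570", brightness = 1),
    gene_spec("UBC", "housekeeping", 0.98,
              burst_log_mean = log(2000), burst_log_sd = 0.4,
              fluorophore = "Opal650", brightness = 1.3),
    gene_spec("HIF1A", "hif1a_mrna",
              c(default = 0.58, "normoxia:HIF1A_KO" = 0, "hypoxia:HIF1A_KO" = 0),
              burst_log_mean = log(800), burst_log_sd = 0.7,
              fluorophore = "Opal570"),
    gene_spec("EPAS1", "hif2a_mrna",
              c(default = 0.45, "normoxia:EPAS1_KO" = 0, "hypoxia:EPAS1_KO" = 0),
              burst_log_mean = log(800), burst_log_sd = 0.7,
              fluorophore = "Opal650"),
    gene_spec("CAIX", "hif1_target",
              c(normoxia = 0.02, hypoxia = 0.36, "hypoxia:HIF1A_KO" = 0.02),
              burst_log_mean = log(1500), burst_log_sd = 0.8,
              fluorophore = "Opal570"),
    gene_spec("BNIP3", "hif1_target",
              c(normoxia = 0.02, hypoxia = 0.30, "hypoxia:HIF1A_KO" = 0.02),
              burst_log_mean = log(1200), burst_log_sd = 0.8,
              fluorophore = "Opal650"),
    gene_spec("SERPINE1", "hif2_target",
              c(normoxia = 0.005, hypoxia = 0.05, "hypoxia:EPAS1_KO" = 0.005),
              burst_log_mean = log(3000), burst_log_sd = 1.0,
              fluorophore = "Opal650"),
    gene_spec("EGFR", "hif2_target",
              c(normoxia = 0.01, hypoxia = 0.06, "hypoxia:EPAS1_KO" = 0.01),
              burst_log_mean = log(1000), burst_log_sd = 0.9,
              fluorophore = "Opal570"),
    gene_spec("NEG_CTRL", "negative_control", 0,
              burst_log_mean = 0, burst_log_sd = 0, fluorophore = "Opal570")
  )
}

#' Default FISH generator configuration
#' @param n_cells cells per sample (default 10000, the scale of one imaging
#'   experiment).
#' @param seed root seed.
#' @return a [generator_config()].
#' @export
default_fish_config <- function(n_cells = 10000, seed = 1L) {
  generator_config(n_cells = n_cells, genes = default_fish_panel(), seed = seed)
}

#' Default scRNA-seq gene set: dense global structure, sparse HIF panel
#'
#' Emulates a six-sample design (two oxygen conditions by three genotypes)
#' in which global expression programs separate the samples while the HIF
#' target panel is sparse and heavily thinned by capture efficiency:
#' ubiquitous housekeeping genes; a hypoxia-induced program; per-genotype
#' clone markers; mitochondrial and riboprotein genes for the QC metrics;
#' and 70 sparse HIF-1/HIF-2 target genes (`HIF1T_*`, `HIF2T_*`) forming
#' the supervised feature panel.
#'
#' @return named list of [gene_spec()] objects (~300 genes).
#' @export
default_sc_genes <- function() {
  genes <- list()
  add <- function(g) genes[[length(genes) + 1L]] <<- g
  for (i in seq_len(100)) {
    add(gene_spec(sprintf("HK%03d", i), "housekeeping", 0.95,
                  burst_log_mean = log(500), burst_log_sd = 0.4))
  }
  for (i in seq_len(40)) {
    add(gene_spec(sprintf("HYPX%02d", i), "housekeeping",
                  c(normoxia = 0.2, hypoxia = 0.9),
                  burst_log_mean = log(500), burst_log_sd = 0.4))
  }
  # abundant, strongly hypoxia-induced program (glycolytic-type genes):
  # the source of clear pseudobulk DE calls at the default thresholds
  for (i in seq_len(15)) {
    add(gene_spec(sprintf("HYPXHI%02d", i), "housekeeping",
                  c(normoxia = 0.02, hypoxia = 0.9),
                  burst_log_mean = log(2000), burst_log_sd = 0.5))
  }
  marker_p <- function(geno) {
    p <- c(default = 0.1)
    for (cond in c("normoxia", "hypoxia")) p[paste0(cond, ":", geno)] <- 0.9
    p
  }
  for (geno in c("NTC", "HIF1A_KO", "EPAS1_KO")) {
    for (i in seq_len(20)) {
      add(gene_spec(sprintf("CLONE_%s_%02d", geno, i), "housekeeping",
                    marker_p(geno), burst_log_mean = log(500), burst_log_sd = 0.4))
    }
  }
  for (i in seq_len(10)) {
    add(gene_spec(sprintf("MT-G%02d", i), "housekeeping", 1,
                  burst_log_mean = log(300), burst_log_sd = 0.3))
  }
  for (i in seq_len(20)) {
    add(gene_spec(sprintf("RPS%02d", i), "housekeeping", 1,
                  burst_log_mean = log(800), burst_log_sd = 0.3))
  }
  for (i in seq_len(35)) {
    add(gene_spec(sprintf("HIF1T_%02d", i), "hif1_target",
                  c(normoxia = 0.005, hypoxia = 0.08, "hypoxia:HIF1A_KO" = 0.005),
                  burst_log_mean = log(100), burst_log_sd = 0.8))
  }
  for (i in seq_len(35)) {
    add(gene_spec(sprintf("HIF2T_%02d", i), "hif2_target",
                  c(normoxia = 0.002, hypoxia = 0.03, "hypoxia:EPAS1_KO" = 0.002),
                  burst_log_mean = log(100), burst_log_sd = 0.8))
  }
  names(genes) <- vapply(genes, `[[`, character(1), "name")
  genes
}

#' Names of the supervised HIF target feature panel
#' @return character vector of the 70 sparse panel gene names.
#' @export
hif_panel_genes <- function() {
  c(sprintf("HIF1T_%02d", seq_len(35)), sprintf("HIF2T_%02d", seq_len(35)))
}

#' Default scRNA-seq generator configuration
#' @param n_cells cells per sample (default 200; about a fifth of a real
#'   library, for desk-scale runtimes).
#' @param seed root seed.
#' @param capture_efficiency UMI capture probability (default 0.05, the
#'   regime in which sequencing misses most transcripts FISH would see).
#' @return a [generator_config()].
#' @export
default_sc_config <- function(n_cells = 200, seed = 1L, capture_efficiency = 0.05) {
  generator_config(n_cells = n_cells, genes = default_sc_genes(),
                   capture_efficiency = capture_efficiency, seed = seed)
}

#' Simulate the full six-sample scRNA-seq experiment
#'
#' Runs [simulate_scrnaseq()] for every (condition, genotype) pair in the
#' config and column-binds the results into one count matrix.
#'
#' @param config a [generator_config()].
#' @return list with `counts` (combined [count_matrix()]) and `truths`
#'   (per-sample list of `simulation_truth`).
#' @export
simulate_sc_experiment <- function(config) {
  keys <- expand.grid(genotype = config$genotypes, condition = config$conditions,
                      stringsAsFactors = FALSE)
  sims <- Map(function(cond, geno) simulate_scrnaseq(config, cond, geno),
              keys$condition, keys$genotype)
  counts <- do.call(cbind_count_matrix, lapply(sims, `[[`, "counts"))
  list(counts = counts, truths = lapply(sims, `[[`, "truth"))
}
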