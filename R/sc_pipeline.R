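#' Gene x cell UMI count matrix with annotations
#'
#' A lightweight container for the scRNA-seq substrate: a sparse integer
#' matrix of counts (genes in rows, cells in columns), per-gene annotations
#' (symbol plus mitochondrial / riboprotein flags) and per-cell annotations
#' (sample, condition, genotype). Mito/ribo flags default to the standard
#' symbol conventions (`MT-` prefix; `RPS`/`RPL` prefix).
#'
#' @param counts matrix or Matrix of nonnegative integers, genes x cells.
#' @param gene_info data.frame with column `gene` (unique symbols) and
#'   optional logical `mito`, `ribo` flags.
#' @param cell_info data.frame with columns `cell_id` (unique), `sample`,
#'   `condition`, `genotype`.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_info, cell_info) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0) || any(counts@x != round(counts@x))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (nrow(counts) != nrow(gene_info)) stop("gene_info does not match matrix rows", call. = FALSE)
  if (ncol(counts) != nrow(cell_info)) stop("cell_info does not match matrix columns", call. = FALSE)
  if (anyDuplicated(gene_info$gene)) stop("duplicate gene identifiers", call. = FALSE)
  if (anyDuplicated(cell_info$cell_id)) stop("duplicate cell identifiers", call. = FALSE)
  if (is.null(gene_info$mito)) gene_info$mito <- grepl("^MT-", gene_info$gene)
  if (is.null(gene_info$ribo)) gene_info$ribo <- grepl("^RP[SL]", gene_info$gene)
  rownames(counts) <- gene_info$gene
  colnames(counts) <- cell_info$cell_id
  rownames(gene_info) <- NULL
  rownames(cell_info) <- NULL
  structure(list(counts = counts, gene_info = gene_info, cell_info = cell_info),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells, %d samples, %.1f%% nonzero\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$cell_info$sample)),
              100 * length(x$counts@x) / prod(dim(x$counts))))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Column-bind count matrices sharing a gene set
#' @param ... `count_matrix` objects with identical gene panels.
#' @return the combined `count_matrix`.
#' @export
cbind_count_matrix <- function(...) {
  cms <- list(...)
  genes <- cms[[1L]]$gene_info$gene
  for (cm in cms) {
    if (!identical(cm$gene_info$gene, genes)) stop("gene panels differ", call. = FALSE)
  }
  count_matrix(do.call(cbind, lapply(cms, `[[`, "counts")),
               cms[[1L]]$gene_info,
               do.call(rbind, lapply(cms, `[[`, "cell_info")))
}

subset_cells <- function(cm, keep) {
  count_matrix(cm$counts[, keep, drop = FALSE], cm$gene_info,
               cm$cell_info[keep, , drop = FALSE])
}

#' Per-cell QC metrics
#' @param cm a [count_matrix()].
#' @return data.frame with `cell_id`, `sample`, `total`, `features`,
#'   `mito_frac`, `ribo_frac`.
#' @export
qc_metrics <- function(cm) {
  totals <- Matrix::colSums(cm$counts)
  safe_frac <- function(sub) ifelse(totals > 0, Matrix::colSums(sub) / pmax(totals, 1), 0)
  data.frame(cell_id = cm$cell_info$cell_id, sample = cm$cell_info$sample,
             total = totals,
             features = Matrix::colSums(cm$counts > 0),
             mito_frac = safe_frac(cm$counts[cm$gene_info$mito, , drop = FALSE]),
             ribo_frac = safe_frac(cm$counts[cm$gene_info$ribo, , drop = FALSE]))
}

#' QC filter configuration
#' @param min_total_counts hard floor on per-cell total counts (default
#'   1000).
#' @param nmads MAD multiple for outlier removal (default 3).
#' @param max_ribo_fraction ceiling on the riboprotein read fraction
#'   (default 0.7).
#' @param doublet_stub keep the doublet stage in the cascade (pass-through
#'   unless external doublet labels are supplied).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(min_total_counts = 1000, nmads = 3,
                          max_ribo_fraction = 0.7, doublet_stub = TRUE) {
  if (min_total_counts < 0) stop("min_total_counts must be >= 0", call. = FALSE)
  if (nmads <= 0) stop("nmads must be > 0", call. = FALSE)
  if (max_ribo_fraction <= 0 || max_ribo_fraction > 1) {
    stop("max_ribo_fraction must be in (0, 1]", call. = FALSE)
  }
  structure(list(min_total_counts = min_total_counts, nmads = nmads,
                 max_ribo_fraction = max_ribo_fraction, doublet_stub = doublet_stub),
            class = "filter_config")
}

# MAD outlier flags on one metric within one sample; zero MAD flags nothing.
mad_outlier <- function(x, nmads, type = c("both", "upper")) {
  type <- match.arg(type)
  med <- stats::median(x)
  mad <- stats::mad(x, center = med)  # 1.4826 * median absolute deviation
  if (mad == 0) return(rep(FALSE, length(x)))
  dev <- x - med
  if (type == "upper") dev > nmads * mad else abs(dev) > nmads * mad
}

#' Quality-control filter cascade for cells
#'
#' Applies, in order: (1) a hard floor on total counts; (2) MAD-based
#' outlier removal (`nmads`, default 3) on log1p total counts and log1p
#' feature counts (two-sided) and on the mitochondrial fraction
#' (upper-sided), computed within each sample; (3) a riboprotein-fraction
#' ceiling; (4) a doublet stage that is a pass-through unless external
#' doublet labels (cell ids) are supplied. Zero-MAD metrics flag no
#' outliers. Every stage is recorded in an auditable report.
#'
#' @param cm a [count_matrix()].
#' @param config a [filter_config()].
#' @param doublet_ids optional character vector of cell ids called doublets
#'   by an external tool.
#' @return list with `counts` (filtered [count_matrix()]) and `report`
#'   (data.frame: stage, cells_in, cells_out, criterion).
#' @export
filter_cells <- function(cm, config = filter_config(), doublet_ids = NULL) {
  if (ncol(cm$counts) == 0L) stop("empty count matrix", call. = FALSE)
  report <- data.frame(stage = character(), cells_in = integer(),
                       cells_out = integer(), criterion = character())
  record <- function(stage, n_in, n_out, criterion) {
    report <<- rbind(report, data.frame(stage = stage, cells_in = n_in,
                                        cells_out = n_out, criterion = criterion))
  }
  fail_if_empty <- function(cm) {
    if (ncol(cm$counts) == 0L) {
      stop(errorCondition("all cells removed by QC filtering",
                          report = report, class = c("schet_filter_error", "error")))
    }
    cm
  }

  qc <- qc_metrics(cm)
  keep <- qc$total >= config$min_total_counts
  record("min_total_counts", ncol(cm$counts), sum(keep),
         sprintf("total counts >= %g", config$min_total_counts))
  cm <- fail_if_empty(subset_cells(cm, keep))

  qc <- qc_metrics(cm)
  out <- rep(FALSE, nrow(qc))
  for (sm in unique(qc$sample)) {
    i <- qc$sample == sm
    out[i] <- mad_outlier(log1p(qc$total[i]), config$nmads, "both") |
              mad_outlier(log1p(qc$features[i]), config$nmads, "both") |
              mad_outlier(qc$mito_frac[i], config$nmads, "upper")
  }
  record("mad_outliers", nrow(qc), sum(!out),
         sprintf("within-sample MAD <= %g on log1p(total), log1p(features) (two-sided), mito fraction (upper)",
                 config$nmads))
  cm <- fail_if_empty(subset_cells(cm, !out))

  qc <- qc_metrics(cm)
  keep <- qc$ribo_frac <= config$max_ribo_fraction
  record("ribo_fraction", nrow(qc), sum(keep),
         sprintf("ribo fraction <= %g", config$max_ribo_fraction))
  cm <- fail_if_empty(subset_cells(cm, keep))

  if (isTRUE(config$doublet_stub)) {
    keep <- !(cm$cell_info$cell_id %in% doublet_ids)
    record("doublet_stub", ncol(cm$counts), sum(keep),
           if (is.null(doublet_ids)) "pass-through (no external doublet labels)"
           else "externally labeled doublets removed")
    cm <- fail_if_empty(subset_cells(cm, keep))
  }
  list(counts = cm, report = report)
}

#' Feature selection: global top-N or a curated panel
#'
#' Unsupervised mode ranks genes by their summed library-size-normalized
#' expression (counts per 10k) across cells and returns the top `n`
#' (default 3000, capped at the gene count). Supervised mode intersects a
#' curated panel (e.g. 70 HIF target genes) with the matrix, warning about
#' and dropping missing symbols.
#'
#' @param cm a [count_matrix()].
#' @param mode `"unsupervised"` or `"supervised"`.
#' @param panel character vector of gene symbols (supervised mode).
#' @param n number of genes in unsupervised mode.
#' @return character vector of selected gene names.
#' @export
select_features <- function(cm, mode = c("unsupervised", "supervised"),
                            panel = NULL, n = 3000) {
  mode <- match.arg(mode)
  if (mode == "supervised") {
    if (is.null(panel)) stop("supervised mode needs a gene panel", call. = FALSE)
    missing <- setdiff(panel, cm$gene_info$gene)
    if (length(missing)) {
      warning(sprintf("%d panel genes absent from the matrix: %s", length(missing),
                      paste(utils::head(missing, 5), collapse = ", ")), call. = FALSE)
    }
    found <- intersect(panel, cm$gene_info$gene)
    if (!length(found)) stop("no panel gene present in the matrix", call. = FALSE)
    return(found)
  }
  cp10k <- normalize_cp10k(cm)
  totals <- Matrix::rowSums(cp10k)
  n <- min(n, nrow(cm$counts))
  cm$gene_info$gene[order(totals, decreasing = TRUE)[seq_len(n)]]
}

# log1p of counts per 10k (library-size normalization); dense matrix out.
normalize_cp10k <- function(cm, log = FALSE) {
  totals <- pmax(Matrix::colSums(cm$counts), 1)
  m <- as.matrix(cm$counts) %*% diag(1e4 / totals, ncol(cm$counts))
  colnames(m) <- colnames(cm$counts)
  if (log) log1p(m) else m
}

#' PCA embedding and k-means clustering on a feature set
#'
#' Cells are normalized to log1p counts-per-10k on the selected features,
#' genes are standardized over cells, PCA retains `n_pcs` components
#' (default 19) and k-means clusters the embedding with `k` centers
#' (default: the number of distinct true samples, so that recovery can be
#' scored). Deterministic under a fixed seed.
#'
#' @param cm a filtered [count_matrix()].
#' @param features character vector of gene names to use.
#' @param n_pcs number of principal components (default 19).
#' @param k number of clusters; defaults to the number of samples in the
#'   cell annotations.
#' @param seed seed for the k-means initialization (default 0).
#' @return list with `embedding` (cells x n_pcs), `cluster` (integer
#'   labels), `features_used`.
#' @export
embed_and_cluster <- function(cm, features, n_pcs = 19, k = NULL, seed = 0L) {
  features <- intersect(features, cm$gene_info$gene)
  if (!length(features)) stop("no usable feature", call. = FALSE)
  sub <- cm$counts[match(features, cm$gene_info$gene), , drop = FALSE]
  m <- t(log1p(as.matrix(sub) %*% diag(1e4 / pmax(Matrix::colSums(cm$counts), 1),
                                       ncol(sub))))  # cells x genes
  sds <- apply(m, 2, stats::sd)
  informative <- sds > 0
  if (!any(informative)) {
    stop("degenerate embedding: every selected feature has zero variance across cells",
         call. = FALSE)
  }
  m <- scale(m[, informative, drop = FALSE])
  max_pcs <- min(nrow(m) - 1L, ncol(m))
  if (n_pcs > max_pcs) stop(sprintf("n_pcs = %d exceeds the usable rank %d", n_pcs, max_pcs),
                            call. = FALSE)
  pca <- stats::prcomp(m, rank. = n_pcs, center = FALSE, scale. = FALSE)
  emb <- pca$x
  rownames(emb) <- cm$cell_info$cell_id
  if (is.null(k)) k <- length(unique(cm$cell_info$sample))
  cl <- with_seed(as.integer(seed), {
    stats::kmeans(emb, centers = k, nstart = 10, iter.max = 100)
  })
  list(embedding = emb, cluster = unname(cl$cluster), features_used = features)
}

#' Adjusted Rand index between cluster labels and reference labels
#'
#' Chance-corrected agreement under the permutation model. Degenerate case:
#' when both partitions are trivial (the adjustment denominator is zero)
#' the ARI is defined as 1 if the partitions are identical up to label
#' names, else 0.
#'
#' @param labels,true_labels equal-length label vectors.
#' @param feature_set optional tag (e.g. `"supervised"`) echoed in the
#'   result.
#' @return object of class `cluster_recovery`: list with `ari`,
#'   `n_clusters`, `feature_set`.
#' @export
recovery_score <- function(labels, true_labels, feature_set = NA_character_) {
  if (length(labels) != length(true_labels)) stop("label lengths differ", call. = FALSE)
  structure(list(ari = adjusted_rand_index(labels, true_labels),
                 n_clusters = length(unique(labels)),
                 feature_set = feature_set),
            class = "cluster_recovery")
}

#' @rdname recovery_score
#' @export
adjusted_rand_index <- function(labels, true_labels) {
  tab <- table(labels, true_labels)
  n <- length(labels)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) {
    same <- identical(as.integer(factor(labels)), as.integer(factor(true_labels)))
    return(if (same) 1 else 0)
  }
  (sum_ij - expected) / (max_index - expected)
}

#' @export
print.cluster_recovery <- function(x, ...) {
  cat(sprintf("cluster_recovery: ARI = %.3f (%d clusters, features: %s)\n",
              x$ari, x$n_clusters, x$feature_set))
  invisible(x)
}

#' Fraction of cells positive for a gene by read count
#'
#' A cell is positive when it carries at least one read for the gene.
#'
#' @param cm a [count_matrix()].
#' @param gene gene symbol.
#' @param subset optional logical or index vector selecting cells.
#' @return percentage in `[0, 100]`.
#' @export
positive_cell_fraction <- function(cm, gene, subset = NULL) {
  i <- match(gene, cm$gene_info$gene)
  if (is.na(i)) stop(sprintf("gene '%s' not present", gene), call. = FALSE)
  counts <- cm$counts[i, ]
  if (!is.null(subset)) counts <- counts[subset]
  if (length(counts) == 0L) stop("empty cell subset", call. = FALSE)
  100 * sum(call_positive_counts(counts)) / length(counts)
}

#' Differential-expression threshold configuration
#'
#' Default thresholds follow the global differential-expression call
#' (log2 fold change > 2, base mean > 350, total-count > 50 prefilter);
#' `supervised = TRUE` switches to the laxer thresholds used to assemble
#' the supervised feature panel (log2FC > 1.5, base mean > 50).
#'
#' @param min_total_count raw-count prefilter across all cells (default 50).
#' @param lfc_threshold log2 fold-change threshold.
#' @param basemean_threshold base-mean threshold.
#' @param pseudocount added to both group means before the ratio.
#' @param supervised use the supervised-panel thresholds.
#' @return list of class `deg_config`.
#' @export
deg_config <- function(min_total_count = 50, lfc_threshold = 2,
                       basemean_threshold = 350, pseudocount = 1,
                       supervised = FALSE) {
  if (supervised) {
    lfc_threshold <- 1.5
    basemean_threshold <- 50
  }
  if (any(c(min_total_count, lfc_threshold, basemean_threshold, pseudocount) < 0)) {
    stop("thresholds must be >= 0", call. = FALSE)
  }
  structure(list(min_total_count = min_total_count, lfc_threshold = lfc_threshold,
                 basemean_threshold = basemean_threshold, pseudocount = pseudocount),
            class = "deg_config")
}

#' Thresholded pseudobulk differential expression
#'
#' A transparent simplification of a count-model DE test: per-cell values
#' are library-size normalized to a fixed counts-per-million (TPM-like)
#' scale — the idiom the default thresholds are quoted in, and one on
#' which a global rescaling of sequencing depth cannot change any call —
#' averaged within each of exactly two groups, and the fold change is
#' `log2((mean_B + pseudocount) / (mean_A + pseudocount))`. The base mean
#' is the mean normalized value over all cells. A gene passes when it
#' survives the raw total-count prefilter and exceeds both the fold-change
#' and base-mean thresholds.
#'
#' @param cm a [count_matrix()].
#' @param group_labels per-cell factor with exactly two levels; the second
#'   level is the numerator (B).
#' @param config a [deg_config()].
#' @return data.frame: gene, mean_a, mean_b, log2fc, base_mean,
#'   total_count, prefilter, pass.
#' @export
pseudobulk_deg <- function(cm, group_labels, config = deg_config()) {
  g <- factor(group_labels)
  if (nlevels(g) != 2L) stop("need exactly two groups", call. = FALSE)
  if (any(table(g) == 0L)) stop("a group has zero cells", call. = FALSE)
  if (length(g) != ncol(cm$counts)) stop("group labels do not match cells", call. = FALSE)
  norm <- normalize_cp10k(cm) * 100  # counts per million
  mean_a <- rowMeans(norm[, g == levels(g)[1L], drop = FALSE])
  mean_b <- rowMeans(norm[, g == levels(g)[2L], drop = FALSE])
  base_mean <- rowMeans(norm)
  total <- Matrix::rowSums(cm$counts)
  log2fc <- log2((mean_b + config$pseudocount) / (mean_a + config$pseudocount))
  prefilter <- total > config$min_total_count
  data.frame(gene = cm$gene_info$gene, mean_a = mean_a, mean_b = mean_b,
             log2fc = log2fc, base_mean = base_mean, total_count = total,
             prefilter = prefilter,
             pass = prefilter & log2fc > config$lfc_threshold &
                    base_mean > config$basemean_threshold,
             row.names = NULL)
}
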