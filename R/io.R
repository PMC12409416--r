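#' Write a cell intensity table as TSV
#'
#' Tab-separated, header row, UTF-8, "." decimal. Columns: `cell_id`,
#' `sample`, `condition`, `genotype`, then one column per channel named
#' `gene@fluorophore`.
#'
#' @param table a [cell_intensity_table()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_intensity_tsv <- function(table, path) {
  data.table::fwrite(as.data.frame(table), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a cell intensity table from TSV
#' @param path file written by [write_intensity_tsv()] (or any TSV with
#'   the same layout).
#' @return a [cell_intensity_table()].
#' @export
read_intensity_tsv <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- setdiff(meta_cols, names(df))
  if (length(need)) {
    stop(sprintf("%s: missing required columns: %s", path, paste(need, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(df$cell_id)) {
    dup <- df$cell_id[duplicated(df$cell_id)][1L]
    line <- which(df$cell_id == dup)[2L] + 1L  # +1 for the header row
    stop(sprintf("%s:%d: duplicate cell_id '%s'", path, line, dup), call. = FALSE)
  }
  chans <- setdiff(names(df), meta_cols)
  cell_intensity_table(df$cell_id, df$sample, df$condition, df$genotype,
                       df[chans])
}

#' Write a count matrix as MatrixMarket MTX plus annotation files
#'
#' Emits the 10x-style triplet: `matrix.mtx` (coordinate integer, 1-based),
#' `genes.tsv` (gene, mito flag, ribo flag) and `barcodes.tsv`
#' (cell_id, sample, condition, genotype).
#'
#' @param cm a [count_matrix()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_mtx <- function(cm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- cm$counts
  trip <- Matrix::summary(m)  # i, j, x (1-based)
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(m), ncol(m), nrow(trip))),
             file.path(dir, "matrix.mtx"))
  if (nrow(trip)) {
    data.table::fwrite(data.table::data.table(trip$i, trip$j, as.integer(trip$x)),
                       file.path(dir, "matrix.mtx"), sep = " ", append = TRUE,
                       col.names = FALSE)
  }
  data.table::fwrite(cm$gene_info, file.path(dir, "genes.tsv"), sep = "\t")
  data.table::fwrite(cm$cell_info, file.path(dir, "barcodes.tsv"), sep = "\t")
  invisible(dir)
}

#' Read a count matrix from an MTX triplet directory
#' @param dir directory holding `matrix.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @return a [count_matrix()].
#' @export
read_mtx <- function(dir) {
  mtx_path <- file.path(dir, "matrix.mtx")
  header <- readLines(mtx_path, n = 1L)
  if (!grepl("^%%MatrixMarket matrix coordinate (integer|real) general", header)) {
    stop(sprintf("%s:1: not a MatrixMarket coordinate header: '%s'", mtx_path, header),
         call. = FALSE)
  }
  head_lines <- readLines(mtx_path, n = 100L)
  n_comment <- which(!startsWith(head_lines, "%"))[1L] - 1L
  body <- as.data.frame(data.table::fread(mtx_path, skip = n_comment, header = FALSE,
                                          sep = " ", colClasses = "numeric"))
  dims <- unlist(body[1L, ], use.names = FALSE)
  trip <- body[-1L, , drop = FALSE]
  if (nrow(trip) != dims[3L]) {
    stop(sprintf("%s: entry count %d does not match declared %d",
                 mtx_path, nrow(trip), dims[3L]), call. = FALSE)
  }
  if (nrow(trip) && (min(trip[[1L]]) < 1 || min(trip[[2L]]) < 1)) {
    bad <- which(trip[[1L]] < 1 | trip[[2L]] < 1)[1L]
    stop(sprintf("%s:%d: MatrixMarket indices are 1-based; found a 0-based (or negative) index",
                 mtx_path, bad + n_comment + 1L), call. = FALSE)
  }
  if (nrow(trip) && any(trip[[3L]] != round(trip[[3L]]))) {
    bad <- which(trip[[3L]] != round(trip[[3L]]))[1L]
    stop(sprintf("%s:%d: non-integer count %g", mtx_path, bad + n_comment + 1L,
                 trip[[3L]][bad]), call. = FALSE)
  }
  m <- Matrix::sparseMatrix(i = trip[[1L]], j = trip[[2L]], x = trip[[3L]],
                            dims = dims[1:2])
  genes <- as.data.frame(data.table::fread(file.path(dir, "genes.tsv")))
  cells <- as.data.frame(data.table::fread(file.path(dir, "barcodes.tsv")))
  count_matrix(m, genes, cells)
}

#' Read a gene panel file (one symbol per line)
#' @param path text file; blank lines and `#` comments ignored.
#' @return character vector of gene symbols.
#' @export
read_panel <- function(path) {
  lines <- trimws(readLines(path))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Write simulation truth as TSV
#' @param truth a `simulation_truth`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  df <- data.frame(cell = seq_along(truth$s), size_factor = truth$s,
                   condition = truth$condition, genotype = truth$genotype)
  df <- cbind(df, as.data.frame(truth$on * 1L))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
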