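#' Per-cell integrated-intensity table
#'
#' The substrate of the FISH / immunofluorescence analysis: one row per
#' cell, with sample metadata and one nonnegative integrated-intensity
#' column per labeled channel. Channel columns are named
#' `"<gene>@<fluorophore>"` and the gene/fluorophore mapping is carried as
#' a `channels` attribute so that normalization can check that a gene
#' channel and its housekeeping reference share the same dye.
#'
#' @param cell_id character/integer vector of unique cell identifiers.
#' @param sample,condition,genotype per-cell metadata vectors (recycled if
#'   scalar).
#' @param intensities numeric matrix or data.frame, one column per channel,
#'   all values >= 0; column names become channel names.
#' @param channels data.frame with columns `channel`, `gene`, `fluorophore`
#'   describing each intensity column. If `NULL`, parsed from channel names
#'   of the form `gene@fluorophore`.
#' @return a data.frame of class `cell_intensity_table`.
#' @export
cell_intensity_table <- function(cell_id, sample, condition, genotype,
                                 intensities, channels = NULL) {
  intensities <- as.data.frame(intensities, check.names = FALSE)
  n <- length(cell_id)
  if (anyDuplicated(cell_id)) stop("duplicate cell_id", call. = FALSE)
  if (nrow(intensities) != n) stop("intensities and cell_id disagree on cell count", call. = FALSE)
  if (any(vapply(intensities, function(v) any(v < 0) || anyNA(v), logical(1)))) {
    stop("intensities must be nonnegative and non-missing", call. = FALSE)
  }
  if (is.null(channels)) channels <- parse_channel_names(names(intensities))
  stopifnot(is.data.frame(channels),
            all(c("channel", "gene", "fluorophore") %in% names(channels)))
  if (!setequal(channels$channel, names(intensities)) ||
      anyDuplicated(channels$channel)) {
    stop("every intensity column needs exactly one (gene, fluorophore) assignment",
         call. = FALSE)
  }
  tab <- data.frame(cell_id = cell_id,
                    sample = rep_len(sample, n),
                    condition = rep_len(condition, n),
                    genotype = rep_len(genotype, n),
                    check.names = FALSE)
  tab <- cbind(tab, intensities)
  attr(tab, "channels") <- channels[order(match(channels$channel, names(intensities))), ,
                                    drop = FALSE]
  class(tab) <- c("cell_intensity_table", "data.frame")
  tab
}

parse_channel_names <- function(nm) {
  parts <- strsplit(nm, "@", fixed = TRUE)
  data.frame(
    channel = nm,
    gene = vapply(parts, `[`, character(1), 1L),
    fluorophore = vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_,
                         character(1))
  )
}

#' @export
print.cell_intensity_table <- function(x, ...) {
  ch <- channel_info(x)
  cat(sprintf("cell_intensity_table: %d cells, %d channels (%s)\n",
              nrow(x), nrow(ch), paste(ch$channel, collapse = ", ")))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Channel metadata of a cell intensity table
#' @param table a `cell_intensity_table`.
#' @return data.frame with columns `channel`, `gene`, `fluorophore`.
#' @export
channel_info <- function(table) {
  ch <- attr(table, "channels")
  if (is.null(ch)) ch <- parse_channel_names(setdiff(names(table), meta_cols))
  ch
}

meta_cols <- c("cell_id", "sample", "condition", "genotype")

channel_values <- function(table, channel) {
  if (!channel %in% names(table)) {
    stop(sprintf("channel '%s' not present in table", channel), call. = FALSE)
  }
  table[[channel]]
}

#' Detection threshold from a negative-control sample
#'
#' The minimal detection threshold of a channel is an empirical quantile of
#' the per-cell intensities measured in a negative-control sample (a probe
#' with no target). The default quantile is 0.99 rather than the maximum,
#' to be robust to a single bright speck; `quantile = 1` gives the control
#' maximum. Quantiles use linear interpolation between order statistics
#' (R's default type 7), a convention that only matters for small control
#' samples.
#'
#' @param negative_control a `cell_intensity_table` measured on the
#'   negative-control sample.
#' @param channel channel (column) name.
#' @param quantile quantile in (0, 1\]; default 0.99.
#' @return object of class `detection_threshold`: list with `channel`,
#'   `threshold`, `source`, `quantile`.
#' @export
detection_threshold <- function(negative_control, channel, quantile = 0.99) {
  if (nrow(negative_control) == 0L) stop("empty negative-control table", call. = FALSE)
  if (quantile <= 0 || quantile > 1) stop("`quantile` must be in (0, 1]", call. = FALSE)
  v <- channel_values(negative_control, channel)
  if (length(v) < 30L) {
    warning(sprintf("only %d negative-control cells; threshold may be unstable", length(v)),
            call. = FALSE)
  }
  thr <- unname(stats::quantile(v, probs = quantile, type = 7))
  structure(list(channel = channel, threshold = thr,
                 source = unique(as.character(negative_control$sample))[1L],
                 quantile = quantile),
            class = "detection_threshold")
}

#' @export
print.detection_threshold <- function(x, ...) {
  cat(sprintf("detection_threshold: channel %s, threshold %.4g (q = %g, control '%s')\n",
              x$channel, x$threshold, x$quantile, x$source))
  invisible(x)
}

threshold_value <- function(threshold) {
  thr <- if (inherits(threshold, "detection_threshold")) threshold$threshold else threshold
  if (!is.numeric(thr) || length(thr) != 1L || is.na(thr) || thr < 0) {
    stop("threshold must be a single nonnegative number", call. = FALSE)
  }
  thr
}

#' Subtract a per-channel scalar background, clipped at zero
#'
#' Intensities become `max(intensity - background, 0)`; metadata and cell
#' order are unchanged. Background is a scalar per channel because the
#' table already holds segmented per-cell totals (pixel-level masking is
#' upstream of this package).
#'
#' @param table a `cell_intensity_table`.
#' @param background named numeric vector of nonnegative backgrounds; names
#'   are channel names. Channels not named are left untouched.
#' @return the corrected `cell_intensity_table`.
#' @export
subtract_background <- function(table, background) {
  if (any(background < 0) || anyNA(background)) {
    stop("background values must be nonnegative", call. = FALSE)
  }
  if (is.null(names(background)) && length(background) == 1L) {
    background <- stats::setNames(rep(background, nrow(channel_info(table))),
                                  channel_info(table)$channel)
  }
  for (ch in names(background)) {
    table[[ch]] <- pmax(channel_values(table, ch) - background[[ch]], 0)
  }
  table
}

#' Normalize a gene channel to a housekeeping probe of the same fluorophore
#'
#' Divides each cell's gene-channel intensity by the mean, over all cells,
#' of the housekeeping channel carried by the same fluorophore. Because a
#' dye's brightness multiplies both channels, the normalized value is
#' invariant to the dye gain, which is the point of the scheme. A
#' fluorophore mismatch between the two channels defeats that purpose and
#' is an error unless `force = TRUE` (then a warning).
#'
#' @param table a `cell_intensity_table`.
#' @param gene_channel channel to normalize.
#' @param housekeeping_channel reference channel (e.g. a POLR2A or UBC probe).
#' @param force proceed on fluorophore mismatch (warn instead of error).
#' @return numeric vector of dimensionless normalized values, one per cell.
#' @export
normalize_to_housekeeping <- function(table, gene_channel, housekeeping_channel,
                                      force = FALSE) {
  g <- channel_values(table, gene_channel)
  h <- channel_values(table, housekeeping_channel)
  ch <- channel_info(table)
  fg <- ch$fluorophore[ch$channel == gene_channel]
  fh <- ch$fluorophore[ch$channel == housekeeping_channel]
  if (!identical(fg, fh) && !(is.na(fg) && is.na(fh))) {
    msg <- sprintf("channels '%s' (%s) and '%s' (%s) carry different fluorophores",
                   gene_channel, fg, housekeeping_channel, fh)
    if (!force) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  m <- mean(h)
  if (m <= 0) stop("housekeeping mean intensity is zero", call. = FALSE)
  g / m
}

#' Call cells positive against a detection threshold
#'
#' A cell is positive iff its value is *strictly* greater than the
#' threshold: a cell exactly at the background level is below the
#' detection limit. For count data use [call_positive_counts()], where a
#' single read suffices.
#'
#' @param values numeric vector of per-cell values.
#' @param threshold a `detection_threshold` or a nonnegative scalar.
#' @return logical vector, one entry per cell.
#' @export
call_positive <- function(values, threshold) {
  values > threshold_value(threshold)
}

#' Positivity from read counts: at least one read
#' @param counts integer vector of per-cell counts.
#' @return logical vector.
#' @export
call_positive_counts <- function(counts) {
  counts >= 1
}
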