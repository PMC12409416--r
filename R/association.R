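#' Spearman rank correlation between two single-cell channels
#'
#' Both vectors are ranked with average ranks for ties and rho is the
#' product-moment correlation of the ranks. The two-sided p-value uses the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees
#' of freedom; for very small samples (`n <= exact_max`, default 10) an
#' exact permutation p-value is computed by full enumeration instead.
#' Cells below the detection limit are included at their measured value by
#' default (scatter plots in this kind of analysis show sub-threshold
#' cells); pass `drop_double_negative` thresholds to exclude cells negative
#' on both channels.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param exact_max largest n for which the exact permutation p-value is
#'   enumerated (capped at 10).
#' @param drop_double_negative optional list(thr_x =, thr_y =): remove
#'   cells at or below both thresholds before correlating. Off by default.
#' @return object of class `correlation_result`: list with `rho`, `n`,
#'   `p_value`, `method`, and the channel values' `constant` flag.
#' @export
spearman_rho <- function(x, y, exact_max = 10, drop_double_negative = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite", call. = FALSE)
  if (!is.null(drop_double_negative)) {
    keep <- x > threshold_value(drop_double_negative$thr_x) |
            y > threshold_value(drop_double_negative$thr_y)
    x <- x[keep]; y <- y[keep]
  }
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("constant vector: Spearman's rho is undefined", call. = FALSE)
    return(structure(list(rho = NA_real_, n = n, p_value = NA_real_,
                          method = "undefined (constant input)", constant = TRUE),
                     class = "correlation_result"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= min(exact_max, 10L)) {
    p <- spearman_exact_p(rx, ry, rho)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  structure(list(rho = rho, n = n, p_value = min(max(p, .Machine$double.xmin), 1),
                 method = method, constant = FALSE),
            class = "correlation_result")
}

# Two-sided exact permutation p-value: enumerate all n! orderings of y's
# ranks and count |rho_perm| >= |rho_obs| (within rounding).
spearman_exact_p <- function(rx, ry, rho_obs) {
  n <- length(rx)
  P <- all_permutations(n)
  ry_perm <- matrix(ry[P], nrow = nrow(P))
  rxc <- rx - mean(rx)
  num <- as.vector(ry_perm %*% rxc)  # covariance numerator per permutation
  denom <- sqrt(sum(rxc^2) * sum((ry - mean(ry))^2))
  rho_all <- num / denom
  mean(abs(rho_all) >= abs(rho_obs) - 1e-10)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    remapped <- sub + (sub >= i)
    out[[i]] <- cbind(rep.int(i, nrow(sub)), remapped, deparse.level = 0)
  }
  do.call(rbind, out)
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f (n = %d, p = %.3g, %s)\n",
              x$rho, x$n, x$p_value, x$method))
  invisible(x)
}

#' 2x2 positivity-overlap table of two channels
#'
#' Cross-tabulates cells as positive/negative on each channel using the
#' strict ">" rule of [call_positive()]. Mirrors the
#' over/below-detection-limit tables printed under single-cell
#' co-expression scatter plots.
#'
#' @param x,y numeric vectors of equal length.
#' @param thr_x,thr_y thresholds (`detection_threshold` objects or
#'   nonnegative scalars).
#' @return object of class `positivity_table`: list with counts `n_pp`,
#'   `n_pn`, `n_np`, `n_nn` (x-positive/y-positive, x-positive/y-negative,
#'   ...), `n`, percentage table `pct`, and the thresholds used.
#' @export
positivity_table <- function(x, y, thr_x, thr_y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  px <- call_positive(x, thr_x)
  py <- call_positive(y, thr_y)
  counts <- c(n_pp = sum(px & py), n_pn = sum(px & !py),
              n_np = sum(!px & py), n_nn = sum(!px & !py))
  structure(list(n_pp = counts[["n_pp"]], n_pn = counts[["n_pn"]],
                 n_np = counts[["n_np"]], n_nn = counts[["n_nn"]],
                 n = length(x), pct = 100 * counts / length(x),
                 thr_x = threshold_value(thr_x), thr_y = threshold_value(thr_y)),
            class = "positivity_table")
}

#' @export
print.positivity_table <- function(x, ...) {
  m <- matrix(c(x$n_pp, x$n_pn, x$n_np, x$n_nn), 2, 2, byrow = TRUE,
              dimnames = list(c("x positive", "x negative"),
                              c("y positive", "y negative")))
  cat(sprintf("positivity_table (n = %d, thresholds %.4g / %.4g)\n", x$n, x$thr_x, x$thr_y))
  print(m)
  invisible(x)
}

#' Conditional positive fraction from a positivity table
#'
#' Among cells positive for one channel, the percentage also positive for
#' the other: `100 * n_pp / (n_pp + n_pn)` conditioning on x, and
#' symmetrically for y. This is the "among all A-positive cells, B\% were
#' also positive for ..." statistic.
#'
#' @param table a `positivity_table`.
#' @param given `"x"` or `"y"`: which channel's positives form the
#'   denominator.
#' @return percentage, or `NA` with a warning if the denominator is empty.
#' @export
conditional_positive_fraction <- function(table, given = c("x", "y")) {
  given <- match.arg(given)
  denom <- if (given == "x") table$n_pp + table$n_pn else table$n_pp + table$n_np
  if (denom == 0) {
    warning("no cells positive for the conditioning channel; fraction undefined",
            call. = FALSE)
    return(NA_real_)
  }
  100 * table$n_pp / denom
}

#' Benjamini-Hochberg q-values for a batch of correlations
#'
#' Advisory multiple-testing adjustment when many channel pairs are tested
#' at once; raw rho/p remain the primary output.
#'
#' @param p_values numeric vector of raw p-values.
#' @return vector of BH-adjusted q-values.
#' @export
adjust_q_values <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}
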