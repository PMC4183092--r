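#' Instantaneous cross-trial noise correlations
#'
#' For each time bin, the Pearson correlation coefficient (phi coefficient)
#' across trials between the binary spiking indicators of two cells: the
#' cells' instantaneous noise correlation under one frozen input. Bins in
#' which either cell has zero cross-trial variance (never or always spikes)
#' carry no information about co-variability and are masked.
#'
#' @param binarr Output of [binarize()] with at least 2 trials.
#' @param pairs Two-column matrix of cell indices *into the array's cell
#'   dimension* (default: all unordered pairs).
#' @return A `"correlation_field"`: matrix `c` (`pairs x bins`, `NA` where
#'   masked), the `pairs` matrix (array indices), the cell labels, and the
#'   bin width.
#' @export
noise_correlation <- function(binarr, pairs = NULL) {
  M <- dim(binarr)[1]
  K <- dim(binarr)[2]
  nb <- dim(binarr)[3]
  stopifnot(M >= 2)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(K, 2))
  }
  pairs <- matrix(as.integer(pairs), ncol = 2)
  # per-bin sufficient statistics, vectorized over bins
  mean_kb <- matrix(0, K, nb) # spiking probability per (cell, bin)
  for (k in seq_len(K)) {
    mean_kb[k, ] <- colMeans(matrix(binarr[, k, , drop = FALSE], M, nb))
  }
  cmat <- matrix(NA_real_, nrow(pairs), nb)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]
    j <- pairs[r, 2]
    xi <- matrix(binarr[, i, , drop = FALSE], M, nb)
    xj <- matrix(binarr[, j, , drop = FALSE], M, nb)
    mi <- mean_kb[i, ]
    mj <- mean_kb[j, ]
    covv <- colMeans(xi * xj) - mi * mj
    vi <- mi - mi^2 # binary indicator variance (MLE form; ratio-invariant)
    vj <- mj - mj^2
    ok <- vi > 0 & vj > 0
    cmat[r, ok] <- covv[ok] / sqrt(vi[ok] * vj[ok])
  }
  structure(
    list(c = cmat, pairs = pairs, cells = attr(binarr, "cells"),
         dt = attr(binarr, "dt"), t0 = attr(binarr, "t0"),
         trials = M),
    class = "correlation_field"
  )
}

#' @export
print.correlation_field <- function(x, ...) {
  cat(sprintf(
    "noise correlation field: %d pairs x %d bins (%d trials), %.1f%% bins valid\n",
    nrow(x$c), ncol(x$c), x$trials, 100 * mean(!is.na(x$c))
  ))
  invisible(x)
}

#' Temporal summary of a correlation field
#'
#' Mask-aware temporal mean and standard deviation of `c_ij(t_l)` per pair
#' over a time window, plus cross-pair aggregates. Weak *average*
#' correlations can coexist with sizable instantaneous ones; the cross-pair
#' spread of temporal means versus the typical instantaneous magnitude
#' quantifies that distinction.
#'
#' @param field A `"correlation_field"`.
#' @param window Time window `c(t0, t1)` in time-units (default: the whole
#'   field).
#' @return List with per-pair `mean` and `sd`, and aggregates
#'   `mean_of_means`, `sd_of_means`, `median_abs_c` (median instantaneous
#'   `|c|` over all valid entries).
#' @export
temporal_summary <- function(field, window = NULL) {
  nb <- ncol(field$c)
  bins <- seq_len(nb)
  if (!is.null(window)) {
    tt <- field$t0 + (bins - 1) * field$dt
    bins <- bins[tt >= window[1] & tt < window[2]]
    stopifnot(length(bins) >= 1)
  }
  sub <- field$c[, bins, drop = FALSE]
  m <- rowMeans(sub, na.rm = TRUE)
  s <- apply(sub, 1, sd, na.rm = TRUE)
  list(mean = m, sd = s,
       mean_of_means = mean(m, na.rm = TRUE),
       sd_of_means = sd(m),
       median_abs_c = median(abs(sub), na.rm = TRUE))
}
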