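#' Binarize a spike raster into words
#'
#' Discretizes time into bins of width `dt_bin`; bin `b` of a cell is 1 iff
#' a spike of that cell falls in `[t0 + (b-1)*dt, t0 + b*dt)`. Bins that
#' receive more than one spike are clipped to 1 and counted in the
#' `"clipped"` attribute (with the default bin width this is essentially
#' impossible for theta neurons, whose interspike interval is bounded below).
#'
#' @param raster A `"spike_raster"`.
#' @param cells Cells to binarize (default: all recorded).
#' @param window Analysis window `c(t0, t1)` in time-units; defaults to the
#'   post-transient record.
#' @return Integer array `trials x cells x bins` with attributes `dt`,
#'   `t0`, `cells` and `clipped`.
#' @export
binarize <- function(raster, cells = NULL, window = NULL) {
  stopifnot(inherits(raster, "spike_raster"))
  dt <- raster$dt_bin
  if (is.null(window)) window <- c(raster$transient, raster$duration)
  if (is.null(cells)) cells <- sort(unique(raster$spikes$neuron))
  nbins <- floor((window[2] - window[1]) / dt + 1e-9)
  stopifnot(nbins >= 1)
  M <- raster$n_trials
  K <- length(cells)
  arr <- array(0L, dim = c(M, K, nbins))
  sp <- raster$spikes
  keep <- sp$neuron %in% cells & sp$time >= window[1] &
    sp$time < window[1] + nbins * dt
  sp <- sp[keep, , drop = FALSE]
  if (nrow(sp) > 0) {
    cellidx <- match(sp$neuron, cells)
    bin <- floor((sp$time - window[1]) / dt) + 1L
    bin[bin > nbins] <- nbins
    ijk <- cbind(sp$trial, cellidx, bin)
    clipped <- sum(duplicated(ijk))
    arr[ijk] <- 1L
  } else {
    clipped <- 0L
  }
  attr(arr, "dt") <- dt
  attr(arr, "t0") <- window[1]
  attr(arr, "cells") <- cells
  attr(arr, "clipped") <- clipped
  arr
}

# integer word ids (trials x windows) for one cell's trial x bin matrix;
# bit order is bin-major within the cell, earliest bin most significant.
# One sparse matrix product per word length keeps this linear in the data.
word_ids_cell <- function(binmat, L) {
  nbins <- ncol(binmat)
  nwin <- nbins %/% L
  W <- Matrix::sparseMatrix(
    i = seq_len(nwin * L), j = rep(seq_len(nwin), each = L),
    x = rep(2^((L - 1):0), nwin), dims = c(nbins, nwin)
  )
  as.matrix(binmat %*% W)
}

# per-cell trial x bin matrices in double storage, extracted once so that
# repeated word-length sweeps do not re-materialize the array
cell_matrices <- function(binarr) {
  M <- dim(binarr)[1]
  nb <- dim(binarr)[3]
  lapply(seq_len(dim(binarr)[2]), function(k) {
    m <- matrix(as.double(binarr[, k, , drop = FALSE]), M, nb)
    m
  })
}

# combined ids across cells, cell-major (first cell most significant)
word_ids_mats <- function(mats, L) {
  ids <- word_ids_cell(mats[[1]], L)
  if (length(mats) > 1) {
    for (k in 2:length(mats)) {
      ids <- ids * 2^L + word_ids_cell(mats[[k]], L)
    }
  }
  ids
}

word_ids <- function(binarr, L) {
  word_ids_mats(cell_matrices(binarr), L)
}

#' Cross-trial word distribution in one window
#'
#' Empirical distribution of `K`-cell x `L`-bin binary words in the window
#' starting at bin index `start` (1-based), counted across trials.
#'
#' @param binarr Output of [binarize()].
#' @param L Word length in bins.
#' @param start First bin of the window.
#' @return A `"word_distribution"`: word counts keyed by integer code
#'   (cell-major bit concatenation), trial total, `K`, `L`, and window
#'   start time.
#' @export
word_distribution <- function(binarr, L, start = 1) {
  K <- dim(binarr)[2]
  nbins <- dim(binarr)[3]
  stopifnot(start + L - 1 <= nbins)
  sub <- binarr[, , start:(start + L - 1), drop = FALSE]
  ids <- word_ids(sub, L)[, 1]
  tab <- table(ids)
  structure(
    list(K = K, L = L,
         t_start = attr(binarr, "t0") + (start - 1) * attr(binarr, "dt"),
         counts = as.vector(tab), words = as.numeric(names(tab)),
         total = length(ids)),
    class = "word_distribution"
  )
}

#' Noise-entropy rate of a word distribution
#'
#' Plug-in estimate `-(1/(L*dt)) * sum(p * log2(p))` over the cross-trial
#' word probabilities, in bits per time-unit.
#'
#' @param dist A `"word_distribution"` (or a vector of counts, in which
#'   case `L` must be supplied).
#' @param dt Bin width in time-units.
#' @param L Word length (taken from `dist` when it is a distribution).
#' @return Entropy rate in bits/tu.
#' @export
noise_entropy_rate <- function(dist, dt, L = NULL) {
  if (inherits(dist, "word_distribution")) {
    counts <- dist$counts
    L <- dist$L
  } else {
    counts <- dist
    stopifnot(!is.null(L))
  }
  stopifnot(sum(counts) > 0)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p)) / (L * dt)
}

#' Time-averaged noise-entropy rate at one word length
#'
#' Plug-in entropy rates are computed for consecutive, non-overlapping
#' `L`-bin windows over the post-transient record and averaged, exploiting
#' the statistical stationarity of the driven network.
#'
#' @param binarr Output of [binarize()] (`trials x cells x bins`).
#' @param L Word length in bins.
#' @param cells Cell subset within the array (default: all of it).
#' @return List with the mean rate `H` (bits/tu), the number of windows,
#'   the per-window rates, and the trial count.
#' @export
time_averaged_entropy <- function(binarr, L, cells = NULL) {
  dt <- attr(binarr, "dt")
  if (!is.null(cells)) {
    keep <- match(cells, attr(binarr, "cells"))
    stopifnot(!anyNA(keep))
    binarr2 <- binarr[, keep, , drop = FALSE]
    attr(binarr2, "dt") <- dt
    binarr <- binarr2
  }
  nbins <- dim(binarr)[3]
  if (nbins < L) stop("record shorter than one window", call. = FALSE)
  ids <- word_ids(binarr, L)
  perwin <- cpp_word_entropies(ids) / (L * dt)
  list(H = mean(perwin), windows = ncol(ids), per_window = perwin,
       trials = dim(binarr)[1])
}

# shared fast path: entropy rates over several word lengths from
# pre-extracted cell matrices
entropy_over_L <- function(mats, Ls, dt) {
  vapply(Ls, function(L) {
    ids <- word_ids_mats(mats, L)
    mean(cpp_word_entropies(ids)) / (L * dt)
  }, numeric(1))
}

#' Entropy rate as a function of word length
#'
#' @param binarr Output of [binarize()].
#' @param Ls Word lengths to evaluate (default `1:20`).
#' @param cells Optional cell subset.
#' @return Data frame with columns `L`, `H` (bits/tu), `windows`, `trials`.
#' @export
entropy_curve <- function(binarr, Ls = 1:20, cells = NULL) {
  dt <- attr(binarr, "dt")
  if (!is.null(cells)) {
    keep <- match(cells, attr(binarr, "cells"))
    stopifnot(!anyNA(keep))
    binarr2 <- binarr[, keep, , drop = FALSE]
    attr(binarr2, "dt") <- dt
    binarr <- binarr2
  }
  mats <- cell_matrices(binarr)
  nbins <- dim(binarr)[3]
  H <- entropy_over_L(mats, Ls, dt)
  data.frame(L = Ls, H = H, windows = nbins %/% Ls,
             trials = dim(binarr)[1])
}

#' Extrapolate the entropy rate to infinite word length
#'
#' Entropy rates of a system with finite correlation time decrease linearly
#' in `1/L` once `L` is large enough (the extensive regime), until finite
#' sampling makes the estimates drop. Following the direct-method
#' convention, the extrapolation finds the point of least fractional change
#' in slope of `H` versus `1/L`, fits a straight line through the extensive
#' segment around that point, and reports the intercept at `1/L -> 0`.
#'
#' @param perL Data frame with columns `L` and `H` (as from
#'   [entropy_curve()]), or a named numeric vector (names = `L`).
#' @return An `"entropy_estimate"`: `limit` (bits/tu), chosen `L_star`,
#'   fitted `slope` and `intercept`, the fitted `L` values, and the input
#'   curve.
#' @examples
#' # exactly extensive curve H = a + b/L recovers a
#' est <- extrapolate_entropy(data.frame(L = 1:8, H = 2 + 3 / (1:8)))
#' est$limit
#' @export
extrapolate_entropy <- function(perL) {
  if (!is.data.frame(perL)) {
    perL <- data.frame(L = as.numeric(names(perL)), H = as.numeric(perL))
  }
  perL <- perL[order(perL$L), ]
  L <- perL$L
  H <- perL$H
  n <- length(L)
  if (n < 4) stop("need at least 4 word lengths to extrapolate", call. = FALSE)
  if (all(diff(H) >= 0) && any(diff(H) > 0)) {
    stop("entropy rate increases with L; non-physical curve, cannot extrapolate",
         call. = FALSE)
  }
  if (all(abs(H - H[1]) < 1e-12)) {
    return(structure(
      list(limit = H[1], L_star = L[n], slope = 0, intercept = H[1],
           fit_L = L, perL = perL),
      class = "entropy_estimate"
    ))
  }
  x <- 1 / L
  s <- diff(H) / diff(x) # slope of each segment, ordered by increasing L
  frac <- abs(diff(s)) / pmax(abs(s[-length(s)]), 1e-12)
  k <- which.min(frac) # earliest minimum wins ties
  fit_idx <- k:(k + 2) # the two segments with the most stable slope
  fit <- lm(H[fit_idx] ~ x[fit_idx])
  limit <- unname(coef(fit)[1])
  structure(
    list(limit = limit, L_star = L[k + 1], slope = unname(coef(fit)[2]),
         intercept = limit, fit_L = L[fit_idx], perL = perL),
    class = "entropy_estimate"
  )
}

#' @export
print.entropy_estimate <- function(x, ...) {
  cat(sprintf(
    "entropy estimate: limit %.4f bits/tu (L* = %d, fit through L = %s)\n",
    x$limit, x$L_star, paste(x$fit_L, collapse = ",")
  ))
  invisible(x)
}

#' Extrapolated single-cell noise-entropy rate
#'
#' Convenience wrapper: binarize one cell, compute the entropy curve for
#' word lengths up to `Lmax`, and extrapolate to `L -> infinity`.
#'
#' @param raster A `"spike_raster"` in which the cell was recorded.
#' @param cell Neuron index.
#' @param Lmax Largest word length (default 20).
#' @param window Optional analysis window passed to [binarize()].
#' @return An `"entropy_estimate"`.
#' @export
single_cell_entropy <- function(raster, cell, Lmax = 20, window = NULL) {
  extrapolate_entropy(spike_entropy_curve(raster, cell, Lmax, window))
}

#' Entropy curve computed directly from a raster's spike lists
#'
#' Equivalent to [binarize()] followed by [entropy_curve()] (double-spike
#' bins clipped identically), but linear in the number of spikes, which
#' matters for large trial ensembles.
#'
#' @inheritParams single_cell_entropy
#' @param cells Cell subset (word bits are cell-major in this order).
#' @return Data frame with columns `L`, `H` (bits/tu), `windows`, `trials`.
#' @export
spike_entropy_curve <- function(raster, cells, Lmax = 20, window = NULL) {
  dt <- raster$dt_bin
  if (is.null(window)) window <- c(raster$transient, raster$duration)
  nbins <- floor((window[2] - window[1]) / dt + 1e-9)
  sp <- raster$spikes
  keep <- sp$neuron %in% cells & sp$time >= window[1] &
    sp$time < window[1] + nbins * dt
  sp <- sp[keep, , drop = FALSE]
  res <- cpp_spike_entropy_curve(
    as.integer(sp$trial),
    as.integer(floor((sp$time - window[1]) / dt)),
    match(sp$neuron, cells) - 1L,
    raster$n_trials, as.integer(nbins), length(cells),
    as.integer(seq_len(Lmax))
  )
  data.frame(L = seq_len(Lmax), H = res$H / (seq_len(Lmax) * dt),
             windows = res$windows, trials = raster$n_trials)
}

#' Pairwise entropy redundancy
#'
#' `delta_ij = lim_L [H1(i) + H1(j) - H2(i, j)]`, the difference between the
#' sum of two cells' marginal noise-entropy rates and their joint pair
#' rate. Positive values measure how much the cells' trial-to-trial
#' variability is shared. All three terms are extrapolated with word
#' lengths up to `Lmax` (pair words explode combinatorially, hence the
#' default 10).
#'
#' @param raster A `"spike_raster"`.
#' @param i,j Neuron indices (both must spike at least once).
#' @param Lmax Largest word length used for all three extrapolations.
#' @param window Optional analysis window.
#' @return List with `delta` (bits/tu) and the three underlying estimates.
#' @export
pairwise_delta <- function(raster, i, j, Lmax = 10, window = NULL) {
  if (!any(raster$spikes$neuron == i) || !any(raster$spikes$neuron == j)) {
    stop("both cells must spike at least once", call. = FALSE)
  }
  Hi <- extrapolate_entropy(spike_entropy_curve(raster, i, Lmax, window))
  Hj <- extrapolate_entropy(spike_entropy_curve(raster, j, Lmax, window))
  Hij <- extrapolate_entropy(spike_entropy_curve(raster, c(i, j), Lmax,
                                                 window))
  list(delta = Hi$limit + Hj$limit - Hij$limit,
       H_i = Hi, H_j = Hj, H_ij = Hij)
}

#' Naive extensive bound on network noise entropy
#'
#' Joint entropy is bounded by the sum of marginals, so `N * <H1>`, with
#' `<H1>` the average extrapolated single-cell rate, bounds the network
#' noise-entropy rate from above. The uncertainty band is `N` times two
#' standard errors of the mean of the sample.
#'
#' @param singleH Numeric sample of extrapolated single-cell entropy rates
#'   (bits/tu), at least 2 values unless the band is not needed.
#' @param N Network size to extrapolate to.
#' @return List with `value` (bits/tu), `band` (length-2 vector), `mean_H1`
#'   and `se_H1`.
#' @export
naive_network_bound <- function(singleH, N) {
  m <- mean(singleH)
  se <- if (length(singleH) >= 2) sd(singleH) / sqrt(length(singleH)) else NA_real_
  list(value = N * m, band = N * c(m - 2 * se, m + 2 * se),
       mean_H1 = m, se_H1 = se, n_cells = length(singleH))
}
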