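#' Synthetic fixtures with known ground truth
#'
#' Generates small synthetic objects whose exact statistics are known in
#' closed form, for validating the estimators without running the
#' simulator:
#' * `"bernoulli_iid"`: binary raster, iid Bernoulli(`p`) per bin; ground
#'   truth entropy rate `H2(p) / dt` bits/tu at every word length.
#' * `"bernoulli_profile"`: inhomogeneous Bernoulli with per-bin
#'   probability profile `p`; ground truth mean window entropy per `L`.
#' * `"duplicated_pair"`: two perfectly correlated copies of one Bernoulli
#'   cell; ground truth pairwise redundancy `delta = H2(p) / dt`.
#' * `"correlated_pair"`: bivariate Bernoulli with Pearson correlation
#'   `rho` per bin.
#' * `"poisson_trains"`: homogeneous Poisson spike raster at given rates.
#' * `"toy_spectrum"`: a `"lyapunov_spectrum"` from explicit exponents;
#'   ground truth `H_KS = sum(lambda > 0) / ln 2`.
#'
#' @param kind Fixture kind (see above).
#' @param params Named list of parameters: `p` (probability or per-bin
#'   profile), `trials`, `bins`, `dt`, `rho`, `rates`, `T`, `lambda`
#'   as applicable.
#' @param seed Integer seed.
#' @return The fixture object with a `"ground_truth"` attribute.
#' @examples
#' fx <- make_fixture("bernoulli_iid",
#'                    list(p = 0.04, trials = 200, bins = 400), seed = 1)
#' attr(fx, "ground_truth")$H # H2(0.04) / 0.05
#' @export
make_fixture <- function(kind = c("bernoulli_iid", "bernoulli_profile",
                                  "duplicated_pair", "correlated_pair",
                                  "poisson_trains", "toy_spectrum"),
                         params = list(), seed = 1L) {
  kind <- match.arg(kind)
  p0 <- function(name, default) if (!is.null(params[[name]])) params[[name]] else default
  dt <- p0("dt", 0.05)
  switch(kind,
    bernoulli_iid = {
      p <- p0("p", 0.04)
      M <- p0("trials", 500)
      nb <- p0("bins", 1000)
      K <- p0("cells", 1)
      arr <- with_local_seed(seed, {
        array(as.integer(runif(M * K * nb) < p), dim = c(M, K, nb))
      })
      attr(arr, "dt") <- dt
      attr(arr, "t0") <- 0
      attr(arr, "cells") <- seq_len(K)
      attr(arr, "ground_truth") <- list(H = binary_entropy(p) / dt, p = p)
      arr
    },
    bernoulli_profile = {
      p <- params$p # vector, one probability per bin
      stopifnot(!is.null(p))
      M <- p0("trials", 500)
      nb <- length(p)
      arr <- with_local_seed(seed, {
        array(as.integer(runif(M * nb) < rep(p, each = M)), dim = c(M, 1, nb))
      })
      attr(arr, "dt") <- dt
      attr(arr, "t0") <- 0
      attr(arr, "cells") <- 1L
      # independent bins: window entropy is the sum of per-bin entropies
      truth_H <- function(L) {
        nwin <- nb %/% L
        hb <- binary_entropy(p)
        mean(vapply(seq_len(nwin), function(w) {
          sum(hb[((w - 1) * L + 1):(w * L)]) / (L * dt)
        }, numeric(1)))
      }
      attr(arr, "ground_truth") <- list(H_of_L = truth_H, p = p)
      arr
    },
    duplicated_pair = {
      p <- p0("p", 0.04)
      M <- p0("trials", 500)
      nb <- p0("bins", 1000)
      one <- with_local_seed(seed, matrix(as.integer(runif(M * nb) < p), M, nb))
      arr <- array(0L, dim = c(M, 2, nb))
      arr[, 1, ] <- one
      arr[, 2, ] <- one
      attr(arr, "dt") <- dt
      attr(arr, "t0") <- 0
      attr(arr, "cells") <- 1:2
      attr(arr, "ground_truth") <- list(delta = binary_entropy(p) / dt, p = p)
      arr
    },
    correlated_pair = {
      p <- p0("p", 0.1)
      rho <- p0("rho", 0.3)
      M <- p0("trials", 500)
      nb <- p0("bins", 1000)
      p11 <- p^2 + rho * p * (1 - p)
      stopifnot(p11 >= 0, p11 <= p)
      arr <- with_local_seed(seed, {
        # draw (X, Y) per (trial, bin) from the bivariate Bernoulli with
        # P(1,1) = p11 and both marginals p
        u <- runif(M * nb)
        x <- integer(M * nb)
        y <- integer(M * nb)
        both <- u < p11
        onlyx <- u >= p11 & u < p
        onlyy <- u >= p & u < 2 * p - p11
        x[both | onlyx] <- 1L
        y[both | onlyy] <- 1L
        a <- array(0L, dim = c(M, 2, nb))
        a[, 1, ] <- x
        a[, 2, ] <- y
        a
      })
      attr(arr, "dt") <- dt
      attr(arr, "t0") <- 0
      attr(arr, "cells") <- 1:2
      attr(arr, "ground_truth") <- list(rho = rho, p = p)
      arr
    },
    poisson_trains = {
      rates <- p0("rates", 0.8)
      T <- p0("T", 100)
      M <- p0("trials", 1)
      sp <- with_local_seed(seed, {
        rows <- list()
        for (m in seq_len(M)) {
          for (k in seq_along(rates)) {
            n <- rpois(1, rates[k] * T)
            if (n > 0) {
              rows[[length(rows) + 1]] <-
                data.frame(trial = m, neuron = k, time = sort(runif(n, 0, T)))
            }
          }
        }
        if (length(rows) > 0) do.call(rbind, rows) else
          data.frame(trial = integer(0), neuron = integer(0),
                     time = numeric(0))
      })
      r <- structure(
        list(spikes = sp, n_neurons = length(rates), n_trials = M,
             duration = T, dt_bin = dt, transient = 0,
             populations = rep("E", length(rates)),
             config_hash = "fixture", input_seed = seed, phases = NULL),
        class = "spike_raster"
      )
      attr(r, "ground_truth") <- list(rates = rates)
      r
    },
    toy_spectrum = {
      lam <- sort(params$lambda, decreasing = TRUE)
      stopifnot(!is.null(lam))
      s <- structure(
        list(exponents = lam, m = length(lam), N = length(lam),
             trace = NULL, t_accum = Inf, t_ortho = NA,
             config_hash = "fixture", input_seed = seed),
        class = "lyapunov_spectrum"
      )
      attr(s, "ground_truth") <- list(H_KS = sum(lam[lam > 0]) / log(2))
      s
    }
  )
}

#' Binary (Bernoulli) entropy in bits
#'
#' @param p Probability (vectorized).
#' @return `-p log2 p - (1-p) log2 (1-p)`, with `H(0) = H(1) = 0`.
#' @export
binary_entropy <- function(p) {
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  q <- p[ok]
  h[ok] <- -q * log2(q) - (1 - q) * log2(1 - q)
  h
}

#' Convert a binary-array fixture to a spike raster
#'
#' Places a spike at the center of every set bin, yielding a
#' `"spike_raster"` whose binarization reproduces the array exactly.
#' Useful for feeding array fixtures to raster-based estimators.
#'
#' @param binarr A `trials x cells x bins` binary array with a `dt`
#'   attribute (as produced by [make_fixture()] or [binarize()]).
#' @return A `"spike_raster"` with zero transient.
#' @export
fixture_to_raster <- function(binarr) {
  dt <- attr(binarr, "dt")
  M <- dim(binarr)[1]
  K <- dim(binarr)[2]
  nb <- dim(binarr)[3]
  idx <- which(binarr == 1L, arr.ind = TRUE)
  structure(
    list(
      spikes = data.frame(trial = idx[, 1], neuron = idx[, 2],
                          time = (idx[, 3] - 0.5) * dt),
      n_neurons = K, n_trials = M, duration = nb * dt,
      dt_bin = dt, transient = 0,
      populations = rep("E", K), config_hash = "fixture",
      input_seed = NA_integer_, phases = NULL
    ),
    class = "spike_raster"
  )
}
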