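#' Lyapunov spectrum of the driven network
#'
#' Computes the leading `m` Lyapunov exponents of the network under one
#' quenched input realization, from the tangent dynamics of the
#' Euler-Maruyama step map. The Jacobian of the step includes the
#' derivatives of the drift *and* of the multiplicative noise term (a
#' diagonal contribution `eps * Z'(theta_i) * dW_i`), together with the
#' coupling cross-terms `Z(theta_i) * a_ij * g'(theta_j)`. An orthonormal
#' frame is propagated and re-orthonormalized by QR factorization every
#' `t_ortho` time-units; exponents are the time-averaged logarithmic growth
#' of the R diagonal, accumulated after a discarded transient.
#'
#' Exponents are reported in nats per time-unit; conversion to bits happens
#' only in [ks_bound()], so the `1/ln 2` factor is applied exactly once.
#'
#' @param cfg A [network_config()].
#' @param A A `"coupling_matrix"` or `NULL`.
#' @param T Total integration time in time-units (including the transient).
#' @param m Number of exponents (default `ceiling(0.4 * N)`: the positive
#'   part of the spectrum in the chaotic balanced regime sits well inside
#'   the first 10% of ranks, and the margin certifies that the last
#'   computed exponent is negative).
#' @param input An `"input_realization"` covering `[0, T]`; defaults to a
#'   fresh one from `cfg$seeds$input`.
#' @param t_ortho Re-orthonormalization interval in time-units (default 1).
#' @param transient Discarded initial stretch in time-units (default
#'   `cfg$transient`).
#' @param ic Initial phase vector (default: uniform from `cfg$seeds$ic`).
#' @return A `"lyapunov_spectrum"`: sorted exponents (nats/tu), convergence
#'   trace (running estimates at each orthonormalization), accumulation
#'   time, and run metadata.
#' @export
lyapunov_spectrum <- function(cfg, A, T, m = ceiling(0.4 * cfg$N),
                              input = NULL, t_ortho = 1,
                              transient = cfg$transient, ic = NULL) {
  validate_config(cfg)
  N <- cfg$N
  stopifnot(m >= 1, m <= N, T > transient)
  if (is.null(input)) input <- generate_input(cfg, 0, T)
  if (is.null(ic)) {
    ic <- with_local_seed(seed_stream(cfg$seeds$ic, "lyapunov-ic"), runif(N))
  }
  csc <- coupling_csc(A, N)
  nsteps <- round(T / cfg$dt_int)
  ntrans <- round(transient / cfg$dt_int)
  ortho_steps <- max(1L, round(t_ortho / cfg$dt_int))
  res <- cpp_lyapunov(ic, csc$p, csc$i, csc$x, cfg$eta, cfg$eps, cfg$b,
                      cfg$d, cfg$dt_int, nsteps, ntrans, as.integer(m),
                      ortho_steps, input$seed, round(input$t0 / cfg$dt_int),
                      seed_stream(cfg$seeds$ic, "lyapunov-frame"),
                      variant_code(cfg), cfg$dt_bin)
  lam <- sort(res$lambda, decreasing = TRUE)
  structure(
    list(exponents = lam, m = as.integer(m), N = N,
         trace = res$trace, t_accum = res$t_accum,
         t_ortho = t_ortho, config_hash = config_hash(cfg),
         input_seed = input$seed),
    class = "lyapunov_spectrum"
  )
}

#' @export
print.lyapunov_spectrum <- function(x, ...) {
  npos <- sum(x$exponents > 0)
  cat(sprintf(
    "Lyapunov spectrum: %d of %d exponents (N = %d), %d positive, lambda_1 = %.4f nats/tu\n",
    x$m, x$N, x$N, npos, x$exponents[1]
  ))
  invisible(x)
}

#' Kolmogorov-Sinai upper bound on network noise entropy
#'
#' `H_KS = (1 / ln 2) * sum of positive Lyapunov exponents`, in bits per
#' time-unit. By the entropy formula for random dynamical systems this
#' bounds the network spike-pattern noise-entropy rate from above. The
#' spectrum must extend into negative exponents, otherwise the sum of
#' positive exponents (and hence the bound) would be truncated.
#'
#' @param spectrum A `"lyapunov_spectrum"`, or a plain numeric vector of
#'   exponents in nats/tu.
#' @return The bound in bits per time-unit (0 if no exponent is positive).
#' @examples
#' ks_bound(c(0.2, 0.1, -0.3)) # 0.3 / ln 2
#' @export
ks_bound <- function(spectrum) {
  lam <- if (inherits(spectrum, "lyapunov_spectrum")) spectrum$exponents else
    as.numeric(spectrum)
  if (min(lam) >= 0 && any(lam > 0)) {
    stop(paste("smallest computed exponent is non-negative;",
               "increase m so the positive part of the spectrum is certified"),
         call. = FALSE)
  }
  sum(lam[lam > 0]) / log(2)
}

#' Firing-rate level curve in the input-statistics plane
#'
#' Sweeps a grid over the input mean `eta` and fluctuation amplitude `eps`,
#' measures the excitatory mean firing rate at each grid point, extracts
#' the contour at a target rate by interpolation of the rate surface, and
#' (optionally) computes the Lyapunov spectrum and Kolmogorov-Sinai bound
#' at points along the contour. The contour is parameterized with `eta`
#' increasing, i.e. from the fluctuation-driven (`eta < 0`) towards the
#' mean-driven (`eta > 0`, small `eps`) regime.
#'
#' @param cfg Template [network_config()]; `eta`/`eps` are overridden.
#' @param etas,epss Grid coordinates (increasing).
#' @param target_rate Firing rate defining the level curve (spikes/tu).
#' @param T_rate Simulation length per grid point for the rate surface.
#' @param n_points Number of contour points at which spectra are evaluated
#'   (0 to skip the spectra).
#' @param T_lyap,m Arguments passed to [lyapunov_spectrum()] at each
#'   evaluated contour point.
#' @return List with the rate surface (`etas`, `epss`, `rate` matrix), the
#'   interpolated contour (data frame `eta`, `eps`), and per-point results
#'   (`eta`, `eps`, `H_KS`, spectra) when requested.
#' @export
level_curve_sweep <- function(cfg, etas, epss, target_rate = 0.82,
                              T_rate = 200, n_points = 0,
                              T_lyap = 300, m = ceiling(0.4 * cfg$N)) {
  A <- build_coupling_matrix(cfg)
  rate <- matrix(NA_real_, length(etas), length(epss))
  for (a in seq_along(etas)) {
    for (e in seq_along(epss)) {
      cfg_ae <- cfg
      cfg_ae$eta <- etas[a]
      cfg_ae$eps <- epss[e]
      inp <- generate_input(cfg_ae, 0, T_rate)
      ics <- sample_initial_ensemble(cfg_ae, A, M = 1)
      r <- run_trials(cfg_ae, A, inp, ics, T = T_rate)
      rate[a, e] <- mean_firing_rate(r, "exc")
    }
  }
  if (target_rate < min(rate) || target_rate > max(rate)) {
    stop("target rate lies outside the simulated rate surface", call. = FALSE)
  }
  cl <- grDevices::contourLines(etas, epss, rate, levels = target_rate)
  if (length(cl) == 0) stop("no contour found at the target rate", call. = FALSE)
  cl <- cl[[which.max(vapply(cl, function(z) length(z$x), numeric(1)))]]
  contour <- data.frame(eta = cl$x, eps = cl$y)
  contour <- contour[order(contour$eta), ]
  out <- list(etas = etas, epss = epss, rate = rate, contour = contour,
              target_rate = target_rate)
  if (n_points > 0) {
    idx <- unique(round(seq(1, nrow(contour), length.out = n_points)))
    pts <- contour[idx, ]
    specs <- vector("list", nrow(pts))
    hks <- numeric(nrow(pts))
    for (q in seq_len(nrow(pts))) {
      cfg_q <- cfg
      cfg_q$eta <- pts$eta[q]
      cfg_q$eps <- max(0, pts$eps[q])
      specs[[q]] <- lyapunov_spectrum(cfg_q, A, T = T_lyap, m = m)
      hks[q] <- ks_bound(specs[[q]])
    }
    out$points <- cbind(pts, H_KS = hks)
    out$spectra <- specs
  }
  out
}
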