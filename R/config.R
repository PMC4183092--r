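#' Network configuration
#'
#' Collects every model parameter of the balanced theta-neuron network: the
#' size and sparseness of the coupling, the statistics of the quenched input
#' drive, the synaptic pulse constants, and the numerical resolutions used
#' for integration and spike binning.
#'
#' @param N Number of neurons.
#' @param kappa Mean in-degree per presynaptic population: each neuron
#'   receives on average `kappa` excitatory and `kappa` inhibitory inputs.
#' @param frac_inhib Fraction of inhibitory cells (default 0.2).
#' @param eta Input mean (dimensionless drift). Negative values put single
#'   cells in the excitable regime; positive values in the oscillatory,
#'   mean-driven regime.
#' @param eps Input fluctuation amplitude, `eps >= 0`.
#' @param b Synaptic pulse half-width in phase units (default 1/20).
#' @param d Pulse amplitude constant (default 35/32); with the unit-integral
#'   normalization used here the pulse integrates to exactly 1.
#' @param dt_int Integrator step in time-units (default 0.002).
#' @param dt_bin Spike binning width in time-units (default 0.05).
#' @param model_variant `"normal"` (smooth model) or `"piecewise"` (the
#'   variant whose velocity is exactly 2 and input-insensitive on the spiking
#'   interval `[1 - 2*dt_bin, 1)`, so the partition spiking rule is exact).
#' @param transient Initial stretch of each shared-input run, in time-units,
#'   flagged as transient and excluded from analysis windows (default 100).
#' @param burn Burn-in duration, in time-units, used when sampling initial
#'   conditions from the stationary ensemble (default 50).
#' @param seeds Named list of integer seeds with elements `coupling`,
#'   `input` and `ic`; missing entries are derived from `master_seed`.
#' @param master_seed Integer master seed used to derive any unspecified
#'   named seed via a deterministic stream-splitting scheme.
#'
#' @return An object of class `"theta_config"` (a validated list).
#' @examples
#' cfg <- network_config(N = 100, kappa = 5, master_seed = 1)
#' cfg$seeds$coupling
#' @export
network_config <- function(N, kappa = 20, frac_inhib = 0.2, eta = -0.5,
                           eps = 0.5, b = 1 / 20, d = 35 / 32,
                           dt_int = 0.002, dt_bin = 0.05,
                           model_variant = c("normal", "piecewise"),
                           transient = 100, burn = 50,
                           seeds = list(), master_seed = 1L) {
  model_variant <- match.arg(model_variant)
  stopifnot(is.numeric(N), length(N) == 1, N >= 1)
  cfg <- list(
    N = as.integer(N), kappa = kappa, frac_inhib = frac_inhib,
    eta = eta, eps = eps, b = b, d = d, dt_int = dt_int, dt_bin = dt_bin,
    model_variant = model_variant, transient = transient, burn = burn,
    seeds = list(
      coupling = if (!is.null(seeds$coupling)) as.integer(seeds$coupling) else
        seed_stream(master_seed, "coupling"),
      input = if (!is.null(seeds$input)) as.integer(seeds$input) else
        seed_stream(master_seed, "input"),
      ic = if (!is.null(seeds$ic)) as.integer(seeds$ic) else
        seed_stream(master_seed, "ic")
    ),
    master_seed = as.integer(master_seed)
  )
  class(cfg) <- "theta_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  with(cfg, {
    if (!(dt_int > 0 && dt_int <= dt_bin / 10)) {
      stop("invalid config: need 0 < dt_int <= dt_bin/10", call. = FALSE)
    }
    if (!(b > 0 && b < 0.5)) stop("invalid config: need 0 < b < 1/2", call. = FALSE)
    if (frac_inhib < 0 || frac_inhib > 1) {
      stop("invalid config: frac_inhib must lie in [0, 1]", call. = FALSE)
    }
    if (eps < 0) stop("invalid config: eps must be >= 0", call. = FALSE)
    if (kappa < 0) stop("invalid config: kappa must be >= 0", call. = FALSE)
    if (kappa > N * min(frac_inhib, 1 - frac_inhib)) {
      stop("invalid config: kappa exceeds N * min(frac_inhib, 1 - frac_inhib)",
           call. = FALSE)
    }
    if (transient < 0 || burn < 0) {
      stop("invalid config: transient and burn must be >= 0", call. = FALSE)
    }
  })
  invisible(cfg)
}

#' Derive a child seed from a master seed
#'
#' Deterministic stream splitting: every source of randomness in the package
#' (coupling wiring, quenched input, initial conditions, per-trial burn-in
#' inputs, per-trial surrogate draws) obtains its own integer seed from a
#' master seed, a purpose label, and an optional index. Growing a trial
#' ensemble therefore never perturbs earlier trials.
#'
#' @param master Integer master seed.
#' @param purpose Character label of the stream.
#' @param index Optional integer index within the stream (e.g. trial number).
#' @return A positive integer seed below 2^31 - 1.
#' @export
seed_stream <- function(master, purpose, index = 0) {
  p <- 2147483647 # 2^31 - 1
  h <- 0
  for (ch in utf8ToInt(purpose)) h <- (h * 69069 + ch) %% p
  s <- (as.numeric(master) %% p) * 69069 %% p
  s <- (s + h * 40503 + as.numeric(index) * 10007) %% p
  as.integer(s + 1)
}

# evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @export
print.theta_config <- function(x, ...) {
  cat(sprintf(
    "theta-neuron network config: N = %d, kappa = %g, %.0f%% inhibitory\n",
    x$N, x$kappa, 100 * x$frac_inhib
  ))
  cat(sprintf("  input: eta = %g, eps = %g (quenched white noise)\n",
              x$eta, x$eps))
  cat(sprintf("  pulse: b = %g, d = %g; dt_int = %g tu, dt_bin = %g tu\n",
              x$b, x$d, x$dt_int, x$dt_bin))
  cat(sprintf("  variant: %s; transient %g tu, burn %g tu\n",
              x$model_variant, x$transient, x$burn))
  invisible(x)
}

# short deterministic fingerprint of the scientific parameters, used to tag
# analysis products with the run that produced them
config_hash <- function(cfg) {
  s <- paste(cfg$N, cfg$kappa, cfg$frac_inhib, cfg$eta, cfg$eps, cfg$b, cfg$d,
             cfg$dt_int, cfg$dt_bin, cfg$model_variant, cfg$transient,
             cfg$burn, cfg$seeds$coupling, cfg$seeds$input, cfg$seeds$ic,
             sep = "|")
  p <- 2147483647
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% p
  sprintf("%08x", h)
}
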