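#' Generate a quenched input realization
#'
#' The stimulus is a collection of `N` independent signals
#' `I_i(t) = eta + eps * dW_i/dt`, where the `dW_i` are scaled increments of
#' independent Wiener processes. One realization is *quenched*: it is frozen
#' and shared bit-identically by every trial, so that cross-trial
#' variability reflects initial conditions only. Increments are produced by
#' a counter-based generator indexed by `(seed, neuron, step)`, which makes
#' slicing a sub-interval return exactly the increments of the full
#' realization restricted to that interval.
#'
#' @param cfg A [network_config()].
#' @param t0,t1 Covered time interval in time-units (`t1 > t0`).
#' @param seed Integer seed; defaults to `cfg$seeds$input`.
#' @return An `"input_realization"` object (lazy: increments are
#'   materialized on demand with [input_increments()]).
#' @export
generate_input <- function(cfg, t0 = 0, t1, seed = cfg$seeds$input) {
  stopifnot(t1 > t0)
  structure(
    list(eta = cfg$eta, eps = cfg$eps, t0 = t0, t1 = t1,
         dt = cfg$dt_int, seed = as.integer(seed)),
    class = "input_realization"
  )
}

#' Materialize Wiener increments of an input realization
#'
#' @param input An `"input_realization"`.
#' @param neurons Integer neuron indices (1-based).
#' @param t0,t1 Sub-interval to materialize; defaults to the full covered
#'   interval. Must lie within `[input$t0, input$t1]`.
#' @return A matrix with one row per integrator step and one column per
#'   requested neuron, holding the raw increments `dW` (standard deviation
#'   `sqrt(dt_int)` each).
#' @export
input_increments <- function(input, neurons, t0 = input$t0, t1 = input$t1) {
  stopifnot(inherits(input, "input_realization"),
            t0 >= input$t0 - 1e-9, t1 <= input$t1 + 1e-9, t1 > t0)
  k0 <- round(t0 / input$dt)
  nk <- round((t1 - t0) / input$dt)
  cpp_input_increments(input$seed, as.integer(neurons) - 1L, k0, nk, input$dt)
}

#' @export
print.input_realization <- function(x, ...) {
  cat(sprintf(
    "quenched input realization: eta = %g, eps = %g, t in [%g, %g] tu, seed %d\n",
    x$eta, x$eps, x$t0, x$t1, x$seed
  ))
  invisible(x)
}

#' Sample an ensemble of initial conditions
#'
#' Seed states are drawn uniformly over the N-torus and, unless
#' `burn = 0`, each is evolved for a burn period (default `cfg$burn`, 50
#' time-units) under an *independent* input realization. The endpoints
#' approximate draws from the stationary measure of the driven network and
#' are the trial initial conditions.
#'
#' @param cfg A [network_config()].
#' @param A A `"coupling_matrix"` (or `NULL` for an uncoupled ensemble).
#' @param M Number of trials.
#' @param burn Burn duration in time-units; defaults to `cfg$burn`.
#' @param seed Seed for the uniform draws and the per-trial burn inputs;
#'   defaults to `cfg$seeds$ic`.
#' @return An `"initial_ensemble"`: `states` is an `N x M` matrix of phases.
#' @export
sample_initial_ensemble <- function(cfg, A, M, burn = cfg$burn,
                                    seed = cfg$seeds$ic) {
  stopifnot(M >= 1)
  N <- cfg$N
  states <- with_local_seed(seed, matrix(runif(N * M), N, M))
  provenance <- "uniform"
  if (burn > 0) {
    csc <- coupling_csc(A, N)
    nsteps <- round(burn / cfg$dt_int)
    trial_seeds <- vapply(seq_len(M), function(m) {
      seed_stream(seed, "burn-input", m)
    }, integer(1))
    res <- cpp_run_trials(states, csc$p, csc$i, csc$x, cfg$eta, cfg$eps,
                          cfg$b, cfg$d, cfg$dt_int, nsteps, 0,
                          0, 0, trial_seeds,
                          rep(FALSE, N), FALSE, 1L,
                          variant_code(cfg), cfg$dt_bin)
    states <- res$theta_final
    provenance <- "burned"
  }
  structure(
    list(states = states, provenance = provenance, burn = burn, seed = seed),
    class = "initial_ensemble"
  )
}

variant_code <- function(cfg) if (cfg$model_variant == "piecewise") 1L else 0L

# CSC pieces of the coupling matrix for the C++ core; A may be a
# coupling_matrix, any Matrix/base matrix, or NULL (no coupling)
coupling_csc <- function(A, N) {
  if (is.null(A)) {
    return(list(p = integer(N + 1), i = integer(0), x = numeric(0)))
  }
  Amat <- if (inherits(A, "coupling_matrix")) A$A else A
  Amat <- methods::as(methods::as(Amat, "CsparseMatrix"), "generalMatrix")
  stopifnot(nrow(Amat) == N, ncol(Amat) == N)
  list(p = Amat@p, i = Amat@i, x = Amat@x)
}

#' Integrate an ensemble of trials under one shared input
#'
#' Euler-Maruyama integration of the network at step `cfg$dt_int`, with the
#' Ito correction in the drift. All trials are driven by the *same* frozen
#' input realization; a spike is recorded when a phase crosses 1 from
#' below, with its time located by linear interpolation within the step.
#' The first `cfg$transient` time-units are flagged as transient and are
#' excluded by the analysis functions.
#'
#' @param cfg A [network_config()].
#' @param A A `"coupling_matrix"` or `NULL` (uncoupled).
#' @param input An `"input_realization"` covering `[0, T]`.
#' @param ics An `"initial_ensemble"` (or an `N x M` phase matrix).
#' @param T Duration in time-units.
#' @param record_cells Integer vector of neurons whose spikes are stored
#'   (default all). Restricting this bounds memory in large ensembles.
#' @param record_phases If `TRUE`, phases of all neurons are stored at spike-
#'   bin resolution (`cfg$dt_bin`); intended for small trial counts.
#' @return A `"spike_raster"`: spike table (`trial`, `neuron`, `time`),
#'   binning metadata, and optionally the phase store (array
#'   `N x n_bins x M` where column `l` holds phases at bin start
#'   `(l-1) * dt_bin`).
#' @examples
#' cfg <- network_config(N = 20, kappa = 2, transient = 5, burn = 2,
#'                       master_seed = 3)
#' A <- build_coupling_matrix(cfg)
#' inp <- generate_input(cfg, 0, 20)
#' ics <- sample_initial_ensemble(cfg, A, M = 2)
#' r <- run_trials(cfg, A, inp, ics, T = 20)
#' mean_firing_rate(r)
#' @export
run_trials <- function(cfg, A, input, ics, T, record_cells = NULL,
                       record_phases = FALSE) {
  validate_config(cfg)
  stopifnot(inherits(input, "input_realization"))
  if (input$t0 > 0 || input$t1 < T) {
    stop("input realization does not cover [0, T]", call. = FALSE)
  }
  states <- if (inherits(ics, "initial_ensemble")) ics$states else ics
  stopifnot(nrow(states) == cfg$N)
  N <- cfg$N
  M <- ncol(states)
  rec <- rep(FALSE, N)
  rec[if (is.null(record_cells)) seq_len(N) else as.integer(record_cells)] <- TRUE
  csc <- coupling_csc(A, N)
  nsteps <- round(T / cfg$dt_int)
  stride <- round(cfg$dt_bin / cfg$dt_int)
  run_chunk <- function(sub) {
    cpp_run_trials(sub, csc$p, csc$i, csc$x, cfg$eta, cfg$eps,
                   cfg$b, cfg$d, cfg$dt_int, nsteps, 0,
                   input$seed, round(input$t0 / cfg$dt_int),
                   integer(0), rec, record_phases, stride,
                   variant_code(cfg), cfg$dt_bin)
  }
  # large ensembles are integrated in chunks of trials so the state stays
  # cache-resident; the counter-based quenched input makes this exact
  chunk <- 64L
  if (M <= chunk || record_phases) {
    res <- run_chunk(states)
  } else {
    starts <- seq(1L, M, by = chunk)
    parts <- lapply(starts, function(s0) {
      run_chunk(states[, s0:min(s0 + chunk - 1L, M), drop = FALSE])
    })
    res <- list(
      trial = unlist(lapply(seq_along(parts), function(i) {
        parts[[i]]$trial + (starts[i] - 1L)
      })),
      neuron = unlist(lapply(parts, `[[`, "neuron")),
      time = unlist(lapply(parts, `[[`, "time")),
      theta_final = do.call(cbind, lapply(parts, `[[`, "theta_final"))
    )
  }
  pops <- if (inherits(A, "coupling_matrix")) A$populations else {
    n_exc <- ceiling((1 - cfg$frac_inhib) * N)
    rep(c("E", "I"), c(n_exc, N - n_exc))
  }
  structure(
    list(
      spikes = data.frame(trial = res$trial, neuron = res$neuron,
                          time = res$time),
      n_neurons = N, n_trials = M, duration = T,
      dt_bin = cfg$dt_bin, transient = cfg$transient,
      populations = pops, config_hash = config_hash(cfg),
      input_seed = input$seed,
      phases = if (record_phases) res$phases else NULL
    ),
    class = "spike_raster"
  )
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf(
    "spike raster: %d neurons, %d trial(s), %g tu (%g tu transient), %d spikes\n",
    x$n_neurons, x$n_trials, x$duration, x$transient, nrow(x$spikes)
  ))
  invisible(x)
}

#' Mean firing rate of a raster
#'
#' Total post-transient spike count divided by (number of selected neurons
#' x post-transient duration x trials), in spikes per time-unit.
#'
#' @param raster A `"spike_raster"`.
#' @param population `"all"`, `"exc"` or `"inh"`.
#' @param cells Optional explicit neuron subset (overrides `population`).
#' @return Firing rate in spikes/tu.
#' @export
mean_firing_rate <- function(raster, population = c("all", "exc", "inh"),
                             cells = NULL) {
  population <- match.arg(population)
  if (is.null(cells)) {
    cells <- switch(population,
      all = seq_len(raster$n_neurons),
      exc = which(raster$populations == "E"),
      inh = which(raster$populations == "I")
    )
  }
  sp <- raster$spikes
  keep <- sp$time >= raster$transient & sp$neuron %in% cells
  dur <- raster$duration - raster$transient
  if (nrow(sp) == 0 || !any(keep)) {
    warning("empty raster; rate is 0")
    return(0)
  }
  sum(keep) / (length(cells) * dur * raster$n_trials)
}
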