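#' Presynaptic cells of a neuron
#'
#' @param A A `"coupling_matrix"`.
#' @param cell Postsynaptic neuron index.
#' @return Integer vector of presynaptic neuron indices (nonzero entries of
#'   row `cell`).
#' @export
presynaptic_cells <- function(A, cell) {
  which(A$A[cell, ] != 0)
}

#' Build a surrogate specification for one cell's recurrent input
#'
#' Describes how to replace the true incoming spike trains of a target cell
#' by independent Poisson-type surrogates, keeping the cell's own quenched
#' input intact:
#' * `"homogeneous"`: independent Poisson trains whose rates match the mean
#'   firing rate of the corresponding upstream cells in the reference run;
#' * `"inhomogeneous"`: an independent Bernoulli draw in each spike bin with
#'   the time-dependent probability given by the normalized cross-trial
#'   spike count (PSTH) of the corresponding upstream network train.
#'
#' Surrogates are redrawn independently on every simulated trial.
#'
#' @param raster Reference `"spike_raster"` in which the upstream cells were
#'   recorded.
#' @param cell Target neuron index.
#' @param A The `"coupling_matrix"` of the reference network.
#' @param kind `"homogeneous"` or `"inhomogeneous"`.
#' @return A `"surrogate_spec"` holding the upstream cells, their synaptic
#'   weights onto the target, and either per-cell rates (spikes/tu) or a
#'   per-cell, per-bin probability profile spanning the full reference
#'   record.
#' @export
build_surrogate_spec <- function(raster, cell, A,
                                 kind = c("homogeneous", "inhomogeneous")) {
  kind <- match.arg(kind)
  upstream <- presynaptic_cells(A, cell)
  if (length(upstream) == 0) {
    stop("target cell has no presynaptic partners", call. = FALSE)
  }
  weights <- as.numeric(A$A[cell, upstream])
  dt <- raster$dt_bin
  if (kind == "homogeneous") {
    dur <- raster$duration - raster$transient
    rates <- vapply(upstream, function(j) {
      sum(raster$spikes$neuron == j & raster$spikes$time >= raster$transient) /
        (dur * raster$n_trials)
    }, numeric(1))
    profile <- NULL
  } else {
    # one upstream cell at a time keeps memory linear in the record length
    nb <- floor(raster$duration / dt + 1e-9)
    profile <- matrix(0, length(upstream), nb)
    for (k in seq_along(upstream)) {
      arr <- binarize(raster, cells = upstream[k],
                      window = c(0, raster$duration))
      profile[k, ] <- colMeans(matrix(arr, dim(arr)[1], nb))
    }
    rates <- NULL
  }
  structure(
    list(kind = kind, cell = cell, upstream = upstream, weights = weights,
         rates = rates, profile = profile, dt = dt,
         duration = raster$duration),
    class = "surrogate_spec"
  )
}

#' @export
print.surrogate_spec <- function(x, ...) {
  cat(sprintf("%s surrogate spec for cell %d: %d upstream trains\n",
              x$kind, x$cell, length(x$upstream)))
  invisible(x)
}

#' Draw one trial's surrogate presynaptic spike trains
#'
#' @param spec A `"surrogate_spec"`.
#' @param T Duration to cover in time-units.
#' @param seed Integer seed for this trial's draw.
#' @return List with vectors `time` and `weight` (synaptic weight of the
#'   train each spike belongs to), merged over upstream cells.
#' @export
draw_surrogate_trains <- function(spec, T = spec$duration, seed) {
  with_local_seed(seed, {
    times <- list()
    wts <- list()
    if (spec$kind == "homogeneous") {
      for (k in seq_along(spec$upstream)) {
        n <- rpois(1, spec$rates[k] * T)
        if (n > 0) {
          times[[k]] <- runif(n, 0, T)
          wts[[k]] <- rep(spec$weights[k], n)
        }
      }
    } else {
      nb <- min(ncol(spec$profile), floor(T / spec$dt))
      centers <- (seq_len(nb) - 0.5) * spec$dt
      for (k in seq_along(spec$upstream)) {
        hit <- runif(nb) < spec$profile[k, seq_len(nb)]
        if (any(hit)) {
          times[[k]] <- centers[hit]
          wts[[k]] <- rep(spec$weights[k], sum(hit))
        }
      }
    }
    time <- unlist(times, use.names = FALSE)
    weight <- unlist(wts, use.names = FALSE)
    if (is.null(time)) {
      time <- numeric(0)
      weight <- numeric(0)
    }
    ord <- order(time)
    list(time = time[ord], weight = weight[ord])
  })
}

# per-step synaptic drive from a list of presynaptic spikes: each spike of
# weight w contributes w * p(t - s), p the constant-velocity pulse replay
# p(tau) = g(2*tau - b) on [0, b]
pulse_drive <- function(trains, cfg, nsteps, t0 = 0) {
  cpp_pulse_drive(trains$time, trains$weight, cfg$b, cfg$d, cfg$dt_int,
                  nsteps, t0)
}

#' Simulate one cell in isolation with surrogate or replayed input
#'
#' Integrates the single-cell dynamics with the cell's own quenched input
#' `I_i` kept intact (identical across trials) while its recurrent input is
#' replaced by surrogate presynaptic trains, redrawn independently each
#' trial, delivered as stereotyped synaptic pulses: because a spiking
#' presynaptic phase traverses the pulse support at speed approximately 2,
#' each spike at time `s` contributes `a_ij * g(2*(t - s) - b)` for
#' `t - s` in `[0, b]`.
#'
#' @param cfg A [network_config()] (supplies `eta`, `eps`, constants, and
#'   the transient convention).
#' @param cell Neuron index (selects the quenched input stream `I_i`).
#' @param input The `"input_realization"` of the reference run (so `I_i` is
#'   the embedded cell's input).
#' @param spec A `"surrogate_spec"`, or a fixed train list
#'   `list(time, weight)` replayed identically on every trial.
#' @param trials Number of trials.
#' @param T Duration in time-units.
#' @param seed Master seed for per-trial initial conditions and surrogate
#'   redraws.
#' @return A `"spike_raster"` with one neuron (labelled 1).
#' @export
simulate_isolated_cell <- function(cfg, cell, input, spec, trials, T,
                                   seed = cfg$seeds$ic) {
  stopifnot(inherits(input, "input_realization"))
  nsteps <- round(T / cfg$dt_int)
  noise <- input_increments(input, cell, 0, T)[, 1]
  fixed_trains <- !inherits(spec, "surrogate_spec")
  if (fixed_trains) drive <- pulse_drive(spec, cfg, nsteps)
  ics <- with_local_seed(seed_stream(seed, "isolated-ic"), runif(trials))
  sp_trial <- list()
  sp_time <- list()
  for (m in seq_len(trials)) {
    if (!fixed_trains) {
      tr <- draw_surrogate_trains(spec, T, seed_stream(seed, "surrogate", m))
      drive <- pulse_drive(tr, cfg, nsteps)
    }
    res <- cpp_run_cell(ics[m], cfg$eta, cfg$eps, cfg$b, cfg$d, cfg$dt_int,
                        nsteps, 0, noise, drive, variant_code(cfg),
                        cfg$dt_bin)
    if (length(res$time) > 0) {
      sp_trial[[m]] <- rep(m, length(res$time))
      sp_time[[m]] <- res$time
    }
  }
  tt <- unlist(sp_time, use.names = FALSE)
  if (is.null(tt)) tt <- numeric(0)
  tr <- unlist(sp_trial, use.names = FALSE)
  if (is.null(tr)) tr <- integer(0)
  structure(
    list(
      spikes = data.frame(trial = tr, neuron = rep(1L, length(tt)), time = tt),
      n_neurons = 1L, n_trials = trials, duration = T,
      dt_bin = cfg$dt_bin, transient = cfg$transient,
      populations = "E", config_hash = config_hash(cfg),
      input_seed = input$seed, phases = NULL
    ),
    class = "spike_raster"
  )
}
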