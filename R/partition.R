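#' State-space partition linking phases to spike words
#'
#' Per neuron, the unit circle splits into `gamma0 = [0, 1 - 2*dt)` and
#' `gamma1 = [1 - 2*dt, 1)`: because the phase velocity at the spiking
#' phase is 2 and the phase-response curve vanishes there, a neuron spikes
#' within the next `dt`-bin (approximately, exactly for the piecewise
#' variant) iff its phase at the bin start lies in `gamma1`.
#'
#' @param dt_bin Spike bin width in time-units.
#' @return A `"partition_spec"` with the interval boundaries.
#' @export
partition_spec <- function(dt_bin) {
  stopifnot(dt_bin > 0, 2 * dt_bin < 1)
  structure(
    list(dt_bin = dt_bin, gamma0 = c(0, 1 - 2 * dt_bin),
         gamma1 = c(1 - 2 * dt_bin, 1)),
    class = "partition_spec"
  )
}

#' Spiking-assumption violation rate
#'
#' Checks the partition-based spiking rule against a simulated run whose
#' phases were stored at bin resolution ([run_trials()] with
#' `record_phases = TRUE`): the fraction of recorded spikes whose cell's
#' phase at the enclosing bin's start was *not* in `gamma1` (violations),
#' and the converse miss rate (phase in `gamma1` but no spike in the bin).
#' Only post-transient bins are evaluated.
#'
#' @param raster A `"spike_raster"` carrying a phase store.
#' @param dt_bin Bin width; defaults to the raster's. May be a coarser
#'   multiple of the stored resolution.
#' @return List with `violation_rate` and `miss_rate` (fractions),
#'   the counts behind them, and the partition used.
#' @export
violation_rate <- function(raster, dt_bin = raster$dt_bin) {
  stopifnot(inherits(raster, "spike_raster"), !is.null(raster$phases))
  store_dt <- raster$dt_bin
  step <- dt_bin / store_dt
  if (abs(step - round(step)) > 1e-9) {
    stop("dt_bin must be a multiple of the stored phase resolution",
         call. = FALSE)
  }
  step <- as.integer(round(step))
  part <- partition_spec(dt_bin)
  g1 <- part$gamma1[1]
  N <- raster$n_neurons
  M <- raster$n_trials
  nrec <- dim(raster$phases)[2]
  # evaluated bins: starts at l * dt_bin, l such that start >= transient and
  # the full bin fits in the record
  l_all <- 0:(floor(raster$duration / dt_bin) - 1)
  l_all <- l_all[l_all * dt_bin >= raster$transient - 1e-9 &
                   (l_all * dt_bin) / store_dt + 1 <= nrec]
  sp <- raster$spikes
  sp <- sp[sp$time >= min(l_all) * dt_bin &
             sp$time < (max(l_all) + 1) * dt_bin, , drop = FALSE]
  lbin <- floor(sp$time / dt_bin + 1e-12)
  ok <- lbin %in% l_all
  sp <- sp[ok, , drop = FALSE]
  lbin <- lbin[ok]
  # phase of the spiking cell at the bin start
  rec_idx <- lbin * step + 1L # column in the phase store
  ph <- raster$phases[cbind(sp$neuron, rec_idx, sp$trial)]
  n_spikes <- nrow(sp)
  n_viol <- sum(ph < g1)
  # converse: cells in gamma1 at a bin start with no spike in that bin
  in_g1 <- 0L
  missed <- 0L
  lpos <- match(lbin, l_all)
  for (m in seq_len(M)) {
    P <- raster$phases[, l_all * step + 1L, m, drop = FALSE]
    ing1_mask <- matrix(P >= g1, N, length(l_all))
    spiked <- matrix(FALSE, N, length(l_all))
    rows <- sp$trial == m
    if (any(rows)) spiked[cbind(sp$neuron[rows], lpos[rows])] <- TRUE
    in_g1 <- in_g1 + sum(ing1_mask)
    missed <- missed + sum(ing1_mask & !spiked)
  }
  list(violation_rate = if (n_spikes > 0) n_viol / n_spikes else 0,
       miss_rate = if (in_g1 > 0) missed / in_g1 else 0,
       n_spikes = n_spikes, n_violations = n_viol,
       n_gamma1 = in_g1, n_missed = missed, partition = part)
}

#' Compare normal and piecewise single-cell models on identical input
#'
#' Simulates one cell under both model variants with the same initial
#' condition, the same quenched input `I_i`, and the same recorded
#' presynaptic spike trains replayed as stereotyped coupling pulses, then
#' matches the two spike lists greedily (earliest-unmatched-first, nearest
#' neighbor within `match_window`) and summarizes the spike-time
#' discrepancies.
#'
#' @param cfg A [network_config()] (variant field is ignored; both are run).
#' @param cell Neuron index selecting the quenched input stream.
#' @param input An `"input_realization"` covering `[0, T]`.
#' @param trains Fixed presynaptic spike list `list(time, weight)`.
#' @param T Duration in time-units.
#' @param ic Shared initial phase (default 0.5).
#' @param match_window Maximal |time difference| for a match, in time-units
#'   (default one spike bin).
#' @return List with per-match `abs_diff`, summary `max`/`median`,
#'   unmatched counts and the two spike vectors.
#' @export
compare_models <- function(cfg, cell, input, trains, T, ic = 0.5,
                           match_window = cfg$dt_bin) {
  nsteps <- round(T / cfg$dt_int)
  noise <- input_increments(input, cell, 0, T)[, 1]
  drive <- pulse_drive(trains, cfg, nsteps)
  run1 <- cpp_run_cell(ic, cfg$eta, cfg$eps, cfg$b, cfg$d, cfg$dt_int,
                       nsteps, 0, noise, drive, 0L, cfg$dt_bin)
  run2 <- cpp_run_cell(ic, cfg$eta, cfg$eps, cfg$b, cfg$d, cfg$dt_int,
                       nsteps, 0, noise, drive, 1L, cfg$dt_bin)
  a <- run1$time
  b <- run2$time
  i <- 1L
  j <- 1L
  diffs <- numeric(0)
  un_a <- 0L
  un_b <- 0L
  while (i <= length(a) && j <= length(b)) {
    dd <- a[i] - b[j]
    if (abs(dd) <= match_window) {
      diffs <- c(diffs, abs(dd))
      i <- i + 1L
      j <- j + 1L
    } else if (dd > 0) {
      un_b <- un_b + 1L
      j <- j + 1L
    } else {
      un_a <- un_a + 1L
      i <- i + 1L
    }
  }
  un_a <- un_a + (length(a) - i + 1L)
  un_b <- un_b + (length(b) - j + 1L)
  if (length(a) > 0 && (un_a + un_b) > 0.05 * (length(a) + length(b))) {
    warning("more than 5% of spikes unmatched between model variants")
  }
  list(abs_diff = diffs,
       max = if (length(diffs) > 0) max(diffs) else NA_real_,
       median = if (length(diffs) > 0) median(diffs) else NA_real_,
       n_matched = length(diffs), unmatched_normal = un_a,
       unmatched_piecewise = un_b,
       spikes_normal = a, spikes_piecewise = b)
}
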