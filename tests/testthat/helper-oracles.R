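# shared oracles used across test files

# quadrature oracle for the uncoupled deterministic firing period:
# T = integral_0^1 dtheta / (F + eta * Z)
period_quadrature <- function(eta) {
  stats::integrate(function(th) {
    1 / ((1 + cos(2 * pi * th)) + eta * (1 - cos(2 * pi * th)))
  }, 0, 1, rel.tol = 1e-10)$value
}

# stable rest phase of the excitable uncoupled cell (F + eta*Z = 0, v' < 0)
rest_phase <- function(eta) {
  stopifnot(eta < 0)
  acos((1 + eta) / (eta - 1)) / (2 * pi)
}

# small standard network shared by several test files (built once per run)
tiny_net <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- network_config(N = 60, kappa = 6, master_seed = 101,
                            transient = 20, burn = 10)
      A <- build_coupling_matrix(cfg)
      inp <- generate_input(cfg, 0, 120)
      ics <- sample_initial_ensemble(cfg, A, M = 30)
      r <- run_trials(cfg, A, inp, ics, T = 120)
      cache <<- list(cfg = cfg, A = A, inp = inp, ics = ics, raster = r)
    }
    cache
  }
})

test_tempdir <- function() {
  td <- tempfile("thetanet-test-")
  dir.create(td)
  td
}
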