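test_that("quenched input is deterministic, sliceable, and has variance dt", {
  cfg <- network_config(N = 5, kappa = 0, master_seed = 77)
  inp <- generate_input(cfg, 0, 100)
  a <- input_increments(inp, 1:3, 0, 10)
  b <- input_increments(inp, 1:3, 0, 10)
  expect_identical(a, b)
  # slicing a sub-interval reproduces the same increments
  sl <- input_increments(inp, 1:3, 4, 8)
  k0 <- 4 / cfg$dt_int
  expect_identical(sl, a[(k0 + 1):(k0 + nrow(sl)), ])
  # chi-square oracle: sample variance of n Gaussian increments with
  # variance dt lies within 3 SE, SE = dt * sqrt(2/n)
  x <- input_increments(inp, 1, 0, 100)[, 1]
  n <- length(x)
  expect_equal(n, 5e4)
  expect_lt(abs(mean(x^2) - cfg$dt_int), 3 * cfg$dt_int * sqrt(2 / n))
})

test_that("eps = 0 trials equal the deterministic flow", {
  cfg <- network_config(N = 1, kappa = 0, frac_inhib = 0, eta = 0.25,
                        eps = 0, transient = 0, burn = 0, master_seed = 3)
  inp <- generate_input(cfg, 0, 10)
  r1 <- run_trials(cfg, NULL, inp, matrix(0.1, 1, 1), T = 10)
  inp2 <- generate_input(cfg, 0, 10, seed = 999) # different noise stream
  r2 <- run_trials(cfg, NULL, inp2, matrix(0.1, 1, 1), T = 10)
  expect_identical(r1$spikes$time, r2$spikes$time)
})

test_that("uncoupled deterministic period matches the quadrature oracle", {
  for (eta in c(0.25, 1)) {
    cfg <- network_config(N = 1, kappa = 0, frac_inhib = 0, eta = eta,
                          eps = 0, transient = 0, burn = 0, master_seed = 3)
    r <- run_trials(cfg, NULL, generate_input(cfg, 0, 40), matrix(0.5, 1, 1),
                    T = 40)
    per_sim <- mean(diff(r$spikes$time))
    per_th <- period_quadrature(eta)
    # closed form: period = 1/sqrt((1+eta)^2 - (1-eta)^2) = 1/(2 sqrt(eta))
    expect_equal(per_th, 1 / (2 * sqrt(eta)), tolerance = 1e-8)
    expect_equal(per_sim, per_th, tolerance = 2e-3)
  }
})

test_that("excitable uncoupled cell at rest stays silent", {
  cfg <- network_config(N = 1, kappa = 0, frac_inhib = 0, eta = -0.5,
                        eps = 0, transient = 0, burn = 0, master_seed = 3)
  th0 <- matrix(rest_phase(-0.5), 1, 1)
  r <- run_trials(cfg, NULL, generate_input(cfg, 0, 50), th0, T = 50)
  expect_equal(nrow(r$spikes), 0)
})

test_that("rerunning with identical seeds reproduces the raster bit-identically", {
  net <- tiny_net()
  r2 <- run_trials(net$cfg, net$A, net$inp, net$ics, T = 120)
  expect_identical(net$raster$spikes, r2$spikes)
  # and the whole pipeline from config alone
  ex1 <- run_experiment(list(cfg = net$cfg, trials = 3, duration = 40))
  ex2 <- run_experiment(list(cfg = net$cfg, trials = 3, duration = 40))
  expect_identical(ex1$raster$spikes, ex2$raster$spikes)
})

test_that("driven single cells are reliable: distinct ICs converge on one input", {
  cfg <- network_config(N = 1, kappa = 0, frac_inhib = 0, eta = -0.5,
                        eps = 0.5, transient = 0, burn = 0, master_seed = 21)
  inp <- generate_input(cfg, 0, 60)
  r <- run_trials(cfg, NULL, inp, matrix(c(0.1, 0.6), 1, 2), T = 60,
                  record_phases = TRUE)
  nrec <- dim(r$phases)[2]
  d_end <- abs(r$phases[1, nrec, 1] - r$phases[1, nrec, 2])
  d_end <- min(d_end, 1 - d_end)
  expect_lt(d_end, 1e-6)
})

test_that("spike times are strictly increasing per trial and neuron", {
  net <- tiny_net()
  sp <- net$raster$spikes
  sp <- sp[order(sp$trial, sp$neuron, sp$time), ]
  key <- paste(sp$trial, sp$neuron)
  dts <- diff(sp$time)
  same <- key[-1] == key[-length(key)]
  expect_true(all(dts[same] > net$cfg$dt_int))
})

test_that("mean firing rate is plain spike-count arithmetic", {
  r <- make_fixture("poisson_trains", list(rates = 0.8, T = 10), seed = 4)
  r$spikes <- data.frame(trial = 1L, neuron = 1L,
                         time = seq(0.5, 9.5, length.out = 8))
  expect_equal(mean_firing_rate(r), 0.8)
  # empty raster warns and returns 0
  r$spikes <- r$spikes[0, ]
  expect_warning(expect_equal(mean_firing_rate(r), 0))
})

test_that("Poisson fixture rate is recovered within 3 standard errors", {
  T <- 400
  rate <- 0.8
  r <- make_fixture("poisson_trains", list(rates = rate, T = T, trials = 5),
                    seed = 11)
  est <- mean_firing_rate(r)
  se <- sqrt(rate / (5 * T))
  expect_lt(abs(est - rate), 3 * se)
})

test_that("halving the integration step changes the network rate by < 1.5%", {
  rates <- vapply(c(0.002, 0.001), function(dtv) {
    cfg <- network_config(N = 200, kappa = 20, dt_int = dtv,
                          master_seed = 42, transient = 50, burn = 20)
    A <- build_coupling_matrix(cfg)
    ics <- sample_initial_ensemble(cfg, A, M = 1)
    r <- run_trials(cfg, A, generate_input(cfg, 0, 450), ics, T = 450)
    mean_firing_rate(r, "exc")
  }, numeric(1))
  expect_lt(abs(rates[1] - rates[2]) / rates[2], 0.015)
})

test_that("the compiled integrator matches a pure-R reference in lockstep", {
  set.seed(17)
  N <- 20
  cfg <- network_config(N = N, kappa = 4, eta = -0.5, eps = 0.5,
                        transient = 0, burn = 0, master_seed = 90)
  A <- build_coupling_matrix(cfg)
  Ad <- as.matrix(A$A)
  Tend <- 1
  inp <- generate_input(cfg, 0, Tend)
  th0 <- matrix(runif(N), N, 1)
  r <- run_trials(cfg, A, inp, th0, T = Tend, record_phases = TRUE)
  dW <- input_increments(inp, 1:N, 0, Tend)
  # independent Euler-Maruyama step in R, emulating the integrator's
  # piecewise-linear trig interpolation so round-off is the only difference
  TAB <- 2048
  ctab <- cos(2 * pi * (0:(TAB + 1)) / TAB)
  stab <- sin(2 * pi * (0:(TAB + 1)) / TAB)
  dt <- cfg$dt_int
  ito <- cfg$eps^2 / 2
  th <- th0[, 1]
  worst <- 0
  for (k in seq_len(nrow(dW))) {
    x <- ifelse(th >= 0.5, th - 1, th)
    g <- coupling_pulse(x, cfg$b, cfg$d) * as.numeric(abs(x) != cfg$b)
    coup <- as.numeric(Ad %*% g)
    xx <- th * TAB
    ki <- floor(xx)
    f <- xx - ki
    cc <- ctab[ki + 1] + (ctab[ki + 2] - ctab[ki + 1]) * f
    ss <- stab[ki + 1] + (stab[ki + 2] - stab[ki + 1]) * f
    dth <- ((1 + cc) + (1 - cc) * (coup + cfg$eta + ito * 2 * pi * ss)) * dt +
      (1 - cc) * cfg$eps * dW[k, ]
    tn <- th + dth
    tn[tn >= 1] <- tn[tn >= 1] - 1
    tn[tn < 0] <- tn[tn < 0] + 1
    th <- tn
    if (k %% 25 == 0) {
      phC <- r$phases[, k / 25 + 1, 1]
      worst <- max(worst, max(pmin(abs(th - phC), 1 - abs(th - phC))))
    }
  }
  expect_lt(worst, 1e-7)
})
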