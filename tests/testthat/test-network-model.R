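test_that("config validation rejects inconsistent parameters", {
  expect_s3_class(network_config(N = 100, kappa = 10), "theta_config")
  expect_error(network_config(N = 100, kappa = 10, dt_int = 0.01),
               "dt_int")
  expect_error(network_config(N = 100, kappa = 10, b = 0.6), "b")
  expect_error(network_config(N = 100, kappa = 30), "kappa")
  expect_error(network_config(N = 100, kappa = 10, eps = -1), "eps")
})

test_that("seed streams are deterministic and distinct", {
  expect_identical(seed_stream(42, "input"), seed_stream(42, "input"))
  expect_false(seed_stream(42, "input") == seed_stream(42, "coupling"))
  expect_false(seed_stream(42, "burn", 1) == seed_stream(42, "burn", 2))
})

test_that("coupling matrix has balanced-state structure", {
  cfg <- network_config(N = 100, kappa = 5, master_seed = 7)
  cm <- build_coupling_matrix(cfg)
  A <- as.matrix(cm$A)
  n_exc <- sum(cm$populations == "E")
  expect_equal(n_exc, 80)
  # Dale-type sign constraint per presynaptic column
  for (j in seq_len(100)) {
    col <- A[, j]
    if (cm$populations[j] == "E") expect_true(all(col >= 0))
    else expect_true(all(col <= 0))
  }
  expect_true(all(diag(A) == 0))
  # every realized weight has magnitude 4/kappa (0.2 printed at kappa = 20)
  expect_true(all(abs(A[A != 0]) == 4 / cfg$kappa))
  cfg20 <- network_config(N = 500, kappa = 20, master_seed = 7)
  cm20 <- build_coupling_matrix(cfg20)
  expect_equal(unique(abs(cm20$A@x)), 0.2)
})

test_that("mean in-degree per population matches the edge-count oracle", {
  cfg <- network_config(N = 100, kappa = 5, master_seed = 123)
  cm <- build_coupling_matrix(cfg)
  A <- as.matrix(cm$A)
  for (p in c("E", "I")) {
    cols <- cm$populations == p
    indeg <- rowSums(A[, cols, drop = FALSE] != 0)
    n_p <- sum(cols)
    pr <- cfg$kappa / n_p
    # rows have ~Binomial(n_p - eps, kappa/n_p) in-degree; 3 SE of the mean
    se <- sqrt(n_p * pr * (1 - pr) / length(indeg))
    expect_lt(abs(mean(indeg) - cfg$kappa), 3 * se + cfg$kappa / n_p)
  }
})

test_that("kappa = 0 gives an empty graph and excess kappa errors", {
  cfg <- network_config(N = 50, kappa = 0, master_seed = 1)
  expect_equal(length(build_coupling_matrix(cfg)$A@x), 0)
})

test_that("doubling N at fixed kappa preserves per-row summed excitatory weight", {
  w <- function(N) {
    cfg <- network_config(N = N, kappa = 10, master_seed = 5)
    cm <- build_coupling_matrix(cfg)
    exc <- cm$populations == "E"
    mean(Matrix::rowSums(cm$A[, exc, drop = FALSE]))
  }
  w1 <- w(200)
  w2 <- w(400)
  # both means estimate kappa * 4/kappa = 4; allow sampling spread
  expect_lt(abs(w1 - w2), 0.4)
  expect_lt(abs(w1 - 4), 0.4)
})

test_that("coupling pulse has compact support and half-unit integral", {
  b <- 1 / 20
  expect_equal(coupling_pulse(c(-b, b)), c(0, 0))
  expect_equal(coupling_pulse(0.3), 0)
  expect_gt(coupling_pulse(0), 0)
  q <- stats::integrate(coupling_pulse, -b, b, rel.tol = 1e-12)
  expect_equal(q$value, 0.5, tolerance = 1e-10)
  # C2 smoothness at the support edge: value and first two finite
  # differences vanish as x -> b
  h <- 1e-5
  expect_lt(coupling_pulse(b - h), 1e-8)
  expect_lt(abs(coupling_pulse(b - h) - coupling_pulse(b - 2 * h)) / h, 1e-2)
})

test_that("vector field matches its closed-form anchor points", {
  cfg <- network_config(N = 3, kappa = 0, frac_inhib = 0, eta = -0.5,
                        eps = 0.5, master_seed = 1)
  # Z(0) = 0 kills every input term: derivative is exactly F(0) = 2
  v0 <- vector_field(c(0, 0.25, 0.5), drive = 7.3,
                     A = matrix(0, 3, 3), cfg = cfg)
  expect_equal(v0[1], 2)
  # theta = 1/2: F = 0, Z = 2; with eps = 0 and drive = eta the
  # derivative is 2 * eta
  cfg0 <- network_config(N = 1, kappa = 0, frac_inhib = 0, eta = -0.5,
                         eps = 0, master_seed = 1)
  expect_equal(vector_field(0.5, drive = cfg0$eta, A = matrix(0, 1, 1),
                            cfg = cfg0), 2 * cfg0$eta)
  # 1-periodicity
  th <- c(0.12, 0.48, 0.93)
  expect_equal(vector_field(th, 0.3, matrix(0, 3, 3), cfg),
               vector_field(th + 1 - 1, 0.3, matrix(0, 3, 3), cfg))
})

test_that("piecewise variant is constant-speed and input-blind on the spiking interval", {
  cfg <- network_config(N = 2, kappa = 0, frac_inhib = 0, eta = -0.5,
                        eps = 0.5, model_variant = "piecewise",
                        master_seed = 1)
  th <- c(1 - cfg$dt_bin, 0.5) # first coordinate inside [1 - 2*dt_bin, 1)
  v1 <- vector_field(th, drive = 0, A = matrix(0, 2, 2), cfg = cfg)
  v2 <- vector_field(th, drive = 55, A = matrix(0, 2, 2), cfg = cfg)
  expect_equal(v1[1], 2)
  expect_equal(v2[1], 2)
  expect_false(v1[2] == v2[2])
})

test_that("analytic Jacobian agrees with finite differences", {
  cfg <- network_config(N = 20, kappa = 4, master_seed = 31)
  A <- build_coupling_matrix(cfg)
  set.seed(8)
  for (rep in 1:3) {
    th <- runif(20)
    dr <- rnorm(1)
    J <- vector_field_jacobian(th, dr, A, cfg)
    h <- 1e-7
    Jfd <- matrix(0, 20, 20)
    for (j in 1:20) {
      e <- rep(0, 20)
      e[j] <- h
      Jfd[, j] <- (vector_field(th + e, dr, A, cfg) -
                     vector_field(th - e, dr, A, cfg)) / (2 * h)
    }
    expect_lt(max(abs(J - Jfd)), 1e-5 * max(1, max(abs(J))))
  }
})
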