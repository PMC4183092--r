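test_that("binarize uses floor arithmetic and clips double spikes", {
  r <- make_fixture("poisson_trains", list(rates = 1, T = 1), seed = 1)
  r$spikes <- data.frame(trial = 1L, neuron = 1L, time = c(0.07, 0.12, 0.13))
  arr <- binarize(r, cells = 1, window = c(0, 0.25))
  expect_equal(dim(arr), c(1, 1, 5))
  expect_equal(as.integer(arr[1, 1, ]), c(0L, 1L, 1L, 0L, 0L))
  expect_equal(attr(arr, "clipped"), 1L) # 0.12 and 0.13 share bin 3
  r$spikes <- r$spikes[0, ]
  expect_true(all(binarize(r, cells = 1, window = c(0, 0.25)) == 0L))
})

test_that("plug-in entropy rate matches closed forms", {
  # all trials identical -> zero entropy
  expect_equal(noise_entropy_rate(c(10), dt = 0.05, L = 1), 0)
  # two equiprobable words, K = 1, L = 1: 1 bit per bin = 20 bits/tu
  expect_equal(noise_entropy_rate(c(5, 5), dt = 0.05, L = 1), 20)
  # word_distribution plumbing on a deterministic array
  arr <- array(0L, dim = c(4, 1, 4))
  arr[1:2, 1, 1] <- 1L
  attr(arr, "dt") <- 0.05
  attr(arr, "t0") <- 0
  wd <- word_distribution(arr, L = 2, start = 1)
  expect_equal(sum(wd$counts), 4)
  expect_equal(noise_entropy_rate(wd, dt = 0.05), 1 / (2 * 0.05))
})

test_that("iid Bernoulli fixture reproduces H2(p)/dt at several word lengths", {
  p <- 0.04
  dt <- 0.05
  fx <- make_fixture("bernoulli_iid",
                     list(p = p, trials = 2000, bins = 600, dt = dt), seed = 2)
  truth <- attr(fx, "ground_truth")$H
  expect_equal(truth, binary_entropy(p) / dt)
  for (L in c(1, 2, 4)) {
    est <- time_averaged_entropy(fx, L)$H
    # plug-in estimates are biased down; tolerate a few percent at 2000 trials
    expect_lt(abs(est - truth) / truth, 0.06)
    expect_lte(est, truth * 1.005)
  }
})

test_that("inhomogeneous Bernoulli fixture matches analytic window entropies", {
  set.seed(5)
  p <- rep(c(0.02, 0.1, 0.05, 0.15), 50)
  fx <- make_fixture("bernoulli_profile", list(p = p, trials = 3000), seed = 6)
  truthf <- attr(fx, "ground_truth")$H_of_L
  for (L in c(2, 4)) {
    expect_equal(time_averaged_entropy(fx, L)$H, truthf(L),
                 tolerance = 0.05)
  }
})

test_that("plug-in estimator bias is negative and shrinks with trials", {
  p <- 0.1
  dt <- 0.05
  truth <- binary_entropy(p) / dt
  est_at <- function(trials, seed) {
    fx <- make_fixture("bernoulli_iid",
                       list(p = p, trials = trials, bins = 300, dt = dt),
                       seed = seed)
    time_averaged_entropy(fx, 4)$H
  }
  small <- vapply(1:5, function(s) est_at(40, s), numeric(1))
  big <- vapply(1:5, function(s) est_at(400, 100 + s), numeric(1))
  expect_lt(mean(small), truth)
  expect_lt(abs(mean(big) - truth), abs(mean(small) - truth))
})

test_that("entropy rates never exceed the K/dt capacity bound", {
  fx <- make_fixture("bernoulli_iid",
                     list(p = 0.5, trials = 500, bins = 200, cells = 2),
                     seed = 9)
  for (L in c(1, 3)) {
    expect_lte(time_averaged_entropy(fx, L)$H, 2 / 0.05)
  }
})

test_that("joint entropy is subadditive on fixtures", {
  fx <- make_fixture("correlated_pair",
                     list(p = 0.1, rho = 0.4, trials = 1500, bins = 400),
                     seed = 3)
  for (L in c(1, 3)) {
    H1 <- time_averaged_entropy(fx, L, cells = 1)$H
    H2 <- time_averaged_entropy(fx, L, cells = 2)$H
    H12 <- time_averaged_entropy(fx, L)$H
    expect_lte(H12, H1 + H2 + 1e-9)
  }
})

test_that("extrapolation recovers flat and exactly extensive curves", {
  flat <- extrapolate_entropy(data.frame(L = 1:8, H = rep(2.5, 8)))
  expect_equal(flat$limit, 2.5)
  ab <- extrapolate_entropy(data.frame(L = 1:10, H = 1.7 + 3.1 / (1:10)))
  expect_equal(ab$limit, 1.7, tolerance = 1e-10)
  expect_error(extrapolate_entropy(data.frame(L = 1:8, H = 1:8)),
               "non-physical")
  expect_error(extrapolate_entropy(data.frame(L = 1:3, H = 3:1)), "at least 4")
})

test_that("extrapolated limit does not exceed the fitted segment", {
  curve <- data.frame(L = 1:12, H = 2 + 1 / (1:12) - c(rep(0, 9), 0.1, 0.3, 0.6))
  est <- extrapolate_entropy(curve)
  expect_lte(est$limit, min(curve$H[est$fit_L]) + 1e-9)
})

test_that("duplicated pair has delta equal to the single-cell rate", {
  p <- 0.08
  fx <- make_fixture("duplicated_pair",
                     list(p = p, trials = 1200, bins = 800), seed = 12)
  # exact identity at the level of curves: H2(L) = H1(L) for every L
  for (L in c(1, 4)) {
    expect_equal(time_averaged_entropy(fx, L)$H,
                 time_averaged_entropy(fx, L, cells = 1)$H)
  }
  r <- fixture_to_raster(fx)
  pd <- pairwise_delta(r, 1, 2, Lmax = 8)
  expect_equal(pd$delta, pd$H_i$limit, tolerance = 1e-9)
})

test_that("independent cells have delta near zero, converging with trials", {
  # truth is 0; the plug-in pair entropy is biased further down than the
  # marginals, so finite sampling leaves a positive residue that must
  # shrink as the trial count grows
  delta_at <- function(trials, seed) {
    fx <- make_fixture("bernoulli_iid",
                       list(p = 0.08, trials = trials, bins = 2000,
                            cells = 2), seed = seed)
    pairwise_delta(fixture_to_raster(fx), 1, 2, Lmax = 4)$delta
  }
  d_small <- delta_at(200, 13)
  d_big <- delta_at(2000, 14)
  expect_lt(abs(d_big), abs(d_small))
  expect_lt(abs(d_big), 0.5)
  # with *exact* distributions the additivity identity is algebraic:
  # joint word probabilities factorize, so H2 = H1 + H1 and delta = 0
  p <- 0.3
  one <- c(1 - p, p)
  pw1 <- as.vector(outer(one, one)) # L = 2 single-cell word probabilities
  pw2 <- as.vector(outer(pw1, pw1)) # independent pair, cell-major
  H1 <- noise_entropy_rate(pw1, dt = 0.05, L = 2)
  H2 <- noise_entropy_rate(pw2, dt = 0.05, L = 2)
  expect_equal(H2, 2 * H1, tolerance = 1e-12)
})

test_that("naive network bound is N times the sample mean with a 2 SE band", {
  nb <- naive_network_bound(1.0, 100)
  expect_equal(nb$value, 100)
  s1 <- c(1, 1.2, 0.8, 1.1, 0.9)
  m <- mean(s1)
  nb1 <- naive_network_bound(s1, 500)
  expect_equal(nb1$value, 500 * m)
  expect_equal(diff(nb1$band), 500 * 4 * sd(s1) / sqrt(5))
  # quartering the sample variance halves the band
  s2 <- m + (s1 - m) / 2
  nb2 <- naive_network_bound(s2, 500)
  expect_equal(diff(nb2$band), diff(nb1$band) / 2)
})

test_that("spike-list and array entropy paths agree exactly", {
  net <- tiny_net()
  curve_fast <- spike_entropy_curve(net$raster, cells = c(3, 9), Lmax = 6)
  arr <- binarize(net$raster, cells = c(3, 9))
  curve_arr <- entropy_curve(arr, Ls = 1:6)
  expect_equal(curve_fast$H, curve_arr$H, tolerance = 1e-12)
  expect_equal(curve_fast$windows, curve_arr$windows)
  one_fast <- spike_entropy_curve(net$raster, cells = 9, Lmax = 8)
  one_arr <- entropy_curve(binarize(net$raster, cells = 9), Ls = 1:8)
  expect_equal(one_fast$H, one_arr$H, tolerance = 1e-12)
})
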