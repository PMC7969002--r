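test_that("transition matrix follows the linear per-frame discretisation", {
  K3 <- ref_rates()
  # zero rates give the identity at any frame time
  expect_equal(build_transition_matrix(rate_spec(matrix(0, 3, 3)), 0.02),
               diag(3), ignore_attr = TRUE)
  P <- build_transition_matrix(K3, 0.02)
  expect_equal(unname(P["O", ]), c(0.9662, 0.0310, 0.0028), tolerance = 1e-12)
  expect_equal(rowSums(P), c(O = 1, PC = 1, C = 1), tolerance = 1e-12)
  # random admissible rate specs keep rows stochastic
  set.seed(11)
  for (i in 1:25) {
    K <- sample(2:5, 1)
    k <- matrix(rexp(K * K, 1 / 2), K, K); diag(k) <- 0
    dt <- 0.9 / max(rowSums(k))
    Pi <- build_transition_matrix(rate_spec(k), dt)
    expect_true(all(abs(rowSums(Pi) - 1) < 1e-12))
    expect_true(all(Pi >= 0))
    # rate recovery is the exact inverse of the discretisation
    ki <- Pi / dt; diag(ki) <- 0
    expect_equal(ki, k, ignore_attr = TRUE, tolerance = 1e-12)
  }
  # coarse frame times are rejected rather than silently clipped
  expect_error(build_transition_matrix(K3, 0.5), "too coarse")
})

test_that("stationary distribution matches linear-algebra and power-iteration oracles", {
  P <- build_transition_matrix(ref_rates(), 0.02)
  pi_qr <- stationary_distribution(P)
  expect_equal(unname(pi_qr), c(0.300, 0.533, 0.167), tolerance = 1e-2)
  # independent oracle: brute-force power iteration
  x <- c(1, 0, 0)
  for (i in 1:20000) x <- as.numeric(x %*% P)
  expect_equal(unname(pi_qr), x, tolerance = 1e-9)
  expect_equal(sum(pi_qr), 1, tolerance = 1e-12)
})

test_that("state paths respect degenerate inputs and converge to stationarity", {
  p0 <- simulate_state_path(diag(3), c(1, 0, 0), 100, 0.02)
  expect_equal(p0$states, rep(0L, 100))
  p1 <- simulate_state_path(diag(3), c(0, 0, 1), 1, 0.02)
  expect_equal(p1$states, 2L)
  P <- build_transition_matrix(ref_rates(), 0.02)
  pi_a <- stationary_distribution(P)
  set.seed(21)
  path <- simulate_state_path(P, pi_a, 1e6, 0.02)
  occ <- tabulate(path$states + 1L, 3) / 1e6
  se <- sqrt(pi_a * (1 - pi_a) / 1e6)
  # wide bound: consecutive frames are strongly correlated, so allow for the
  # effective sample size being ~ (1 - p_ii) * n
  expect_true(all(abs(occ - pi_a) < 30 * se))
})

test_that("empirical dwell durations agree with 1/sum(k_ij)", {
  P <- build_transition_matrix(ref_rates(), 0.02)
  set.seed(31)
  path <- simulate_state_path(P, stationary_distribution(P), 2e5, 0.02)
  d <- extract_dwells(structure(list(trace_id = "t", states = path$states,
                                     frame_time = 0.02), class = "state_path"))
  d <- d[!d$censored_start & !d$censored_end, ]
  exits <- rowSums(ref_rates()$k)
  for (s in 0:2) {
    ds <- d$seconds[d$state == s]
    expected <- 1 / exits[s + 1]
    expect_lt(abs(mean(ds) - expected), 3 * sd(ds) / sqrt(length(ds)))
  }
})

test_that("emission adds unbiased Gaussian noise of the requested SD", {
  path <- structure(list(states = rep(0L, 94000), frame_time = 0.02),
                    class = "true_path")
  set.seed(41)
  tiny <- emit_estar(path, emission_spec(c(0.2, 0.3), 1e-12))
  expect_equal(tiny$estar, rep(0.2, 94000), tolerance = 1e-9)
  set.seed(42)
  tr <- emit_estar(path, emission_spec(c(0.30, 0.42), 0.070))
  expect_equal(sd(tr$estar), 0.070, tolerance = 0.001 / 0.070)
  expect_lt(abs(mean(tr$estar) - 0.30), 3 * 0.070 / sqrt(94000))
})

test_that("binning averages blocks, drops remainders and shrinks noise by sqrt(f)", {
  expect_equal(bin_trace(c(1, 2, 3), 1), c(1, 2, 3))
  expect_equal(bin_trace(rep(c(0.1, 0.5), each = 10), 10), c(0.1, 0.5))
  expect_length(bin_trace(rnorm(6000), 10), 600)
  expect_length(bin_trace(seq_len(25), 10), 2)  # remainder dropped
  expect_equal(bin_trace(seq_len(25), 10), c(5.5, 15.5))
  set.seed(51)
  z <- rnorm(1e5, 0, 0.07)
  expect_equal(sd(bin_trace(z, 10)), 0.07 / sqrt(10), tolerance = 0.02)
  expect_error(bin_trace(numeric(0), 2), "empty")
  expect_error(bin_trace(1:10, 0), "factor")
})

test_that("dataset simulation is reproducible and honours the binning pipeline", {
  cfg <- sim_config(ref_rates(), ref_emission(), frame_time = 0.02,
                    n_traces = 5, n_frames = 100, seed = 99)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$traces, d2$traces)
  expect_identical(d1$paths, d2$paths)
  expect_length(d1$traces, 5)
  expect_length(d1$traces[[1]]$estar, 100)

  cfgb <- sim_config(ref_rates(), emission_spec(c(0.20, 0.30, 0.42), 0.068),
                     frame_time = 0.2, n_traces = 3, n_frames = 60,
                     bin_factor = 10L, seed = 7)
  db <- simulate_dataset(cfgb)
  expect_length(db$traces[[1]]$estar, 60)
  expect_equal(db$traces[[1]]$frame_time, 0.2)
  # ground truth retained at fine resolution
  expect_length(db$paths[[1]]$states, 600)
  expect_equal(db$paths[[1]]$frame_time, 0.02)

  one <- simulate_dataset(sim_config(ref_rates(), ref_emission(), 0.02, 1, 1,
                                     seed = 3))
  expect_length(one$traces, 1)
  expect_length(one$traces[[1]]$estar, 1)
})

test_that("noise SD is estimated as the mean of per-trace sample SDs", {
  expect_equal(estimate_noise_sd(list(fret_trace("c", rep(0.3, 10), 0.02))), 0)
  two <- list(fret_trace("a", rnorm(5000, 0, 0.06), 0.02),
              fret_trace("b", rnorm(5000, 0, 0.08), 0.02))
  set.seed(61)
  sds <- vapply(two, function(tr) sd(tr$estar), numeric(1))
  expect_equal(estimate_noise_sd(two), mean(sds), tolerance = 1e-12)
  # recovers the generator noise level from simulated static molecules
  set.seed(62)
  static <- lapply(1:50, function(i) fret_trace(i, rnorm(470, 0.3, 0.070), 0.02))
  expect_equal(estimate_noise_sd(static), 0.070, tolerance = 0.002 / 0.070)
  expect_error(estimate_noise_sd(list()), "no traces")
})
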