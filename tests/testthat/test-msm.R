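test_that("sliding-window counting enumerates the stated pairs", {
  C <- count_transitions(c(1L, 1L, 2L, 2L, 1L), 1)$counts
  expect_equal(C, matrix(c(1, 1, 1, 1), 2, byrow = TRUE))
  C2 <- count_transitions(c(1L, 2L, 1L, 2L), 2)$counts
  expect_equal(C2, diag(c(1, 1)))
  # no pairs across trajectory boundaries
  C3 <- count_transitions(list(c(1L, 2L), c(2L, 1L)), 1)$counts
  expect_equal(C3, matrix(c(0, 1, 1, 0), 2, byrow = TRUE))
  expect_error(count_transitions(list(1L, 2L), 1), "no countable pairs")
})

test_that("largest connected set handles ties and block structure", {
  expect_equal(largest_connected_set(matrix(1, 2, 2)), 1:2)
  expect_equal(largest_connected_set(diag(2)), 1L) # tie -> lowest index
  C <- matrix(0, 5, 5)
  C[1:2, 1:2] <- 1
  C[3:5, 3:5] <- 1
  expect_equal(largest_connected_set(C), 3:5)
  expect_error(largest_connected_set(matrix(numeric(0), 0, 0)), "empty")
})

test_that("reversible MLE reproduces analytic cases", {
  m <- estimate_reversible(matrix(c(9, 1, 1, 9), 2, byrow = TRUE))
  expect_equal(m$T, two_state_T(0.1), tolerance = 1e-9)
  expect_equal(m$pi, c(0.5, 0.5), tolerance = 1e-9)
  # symmetric counts: T is the row-normalized count matrix
  C <- matrix(c(4, 2, 1, 2, 6, 2, 1, 2, 8), 3, byrow = TRUE)
  m2 <- estimate_reversible(C)
  expect_equal(m2$T, C / rowSums(C), tolerance = 1e-8)
  expect_equal(m2$pi, rowSums(C) / sum(C), tolerance = 1e-8)
})

test_that("reversible MLE recovers a known 4-state chain from data", {
  T <- four_state_T()
  d <- make_markov_chain(T, 1e6, seed = 17)
  m <- estimate_reversible(count_transitions(d, 1))
  expect_lt(max(abs(m$T - T)), 0.01)
})

test_that("every estimated model satisfies detailed balance and spectral bounds", {
  set.seed(23)
  for (i in 1:10) {
    k <- sample(3:8, 1)
    C <- matrix(rpois(k * k, 8) + 1, k)
    m <- estimate_reversible(C)
    db <- outer(m$pi, rep(1, k)) * m$T
    expect_lt(max(abs(db - t(db))), 1e-10)
    expect_lt(max(abs(rowSums(m$T) - 1)), 1e-12)
    ev <- msm_eigenvalues(m)
    expect_true(all(ev <= 1 + 1e-10 & ev >= -1 - 1e-10))
    # stationary distribution equals the left unit eigenvector
    lv <- Re(eigen(t(m$T))$vectors[, 1])
    lv <- lv / sum(lv)
    expect_lt(max(abs(lv - m$pi)), 1e-8)
  }
})

test_that("reversible MLE beats random detailed-balance matrices in likelihood", {
  set.seed(31)
  C <- matrix(rpois(16, 6) + 1, 4)
  m <- estimate_reversible(C)
  ll <- function(T) sum(C * log(T))
  ll_mle <- ll(m$T)
  n_rand <- 1e5
  better <- 0L
  for (i in seq_len(n_rand / 100)) {
    # 100 random reversible matrices per block, from symmetric weights
    for (j in 1:100) {
      x <- matrix(rexp(16), 4)
      x <- x + t(x)
      T <- x / rowSums(x)
      if (ll(T) > ll_mle + 1e-9) better <- better + 1L
    }
  }
  expect_equal(better, 0L)
})

test_that("implied timescales match the analytic 2-state value", {
  T <- two_state_T(0.1)
  m <- msmflux:::new_msm(T, c(0.5, 0.5), 1L, 1:2)
  expect_equal(model_timescales(m, 1), -1 / log(0.8), tolerance = 1e-12)
  # lambda -> 1 reports Inf
  m2 <- msmflux:::new_msm(two_state_T(1e-14), c(0.5, 0.5), 1L, 1:2)
  expect_equal(model_timescales(m2, 1), Inf)
})

test_that("implied timescales are flat in lag for exact Markov data", {
  T <- four_state_T()
  d <- replicate(8, make_markov_chain(T, 5e4, seed = sample.int(1e6, 1)),
                 simplify = FALSE)
  its <- implied_timescales(d, lags = c(1L, 2L, 4L, 8L), n_timescales = 1)
  ts <- its$timescale_1
  expect_lt(max(abs(ts - mean(ts))) / mean(ts), 0.1)
})

test_that("VAMP2 scores follow the eigenvalue definition", {
  m5 <- msmflux:::new_msm(diag(5), rep(0.2, 5), 1L, 1:5)
  expect_equal(vamp2_score(m5), 5)
  m2 <- msmflux:::new_msm(two_state_T(0.1), c(0.5, 0.5), 1L, 1:2)
  expect_equal(vamp2_score(m2), 1.64)
  set.seed(2)
  for (i in 1:5) {
    C <- matrix(rpois(25, 5) + 1, 5)
    expect_gte(vamp2_score(estimate_reversible(C)), 1)
  }
})

test_that("grid search prefers the true number of metastable states", {
  pot <- four_well_potential(barrier = 2)
  set.seed(6)
  trajs <- lapply(1:8, function(i) {
    cfg <- langevin_config(kT = 0.61603, D = 1, dt = 0.005, n_steps = 4e4,
                           x0 = c(-6, -2, 2, 6)[(i - 1) %% 4 + 1],
                           seed = 300 + i, thin = 4L)
    simulate_langevin(pot, cfg)$coords
  })
  gs <- grid_search_states(trajs, c(2L, 4L, 50L), lag = 20L, seed = 5)
  sc <- gs$scores$vamp2
  expect_gt(sc[2], sc[1])
  # deterministic under a fixed seed
  gs2 <- grid_search_states(trajs, c(2L, 4L, 50L), lag = 20L, seed = 5)
  expect_identical(gs$scores, gs2$scores)
})

test_that("a single well shows no slow process in the grid search", {
  set.seed(7)
  trajs <- lapply(1:4, function(i) {
    cfg <- langevin_config(kT = 0.61603, D = 1, dt = 0.005, n_steps = 1e4,
                           x0 = 0, seed = 400 + i)
    simulate_langevin(make_harmonic(k = 4, half_width = 5), cfg)$coords
  })
  gs <- grid_search_states(trajs, c(2L, 5L, 10L), lag = 50L, seed = 8)
  expect_true(all(gs$scores$vamp2 < 1.3, na.rm = TRUE))
})

test_that("bootstrap respects its configuration and degenerate input", {
  d <- lapply(1:5, function(i) make_markov_chain(four_state_T(), 2000,
                                                 seed = 50 + i))
  ens <- bootstrap_msm(d, n_rounds = 25, fraction = 0.8, lag = 1L, seed = 3)
  expect_equal(ens$n_rounds, 25L)
  expect_equal(ens$fraction, 0.8)
  # identical trajectories give identical bootstrap models
  same <- rep(list(d[[1]]), 4)
  ens2 <- bootstrap_msm(same, n_rounds = 10, fraction = 0.8, lag = 1L,
                        seed = 3)
  Ts <- lapply(ens2$models, `[[`, "T")
  for (T in Ts) expect_equal(T, Ts[[1]], tolerance = 1e-12)
  expect_error(bootstrap_msm(d[1], lag = 1L), "at least two")
})

test_that("bootstrap stationary distributions scatter around the full fit", {
  T <- four_state_T()
  d <- lapply(1:10, function(i) make_markov_chain(T, 5000, seed = 70 + i))
  full <- estimate_reversible(count_transitions(d, 1))
  ens <- bootstrap_msm(d, n_rounds = 50, fraction = 0.8, lag = 1L, seed = 9)
  pis <- t(vapply(ens$models, `[[`, numeric(4), "pi"))
  for (j in 1:4) {
    expect_lt(abs(mean(pis[, j]) - full$pi[j]),
              4 * sd(pis[, j]) / sqrt(2) + 1e-3)
  }
})

test_that("Chapman-Kolmogorov holds for exact Markov data and fails for lumped", {
  T <- four_state_T()
  d <- lapply(1:10, function(i) make_markov_chain(T, 2e4, seed = 90 + i))
  m <- estimate_reversible(count_transitions(d, 1))
  sets <- list(low = 1:2, high = 3:4)
  ck <- ck_test(m, d, sets, factors = 1:5, n_boot = 50, seed = 4)
  expect_true(all(ck$predicted >= 0 & ck$predicted <= 1))
  # k = 1: prediction equals estimation by construction
  k1 <- ck[ck$factor == 1, ]
  expect_equal(k1$predicted, k1$estimated, tolerance = 1e-12)
  inside <- with(ck, predicted >= lower - 1e-9 & predicted <= upper + 1e-9)
  expect_gte(mean(inside), 0.9)

  # hidden 3-state chain lumped to 2 states: systematic CK deviation
  Th <- matrix(c(0.98, 0.02, 0,
                 0.05, 0.90, 0.05,
                 0, 0.02, 0.98), 3, byrow = TRUE)
  dh <- lapply(1:10, function(i) {
    s <- make_markov_chain(Th, 2e4, seed = 120 + i)
    ifelse(s == 3L, 2L, 1L) # lump states 2 and 3... states {1,2}->1, {3}->2
  })
  mh <- estimate_reversible(count_transitions(dh, 1))
  ckh <- ck_test(mh, dh, list(a = 1, b = 2), factors = c(1L, 5L, 10L),
                 n_boot = 50, seed = 5)
  late <- ckh[ckh$factor == 10, ]
  outside <- with(late, predicted < lower | predicted > upper)
  expect_true(any(outside))
})

test_that("MSM JSON round-trips", {
  m <- estimate_reversible(matrix(c(9, 1, 1, 9), 2, byrow = TRUE),
                           frame_time = 0.5)
  f <- withr::local_tempfile(fileext = ".json")
  write_msm_json(m, f)
  m2 <- read_msm_json(f)
  expect_equal(m2$T, m$T, tolerance = 1e-12)
  expect_equal(m2$pi, m$pi, tolerance = 1e-12)
  expect_equal(m2$frame_time, 0.5)
})
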