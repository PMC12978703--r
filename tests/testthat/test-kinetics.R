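sym3 <- matrix(c(0.5, 0.5, 0,
                 0.25, 0.5, 0.25,
                 0, 0.5, 0.5), 3, byrow = TRUE)
model3 <- msmflux:::new_msm(sym3, c(0.25, 0.5, 0.25), 1L, 1:3)

test_that("committor of the symmetric 3-state chain is (0, 1/2, 1)", {
  q <- committor(model3, 1, 3)
  expect_equal(q$q_plus, c(0, 0.5, 1))
  expect_equal(q$q_minus, c(1, 0.5, 0))
})

test_that("committor boundary and error cases", {
  q <- committor(model3, c(1, 2), 3)
  expect_equal(q$q_plus, c(0, 0, 1)) # A union B covers everything
  expect_error(committor(model3, 1, 1), "disjoint")
  expect_error(committor(model3, 1, 9), "outside")
})

test_that("committor matches an independent linear solve on a biased chain", {
  # birth-death chain, right hops twice as likely as left hops
  k <- 6
  T <- matrix(0, k, k)
  for (i in 2:(k - 1)) {
    T[i, i + 1] <- 0.2
    T[i, i - 1] <- 0.1
    T[i, i] <- 0.7
  }
  T[1, 1] <- 0.8; T[1, 2] <- 0.2
  T[k, k] <- 0.9; T[k, k - 1] <- 0.1
  pi_unnorm <- cumprod(c(1, rep(2, k - 1)))
  m <- msmflux:::new_msm(T, pi_unnorm / sum(pi_unnorm), 1L, 1:k)
  q <- committor(m, 1, k)
  # independent oracle: assemble and solve the boundary-value system directly
  inter <- 2:(k - 1)
  A <- diag(length(inter)) - T[inter, inter]
  rhs <- T[inter, k]
  q_ref <- c(0, solve(A, rhs), 1)
  expect_equal(q$q_plus, q_ref, tolerance = 1e-12)
  expect_true(all(diff(q$q_plus) >= -1e-12)) # monotone along the chain
  expect_true(all(q$q_plus >= 0 & q$q_plus <= 1))
})

test_that("reactive flux reproduces the 2-state arithmetic case", {
  m <- msmflux:::new_msm(two_state_T(0.1), c(0.5, 0.5), 1L, 1:2)
  q <- committor(m, 1, 2)
  fl <- reactive_flux(m, q)
  expect_equal(fl$gross[1, 2], 0.05)
  expect_equal(fl$total_flux, 0.05)
  expect_equal(fl$rate, 0.1)
})

test_that("net flux is conserved at intermediate states", {
  q <- committor(model3, 1, 3)
  fl <- reactive_flux(model3, q)
  net_in <- sum(fl$net[, 2]); net_out <- sum(fl$net[2, ])
  expect_lt(abs(net_in - net_out), 1e-12)
  # random reversible models too
  set.seed(12)
  for (i in 1:5) {
    C <- matrix(rpois(36, 5) + 1, 6)
    m <- estimate_reversible(C)
    q <- committor(m, 1, 6)
    fl <- reactive_flux(m, q)
    for (s in 2:5)
      expect_lt(abs(sum(fl$net[, s]) - sum(fl$net[s, ])), 1e-12)
  }
})

test_that("TPT rate inverts to the MFPT for metastable 2-state models", {
  m <- msmflux:::new_msm(two_state_T(0.01), c(0.5, 0.5), 1L, 1:2)
  q <- committor(m, 1, 2)
  rate <- reactive_flux(m, q)$rate
  expect_equal(1 / rate, mfpt(m, 1, 2)$value, tolerance = 0.05)
})

test_that("MFPT solves analytic cases exactly", {
  m <- msmflux:::new_msm(two_state_T(0.1), c(0.5, 0.5), 1L, 1:2)
  expect_equal(mfpt(m, 1, 2)$value, 10)
  # absorbing state reached with probability 1 in one step
  T <- matrix(c(0, 1, 0, 1), 2, byrow = TRUE)
  ma <- msmflux:::new_msm(T, c(0.5, 0.5), 1L, 1:2)
  expect_equal(mfpt(ma, 1, 2)$value, 1)
})

test_that("MFPT matches empirical first passage on a 5-state ring", {
  k <- 5
  T <- matrix(0, k, k)
  for (i in 1:k) {
    T[i, i %% k + 1] <- 0.3
    T[i, (i - 2) %% k + 1] <- 0.1
    T[i, i] <- 0.6
  }
  pi <- rep(1 / k, k)
  m <- msmflux:::new_msm(T, pi, 1L, 1:k)
  pred <- mfpt(m, 1, 4)$value
  emp <- mean(sample_first_passage(T, 1, 4, n_chains = 1e5, seed = 3))
  expect_equal(pred, emp, tolerance = 0.05)
})

test_that("MFPT scales linearly with the physical frame time", {
  C <- matrix(c(9, 1, 1, 9), 2, byrow = TRUE)
  m1 <- estimate_reversible(C, frame_time = 1)
  m2 <- estimate_reversible(C, frame_time = 2.5)
  expect_equal(mfpt(m2, 1, 2)$value, 2.5 * mfpt(m1, 1, 2)$value)
})

test_that("bootstrap MFPT reports spread and skipped rounds", {
  T <- four_state_T()
  d <- lapply(1:10, function(i) make_markov_chain(T, 5000, seed = 140 + i))
  ens <- bootstrap_msm(d, n_rounds = 40, fraction = 0.8, lag = 1L, seed = 2)
  r <- mfpt_with_error(ens, 1, 4)
  expect_gt(r$value, 0)
  expect_gt(r$err, 0)
  expect_equal(r$n_rounds, length(ens$models))
  expect_true(r$n_skipped >= 0)
  truth <- mfpt(estimate_reversible(count_transitions(d, 1)), 1, 4)$value
  expect_lt(abs(r$value - truth), 4 * r$err + 0.05 * truth)
  # identical rounds give zero spread
  same <- rep(list(d[[1]]), 4)
  ens2 <- bootstrap_msm(same, n_rounds = 12, fraction = 0.8, lag = 1L,
                        seed = 3)
  r2 <- mfpt_with_error(ens2, 1, 4)
  expect_equal(r2$err, 0, tolerance = 1e-10)
})

test_that("uphill MFPT exceeds downhill MFPT on a tilted double well", {
  kT <- 0.61603
  pot <- make_double_well(3, 1.5, tilt = 2)
  ds <- make_dataset(pot, n_traj = 10, n_steps = 1e5, master_seed = 77,
                     dt = 0.002, kT = kT, thin = 10L,
                     starts = matrix(c(-1.5, 1.5), 2))
  disc <- kmeans_fit(lapply(ds$trajectories, `[[`, "coords"), 20, seed = 5)
  model <- estimate_reversible(count_transitions(disc, 10L))
  xbar <- state_mean_coordinate(
    do.call(rbind, lapply(ds$trajectories, `[[`, "coords"))[, 1],
    disc, model)
  A <- which(xbar < -1); B <- which(xbar > 1)
  down <- mfpt(model, A, B)$value # towards the deeper basin
  up <- mfpt(model, B, A)$value
  expect_gt(up, down)
})
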