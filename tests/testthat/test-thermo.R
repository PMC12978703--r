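test_that("single-state reweighting equals plain Boltzmann inversion", {
  set.seed(1)
  x <- rnorm(5000)
  edges <- make_bin_edges(x, 20)
  model <- msmflux:::new_msm(matrix(1, 1, 1), 1, 1L, 1L)
  fes <- reweighted_fes(matrix(x), rep(1L, 5000), model, list(edges),
                        kT = 0.61603)
  ref <- histogram_fes(matrix(x), list(edges), kT = 0.61603)
  expect_equal(fes$F, ref$F, tolerance = 1e-12)
})

test_that("reweighting equalizes states sampled 90/10 but with equal pi", {
  # state 1 frames at x ~ 0, state 2 frames at x ~ 10
  n1 <- 900; n2 <- 100
  coords <- matrix(c(rep(0, n1), rep(10, n2)))
  dtraj <- c(rep(1L, n1), rep(2L, n2))
  model <- msmflux:::new_msm(two_state_T(0.5), c(0.5, 0.5), 1L, 1:2)
  edges <- seq(-1, 11, by = 2)
  fes <- reweighted_fes(coords, dtraj, model, list(edges), kT = 1)
  mass <- exp(-fes$F[!is.na(fes$F)])
  expect_equal(mass[1], mass[2], tolerance = 1e-12)
})

test_that("reweighted surface recovers the double-well potential", {
  kT <- 0.61603
  pot <- make_double_well(2, 1.5)
  ds <- make_dataset(pot, n_traj = 10, n_steps = 1e5, master_seed = 33,
                     dt = 0.002, kT = kT, thin = 5L,
                     starts = matrix(c(-1.5, 1.5), 2))
  coords <- do.call(rbind, lapply(ds$trajectories, `[[`, "coords"))
  disc <- kmeans_fit(lapply(ds$trajectories, `[[`, "coords"), 30, seed = 2)
  model <- estimate_reversible(count_transitions(disc, 20L))
  edges <- seq(-3, 3, length.out = 31)
  fes <- reweighted_fes(coords, disc, model, list(edges), kT = kT)
  ctr <- fes_centers(fes)[[1]]
  truth <- potential_energy(pot, ctr)
  truth <- truth - min(truth)
  # >= 100 effective samples: raw counts discounted by the ~10-frame
  # correlation time of the thinned trajectory
  ok <- !is.na(fes$F) & fes$counts >= 1000
  expect_gt(sum(ok), 15)
  expect_lt(max(abs(fes$F[ok] - truth[ok])), 0.3)
  # reweighting conservation: stationary weights sum to one before binning
  expect_equal(sum(model$pi), 1, tolerance = 1e-12)
})

test_that("reweighted and plain histograms agree at equilibrium", {
  kT <- 0.61603
  pot <- make_harmonic(k = 2, half_width = 6)
  ds <- make_dataset(pot, n_traj = 5, n_steps = 1e5, master_seed = 44,
                     dt = 0.002, kT = kT, thin = 5L)
  coords <- do.call(rbind, lapply(ds$trajectories, `[[`, "coords"))
  disc <- kmeans_fit(lapply(ds$trajectories, `[[`, "coords"), 20, seed = 3)
  model <- estimate_reversible(count_transitions(disc, 20L))
  edges <- make_bin_edges(coords[, 1], 25)
  few <- reweighted_fes(coords, disc, model, list(edges), kT = kT)
  fhist <- histogram_fes(coords, list(edges), kT = kT)
  ok <- !is.na(few$F) & !is.na(fhist$F) & fhist$counts >= 500
  expect_lt(max(abs(few$F[ok] - fhist$F[ok])), 0.2)
})

test_that("bootstrap surface errors behave as documented", {
  f1 <- fes_from_matrix(matrix(c(0, 1, 2, 3), 2))
  # identical rounds -> zero error
  expect_equal(max(fes_error(list(f1, f1, f1))), 0)
  # constant offsets vanish after per-round min-shifting
  f2 <- fes_from_matrix(matrix(c(0, 1, 2, 3), 2) + 5)
  expect_equal(max(fes_error(list(f1, f2))), 0)
  # genuine differences survive
  f3 <- fes_from_matrix(matrix(c(0, 2, 2, 3), 2))
  expect_gt(max(fes_error(list(f1, f3))), 0)
  # bins defined in under half the rounds are undefined
  f4 <- fes_from_matrix(matrix(c(0, NA, 2, 3), 2))
  err <- fes_error(list(f4, f4, f4))
  expect_true(is.na(err[2, 1]))
})

test_that("minimax path solves stated 1D and flat cases", {
  ramp <- fes_from_matrix(matrix(c(0, 1, 2, 3), 4))
  p <- minimax_path(ramp, 1, 4)
  expect_equal(p$barrier, 3)
  flat <- fes_from_matrix(matrix(0, 5, 5))
  pf <- minimax_path(flat, c(1, 1), c(5, 5))
  expect_equal(pf$barrier, 0)
  # secondary criterion: shortest path on a flat surface is the diagonal
  expect_equal(nrow(pf$bins), 5)
})

test_that("minimax path routes through the lower of two channels", {
  pot <- make_two_channel(5.8, 6.5)
  ax <- list(seq(-4, 4, length.out = 81), seq(-2, 2, length.out = 41))
  G <- as.matrix(expand.grid(ax[[1]], ax[[2]]))
  F <- matrix(potential_energy(pot, G), 81, 41)
  fes <- structure(list(dims = 2L,
                        bin_edges = lapply(ax, function(a)
                          c(a - (a[2] - a[1]) / 2, a[length(a)] + (a[2] - a[1]) / 2)),
                        F = F, counts = array(1, dim(F)), kT = 0.616),
                   class = "free_energy_surface")
  s <- c(which.min(abs(ax[[1]] + 3.8)), which.min(abs(ax[[2]] - 1)))
  e <- c(which.min(abs(ax[[1]] - 3.8)), which.min(abs(ax[[2]] - 1)))
  p <- minimax_path(fes, s, e)
  expect_equal(p$barrier, 5.8, tolerance = 0.05)
  # the path stays in the w > 0 channel at the crossing
  crossing <- p$bins[which.min(abs(ax[[1]][p$bins[, 1]])), 2]
  expect_gt(ax[[2]][crossing], 0)
  # channel_barriers agrees with the path search (dual route)
  cb_fast <- channel_barriers(fes, fast = TRUE)
  cb_slow <- channel_barriers(fes, fast = FALSE)
  expect_equal(cb_fast, cb_slow, tolerance = 1e-12)
  expect_equal(unname(cb_fast["a"]), 5.8, tolerance = 0.05)
  expect_equal(unname(cb_fast["b"]), 6.5, tolerance = 0.05)
})

test_that("minimax path equals brute-force enumeration on small grids", {
  set.seed(14)
  for (i in 1:8) {
    F <- matrix(runif(12, 0, 5), 4, 3)
    fes <- fes_from_matrix(F)
    p <- minimax_path(fes, c(1, 1), c(4, 3))
    expect_equal(p$barrier, brute_force_minimax(F, c(1, 1), c(4, 3)),
                 tolerance = 1e-12)
    # path is 8-connected and starts/ends correctly
    steps <- abs(diff(p$bins))
    expect_true(all(steps <= 1))
    expect_equal(p$bins[1, ], c(row = 1, col = 1))
  }
})

test_that("disconnected or undefined endpoints raise errors", {
  F <- matrix(c(0, NA, 1), 3)
  fes <- fes_from_matrix(F)
  expect_error(minimax_path(fes, 1, 2), "undefined")
  expect_error(minimax_path(fes, 1, 3), "disconnected")
})

test_that("barrier comparison behaves across regimes", {
  same <- rep(5.8, 20)
  cmp0 <- compare_barriers(same, same)
  expect_equal(cmp0$delta, 0)
  expect_equal(cmp0$p_value, 1)
  set.seed(9)
  a <- rnorm(200, 5.8, 0.7)
  b <- rnorm(200, 6.5, 0.8)
  cmp <- compare_barriers(a, b)
  expect_lt(cmp$p_value, 0.01)
  expect_lt(cmp$delta, 0)
  cmp_far <- compare_barriers(a, b + 10)
  expect_lt(cmp_far$p_value, cmp$p_value)
  expect_error(compare_barriers(a[1:5], b), ">= 10")
})
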