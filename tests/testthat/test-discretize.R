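test_that("k-means solves separable toy problems exactly", {
  X <- matrix(c(0, 0, 10, 10), ncol = 1)
  d <- kmeans_fit(X, 2, seed = 1)
  expect_equal(sort(d$centers[, 1]), c(0, 10))
  expect_equal(d$inertia, 0)
  # k = number of distinct points -> zero inertia
  X2 <- matrix(c(1, 2, 3, 1, 2, 3), ncol = 1)
  d2 <- kmeans_fit(X2, 3, seed = 2)
  expect_equal(d2$inertia, 0)
  expect_error(kmeans_fit(X2, 4, seed = 1), "distinct")
})

test_that("k-means and mini-batch recover well-separated blob centres", {
  X <- blob_data(1e4)
  d <- kmeans_fit(X, 2, seed = 3)
  expect_equal(sort(d$centers[, 1]), c(-5, 5), tolerance = 0.1 / 5)
  mb <- minibatch_kmeans_fit(X, 2, batch_size = 500, seed = 3,
                             n_batches = 100)
  expect_equal(sort(mb$centers[, 1]), c(-5, 5), tolerance = 0.2 / 5)
  # mini-batch with batch_size = n behaves like full passes: inertia close
  # to the Lloyd optimum on this separable fixture
  mbf <- minibatch_kmeans_fit(X, 2, batch_size = nrow(X), seed = 4,
                              n_batches = 5)
  expect_lt(mbf$inertia, 1.5 * d$inertia)
  expect_identical(minibatch_kmeans_fit(X, 2, batch_size = 500, seed = 7,
                                        n_batches = 20)$centers,
                   minibatch_kmeans_fit(X, 2, batch_size = 500, seed = 7,
                                        n_batches = 20)$centers)
})

test_that("assignment ties break to the lowest centre index", {
  centers <- matrix(c(-1, 1), ncol = 1)
  expect_equal(assign_states(centers, matrix(0)), 1L)
  expect_equal(assign_states(centers, centers), c(1L, 2L))
  # joint translation leaves labels unchanged
  X <- matrix(rnorm(50), ncol = 1)
  expect_equal(assign_states(centers, X),
               assign_states(centers + 7, X + 7))
  expect_error(assign_states(matrix(numeric(0), 0, 1), X), "empty")
})

test_that("assignment of the centres themselves is the identity labelling", {
  set.seed(11)
  centers <- matrix(rnorm(20), ncol = 2)
  expect_equal(assign_states(centers, centers), 1:10)
})

test_that("inertia is non-increasing over Lloyd iterations", {
  set.seed(5)
  X <- matrix(rnorm(600), ncol = 2)
  inertias <- vapply(1:6, function(iters)
    kmeans_fit(X, 5, seed = 9, max_iter = iters)$inertia, numeric(1))
  expect_true(all(diff(inertias) <= 1e-9))
})

test_that("least-counts selection picks the emptiest clusters first", {
  # counts per cluster: 5, 1, 3
  dtrajs <- list(c(rep(1L, 5), 2L, rep(3L, 3)))
  disc <- msmflux:::new_discretization(matrix(1:3, ncol = 1), dtrajs,
                                       0, 1L, "manual")
  s1 <- least_counts_select(disc, 1, seed = 2)
  expect_equal(s1$cluster, 2L)
  s2 <- least_counts_select(disc, 2, seed = 2)
  expect_equal(s2$cluster, c(2L, 3L))
  # tie by cluster index
  disc2 <- msmflux:::new_discretization(matrix(1:2, ncol = 1),
                                        list(c(1L, 1L, 2L, 2L)), 0, 1L, "m")
  s3 <- least_counts_select(disc2, 2, seed = 1)
  expect_equal(s3$cluster, c(1L, 2L))
  expect_error(least_counts_select(disc, 100), "exceeds")
})

test_that("selected frames map back to the right trajectory and frame", {
  dtrajs <- list(c(1L, 1L, 2L), c(2L, 3L, 3L, 3L))
  disc <- msmflux:::new_discretization(matrix(1:3, ncol = 1), dtrajs,
                                       0, 1L, "manual")
  sel <- least_counts_select(disc, 3, seed = 4)
  for (i in seq_len(nrow(sel)))
    expect_equal(dtrajs[[sel$traj[i]]][sel$frame[i]], sel$cluster[i])
})

test_that("draws within the least cluster are uniform over its frames", {
  dtrajs <- list(c(rep(1L, 40), rep(2L, 200)))
  disc <- msmflux:::new_discretization(matrix(1:2, ncol = 1), dtrajs,
                                       0, 1L, "manual")
  picks <- vapply(1:2000, function(s)
    least_counts_select(disc, 1, seed = s)$frame, integer(1))
  tab <- tabulate(picks, nbins = 40)
  expect_gt(chisq.test(tab)$p.value, 0.01)
})
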