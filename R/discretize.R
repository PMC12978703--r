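# State decomposition of the projected space: Lloyd k-means and mini-batch
# k-means with k-means++ initialization, plus least-counts seed selection
# for adaptive sampling. The Lloyd/mini-batch loops are written out here
# because the tie-breaking, initialization and empty-cluster repair rules
# are part of the module contract; the per-frame assignment pass is
# compiled.

.kmeanspp_init <- function(X, k, sample_cap = 2e5) {
  # assumes RNG already seeded by the caller; on very large inputs the
  # init runs on a seeded subsample (the Lloyd/mini-batch refinement that
  # follows sees all the data)
  if (nrow(X) > sample_cap) X <- X[sample.int(nrow(X), sample_cap), , drop = FALSE]
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in seq_len(k)[-1]) {
    p <- d2 / sum(d2)
    if (!all(is.finite(p)) || sum(d2) <= 0)
      idx <- sample.int(n, 1L)
    else
      idx <- sample.int(n, 1L, prob = p)
    centers[j, ] <- X[idx, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  centers
}

.pool_X <- function(X) {
  mats <- .as_mat_list(X)
  list(pooled = do.call(rbind, mats),
       block_rows = vapply(mats, nrow, integer(1)))
}

.split_labels <- function(labels, block_rows) {
  ends <- cumsum(block_rows)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_along(ends), function(i) labels[starts[i]:ends[i]])
}

new_discretization <- function(centers, dtrajs, inertia, seed, method) {
  structure(list(centers = centers, dtrajs = dtrajs, inertia = inertia,
                 seed = as.integer(seed), k = nrow(centers),
                 method = method),
            class = "discretization")
}

#' @export
print.discretization <- function(x, ...) {
  cat(sprintf("Discretization: %d states (%s), %d trajectories, inertia %.4g\n",
              x$k, x$method, length(x$dtrajs), x$inertia))
  invisible(x)
}

#' Lloyd k-means state decomposition
#'
#' k-means++ seeded initialization followed by full Lloyd iterations until
#' the maximum centre shift drops below `tol` or `max_iter` is reached.
#' Ties in assignment go to the lowest centre index; an emptied cluster is
#' re-seeded at the point farthest from its assigned centre.
#'
#' @param X Matrix, `feature_matrix`, or list of per-trajectory matrices.
#' @param k Number of states (`k` must not exceed the number of distinct
#'   points).
#' @param seed Integer seed (initialization is deterministic given it).
#' @param max_iter Maximum Lloyd iterations.
#' @param tol Convergence threshold on the maximum centre shift.
#' @return A `discretization`: `centers` (k x d), `dtrajs` (per-trajectory
#'   1-based label vectors), `inertia` (total within-cluster sum of
#'   squares), `seed`.
#' @export
kmeans_fit <- function(X, k, seed = 1L, max_iter = 100L, tol = 1e-8) {
  px <- .pool_X(X)
  P <- px$pooled
  n <- nrow(P)
  if (k > n) stop("k exceeds the number of points", call. = FALSE)
  if (k > nrow(unique(P)))
    stop("k exceeds the number of distinct points", call. = FALSE)
  set.seed(seed)
  centers <- .kmeanspp_init(P, k)
  for (it in seq_len(max_iter)) {
    asg <- assign_nearest_cpp(P, centers)
    lab <- asg$labels
    newc <- .update_centers(P, lab, k, centers, asg$dist2)
    shift <- max(sqrt(rowSums((newc - centers)^2)))
    centers <- newc
    if (shift < tol) break
  }
  asg <- assign_nearest_cpp(P, centers)
  new_discretization(centers, .split_labels(asg$labels, px$block_rows),
                     inertia = sum(asg$dist2), seed = seed, method = "kmeans")
}

.update_centers <- function(P, lab, k, centers, dist2) {
  counts <- tabulate(lab, nbins = k)
  sums <- rowsum(P, lab) # rows sorted by label
  present <- as.integer(rownames(sums))
  newc <- centers
  newc[present, ] <- sums / counts[present]
  empty <- which(counts == 0L)
  for (j in empty) {
    # re-seed an empty cluster at the point farthest from its centre
    far <- which.max(dist2)
    newc[j, ] <- P[far, ]
    dist2[far] <- 0
  }
  newc
}

#' Mini-batch k-means state decomposition
#'
#' Streaming centre updates on seeded random batches with per-centre
#' learning rate `1/counts`, finished by one full-data assignment pass.
#'
#' @inheritParams kmeans_fit
#' @param batch_size Points per batch (at most the number of points).
#' @param n_batches Number of batches.
#' @return A `discretization`.
#' @export
minibatch_kmeans_fit <- function(X, k, batch_size = 1000L, seed = 1L,
                                 n_batches = 100L) {
  px <- .pool_X(X)
  P <- px$pooled
  n <- nrow(P)
  if (batch_size > n) stop("batch_size exceeds the number of points", call. = FALSE)
  if (k > n) stop("k exceeds the number of points", call. = FALSE)
  set.seed(seed)
  centers <- .kmeanspp_init(P, k)
  counts <- numeric(k)
  for (b in seq_len(n_batches)) {
    idx <- sample.int(n, batch_size)
    B <- P[idx, , drop = FALSE]
    lab <- assign_nearest_cpp(B, centers)$labels
    for (j in unique(lab)) {
      rows <- which(lab == j)
      for (r in rows) {
        counts[j] <- counts[j] + 1
        eta <- 1 / counts[j]
        centers[j, ] <- (1 - eta) * centers[j, ] + eta * B[r, ]
      }
    }
  }
  asg <- assign_nearest_cpp(P, centers)
  new_discretization(centers, .split_labels(asg$labels, px$block_rows),
                     inertia = sum(asg$dist2), seed = seed,
                     method = "minibatch_kmeans")
}

#' Assign points to nearest centres
#'
#' Euclidean nearest-centre labels; exact ties go to the lowest centre
#' index.
#'
#' @param centers k x d centre matrix.
#' @param X Points (n x d).
#' @return Integer vector of 1-based labels.
#' @export
assign_states <- function(centers, X) {
  centers <- .as_matrix(centers)
  if (!nrow(centers)) stop("empty centre set", call. = FALSE)
  X <- .as_matrix(X)
  if (ncol(X) != ncol(centers)) stop("dimension mismatch", call. = FALSE)
  assign_nearest_cpp(X, centers)$labels
}

#' Least-counts adaptive-sampling seed selection
#'
#' Ranks clusters by ascending population (ties by cluster index) and draws
#' one frame uniformly at random from each cluster in round-robin over that
#' ranking until `n_seeds` frames are chosen — the "least visited states
#' first" restart rule of adaptive sampling.
#'
#' @param disc A `discretization`.
#' @param n_seeds Number of restart frames to select (>= 1).
#' @param seed Integer seed for the uniform draws.
#' @return A `seed_selection`: data.frame with `traj` (trajectory index),
#'   `frame` (1-based frame index) and `cluster`.
#' @export
least_counts_select <- function(disc, n_seeds, seed = 1L) {
  stopifnot(inherits(disc, "discretization"))
  .check_scalar(n_seeds, "n_seeds", positive = TRUE)
  all_lab <- unlist(disc$dtrajs, use.names = FALSE)
  if (n_seeds > length(all_lab))
    stop("n_seeds exceeds the total number of frames", call. = FALSE)
  counts <- tabulate(all_lab, nbins = disc$k)
  nonempty <- which(counts > 0L)
  ranking <- nonempty[order(counts[nonempty], nonempty)]
  # frame lookup: trajectory and within-trajectory index per pooled row
  traj_of <- rep(seq_along(disc$dtrajs),
                 vapply(disc$dtrajs, length, integer(1)))
  frame_of <- unlist(lapply(disc$dtrajs, seq_along), use.names = FALSE)
  pool <- split(seq_along(all_lab), all_lab)
  set.seed(seed)
  picked <- integer(0)
  chosen_cluster <- integer(0)
  ri <- 1L
  avail <- lapply(pool, identity)
  while (length(picked) < n_seeds) {
    cl <- ranking[((ri - 1L) %% length(ranking)) + 1L]
    ri <- ri + 1L
    key <- as.character(cl)
    rows <- avail[[key]]
    if (is.null(rows) || !length(rows)) next
    take <- if (length(rows) == 1L) rows else rows[sample.int(length(rows), 1L)]
    avail[[key]] <- setdiff(rows, take)
    picked <- c(picked, take)
    chosen_cluster <- c(chosen_cluster, cl)
    if (!any(vapply(avail, length, integer(1)) > 0L)) break
  }
  out <- data.frame(traj = traj_of[picked], frame = frame_of[picked],
                    cluster = chosen_cluster)
  class(out) <- c("seed_selection", "data.frame")
  out
}

#' Write discrete trajectories as one-integer-per-line text files
#'
#' @param disc A `discretization`.
#' @param dir Output directory; files are `dtraj_001.txt`, ... Centres go
#'   to `centers.csv`.
#' @export
write_discretization <- function(disc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(disc$dtrajs))
    writeLines(as.character(disc$dtrajs[[i]]),
               file.path(dir, sprintf("dtraj_%03d.txt", i)))
  utils::write.csv(as.data.frame(disc$centers),
                   file.path(dir, "centers.csv"), row.names = FALSE)
  invisible(dir)
}

#' Density-flattened k-means discretization
#'
#' k-means on a subsample that contributes the same number of frames from
#' every occupied cell of a coarse grid over the projected space (dense
#' cells are subsampled, sparse cells resampled with replacement),
#' followed by a full-data nearest-centre assignment. Plain k-means
#' allocates centres in proportion to data density, which leaves rarely
#' visited regions — barrier tops, exactly where adaptive sampling spends
#' least time — as single huge states; flattening allocates centres
#' roughly uniformly over *visited* space instead, so sparse transition
#' regions are resolved at the same length scale as the basins.
#'
#' @inheritParams kmeans_fit
#' @param cells Cells per dimension of the flattening grid.
#' @param per_cell Subsample frames contributed by each occupied cell.
#' @return A `discretization`.
#' @export
flattened_kmeans <- function(X, k, cells = 48L, per_cell = 25L, seed = 1L,
                             max_iter = 50L) {
  px <- .pool_X(X)
  P <- px$pooled
  set.seed(seed)
  idx <- seq_len(nrow(P))
  cell <- rep(0, nrow(P))
  for (d in seq_len(ncol(P))) {
    br <- seq(min(P[, d]), max(P[, d]), length.out = cells + 1L)
    cell <- cell * (cells + 2L) + findInterval(P[, d], br,
                                               rightmost.closed = TRUE)
  }
  by_cell <- split(idx, cell)
  sub <- unlist(lapply(by_cell, function(ix)
    if (length(ix) >= per_cell) sample(ix, per_cell)
    else sample(ix, per_cell, replace = TRUE)), use.names = FALSE)
  fit <- kmeans_fit(P[sub, , drop = FALSE], k,
                    seed = derive_seed(seed, "flat_kmeans"),
                    max_iter = max_iter)
  labels <- assign_states(fit$centers, P)
  new_discretization(fit$centers, .split_labels(labels, px$block_rows),
                     inertia = NA_real_, seed = seed,
                     method = "kmeans_flattened")
}
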