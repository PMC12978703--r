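# MSM-reweighted free-energy surfaces, minimax (minimum-energy) paths and
# barrier statistics.

#' Histogram bin edges over a data range
#'
#' Convenience constructor: `n` equal bins spanning the data (optionally
#' padded). Bins are half-open `[lo, hi)` with the last bin closed.
#'
#' @param x Data vector.
#' @param n Number of bins.
#' @param pad Fractional range padding on each side.
#' @return Numeric vector of `n + 1` edges.
#' @export
make_bin_edges <- function(x, n = 40L, pad = 0.001) {
  r <- range(x, finite = TRUE)
  w <- diff(r) * pad
  seq(r[1] - w, r[2] + w, length.out = n + 1L)
}

.bin_index <- function(x, edges) {
  # half-open [lo, hi), last bin closed
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  i[i < 1L | i > length(edges) - 1L] <- NA_integer_
  i
}

new_fes <- function(F, counts, bin_edges, kT, F_err = NULL) {
  structure(list(dims = length(bin_edges), bin_edges = bin_edges,
                 F = F, counts = counts, F_err = F_err, kT = kT),
            class = "free_energy_surface")
}

#' @export
print.free_energy_surface <- function(x, ...) {
  def <- sum(!is.na(x$F))
  cat(sprintf("Free-energy surface: %dD, %s bins (%d defined), max F %.3g kcal/mol\n",
              x$dims, paste(lengths(x$bin_edges) - 1L, collapse = " x "),
              def, max(x$F, na.rm = TRUE)))
  invisible(x)
}

#' Bin centres of a free-energy surface
#'
#' @param fes A `free_energy_surface`.
#' @return List of per-dimension centre vectors.
#' @export
fes_centers <- function(fes) {
  lapply(fes$bin_edges, function(e) (e[-1] + e[-length(e)]) / 2)
}

#' MSM-reweighted free-energy surface
#'
#' Each frame is weighted by `pi[s(frame)] / N(s(frame))` — the stationary
#' probability of its state spread over that state's frames — so the
#' histogram estimates equilibrium populations even when trajectories were
#' started far from equilibrium (as with adaptively seeded ensembles).
#' `F = -kT log(mass)`, shifted so the minimum over defined bins is 0.
#' Frames in states outside the model's active set are dropped (fraction
#' recorded in the result's `dropped_fraction`). Empty bins are `NA`, never
#' infinite.
#'
#' @param coords Frame coordinates to bin: matrix with 1 or 2 columns,
#'   frame-aligned with `dtrajs` in pooled order.
#' @param dtrajs Discrete trajectories (pooled frame order must match
#'   `coords` rows).
#' @param model An `msm_model`.
#' @param bin_edges List of per-dimension edge vectors (or one vector for
#'   1D); see [make_bin_edges()].
#' @param kT Thermal energy, kcal/mol.
#' @param min_count Bins with fewer raw frames than this are treated as
#'   undefined (default 1 = any frame defines a bin). A small threshold
#'   suppresses the huge free-energy variance of single-frame bins when
#'   the surface feeds a path search.
#' @return A `free_energy_surface` with `F` (vector or matrix, kcal/mol),
#'   `counts`, and `kT`.
#' @export
reweighted_fes <- function(coords, dtrajs, model, bin_edges,
                           kT = kT_at(310), min_count = 1L) {
  coords <- .as_matrix(coords)
  if (is.numeric(bin_edges)) bin_edges <- list(bin_edges)
  stopifnot(ncol(coords) %in% c(1L, 2L), length(bin_edges) == ncol(coords),
            inherits(model, "msm_model"))
  s <- unlist(.as_dtraj_list(dtrajs), use.names = FALSE)
  if (length(s) != nrow(coords))
    stop("coords and dtrajs are not frame-aligned", call. = FALSE)
  pos <- match(s, model$active_set)
  ok <- !is.na(pos)
  if (!any(ok)) stop("all frames are in inactive states", call. = FALSE)
  state_counts <- tabulate(pos[ok], nbins = length(model$active_set))
  w <- model$pi[pos[ok]] / state_counts[pos[ok]]
  b1 <- .bin_index(coords[ok, 1], bin_edges[[1]])
  nb1 <- length(bin_edges[[1]]) - 1L
  if (ncol(coords) == 1L) {
    inb <- !is.na(b1)
    mass <- numeric(nb1)
    msums <- rowsum(w[inb], b1[inb])
    mass[as.integer(rownames(msums))] <- msums
    cnt <- tabulate(b1[inb], nbins = nb1)
  } else {
    b2 <- .bin_index(coords[ok, 2], bin_edges[[2]])
    nb2 <- length(bin_edges[[2]]) - 1L
    inb <- !is.na(b1) & !is.na(b2)
    idx <- (b2[inb] - 1L) * nb1 + b1[inb]
    mass <- numeric(nb1 * nb2)
    msums <- rowsum(w[inb], idx)
    mass[as.integer(rownames(msums))] <- msums
    cnt <- tabulate(idx, nbins = nb1 * nb2)
    dim(mass) <- c(nb1, nb2); dim(cnt) <- c(nb1, nb2)
  }
  F <- -kT * log(mass)
  F[!is.finite(F)] <- NA_real_
  F[cnt < min_count] <- NA_real_
  F <- F - min(F, na.rm = TRUE)
  out <- new_fes(F, cnt, bin_edges, kT)
  out$dropped_fraction <- 1 - mean(ok)
  out
}

#' Plain (unweighted) histogram free energy
#'
#' Boltzmann inversion of the raw histogram — the equilibrium-sampling
#' baseline the reweighted surface is compared against.
#'
#' @inheritParams reweighted_fes
#' @return A `free_energy_surface`.
#' @export
histogram_fes <- function(coords, bin_edges, kT = kT_at(310)) {
  coords <- .as_matrix(coords)
  if (is.numeric(bin_edges)) bin_edges <- list(bin_edges)
  n <- nrow(coords)
  dummy_model <- new_msm(matrix(1, 1, 1), 1, 1L, 1L)
  reweighted_fes(coords, rep(1L, n), dummy_model, bin_edges, kT)
}

#' Per-bin bootstrap error of a free-energy surface
#'
#' Sample standard deviation over per-round surfaces, after shifting each
#' round to its own minimum (free energies are defined up to a constant,
#' so a per-round min-shift happens first — constant offsets between
#' rounds do not count as error). Bins defined in fewer than half the
#' rounds are marked undefined.
#'
#' @param surfaces List of `free_energy_surface`s on identical grids
#'   (e.g. one per bootstrap MSM).
#' @return Matrix/vector of per-bin standard deviations (kcal/mol), `NA`
#'   where undefined.
#' @export
fes_error <- function(surfaces) {
  stopifnot(length(surfaces) >= 2)
  mats <- lapply(surfaces, function(s) {
    f <- s$F
    f - min(f, na.rm = TRUE)
  })
  arr <- simplify2array(mats)
  nd <- length(dim(arr))
  defined <- apply(!is.na(arr), seq_len(nd - 1L), mean)
  err <- apply(arr, seq_len(nd - 1L), stats::sd, na.rm = TRUE)
  err[defined < 0.5] <- NA_real_
  err
}

#' Minimax (minimum-energy) path across a free-energy surface
#'
#' Finds the path from `start_bin` to `end_bin` through defined bins
#' (8-connected in 2D) that minimizes the maximum free energy encountered
#' — the widest-path variant of Dijkstra. Among paths with equal minimax
#' value, the one with the smallest cumulative free energy wins. The
#' reported barrier is `max(F along path) - F(start)`. This "lowest
#' highest-energy" path is the operational minimum-energy path: its
#' maximum is exactly the saddle a transition must cross.
#'
#' @param fes A `free_energy_surface` (1D or 2D).
#' @param start_bin,end_bin Bin indices: integer (1D) or length-2 integer
#'   (2D, `c(row, col)` in the `F` matrix).
#' @param mask Optional logical array (same shape as `fes$F`): FALSE bins
#'   are excluded, e.g. to confine the path to one channel.
#' @return A `path_result`: `bins` (matrix of bin indices along the path),
#'   `F_along`, `barrier`.
#' @export
minimax_path <- function(fes, start_bin, end_bin, mask = NULL) {
  F <- fes$F
  if (is.null(dim(F))) F <- matrix(F, ncol = 1L)
  nr <- nrow(F); nc <- ncol(F)
  start_bin <- as.integer(start_bin); end_bin <- as.integer(end_bin)
  if (length(start_bin) == 1L) start_bin <- c(start_bin, 1L)
  if (length(end_bin) == 1L) end_bin <- c(end_bin, 1L)
  sid <- (start_bin[2] - 1L) * nr + start_bin[1]
  eid <- (end_bin[2] - 1L) * nr + end_bin[1]
  ok <- !is.na(F)
  if (!is.null(mask)) ok <- ok & mask
  if (!ok[sid] || !ok[eid])
    stop("start or end bin undefined (or masked out)", call. = FALSE)
  n <- nr * nc
  bottleneck <- rep(Inf, n); cum <- rep(Inf, n); prev <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  bottleneck[sid] <- F[sid]; cum[sid] <- F[sid]
  # neighbour offsets: 8-connectivity (degenerates to 2 in 1D)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  repeat {
    cand <- which(!visited & is.finite(bottleneck))
    if (!length(cand)) break
    u <- cand[order(bottleneck[cand], cum[cand])][1L]
    if (u == eid) break
    visited[u] <- TRUE
    ur <- (u - 1L) %% nr + 1L; uc <- (u - 1L) %/% nr + 1L
    for (o in seq_len(nrow(offs))) {
      vr <- ur + offs$dr[o]; vc <- uc + offs$dc[o]
      if (vr < 1L || vr > nr || vc < 1L || vc > nc) next
      v <- (vc - 1L) * nr + vr
      if (visited[v] || !ok[v]) next
      nb <- max(bottleneck[u], F[v])
      ncum <- cum[u] + F[v]
      if (nb < bottleneck[v] || (nb == bottleneck[v] && ncum < cum[v])) {
        bottleneck[v] <- nb; cum[v] <- ncum; prev[v] <- u
      }
    }
  }
  if (!is.finite(bottleneck[eid]))
    stop("start and end bins are disconnected through defined bins",
         call. = FALSE)
  path <- eid
  while (path[1L] != sid) path <- c(prev[path[1L]], path)
  bins <- cbind(row = (path - 1L) %% nr + 1L, col = (path - 1L) %/% nr + 1L)
  F_along <- F[path]
  structure(list(bins = bins, F_along = F_along,
                 barrier = max(F_along) - F_along[1L]),
            class = "path_result")
}

#' @export
print.path_result <- function(x, ...) {
  cat(sprintf("Minimax path: %d bins, barrier %.3f kcal/mol\n",
              nrow(x$bins), x$barrier))
  invisible(x)
}

# vectorized 8-connected flood fill: is eid reachable from sid through
# `allowed` cells?
.flood_connected <- function(allowed, sid, eid) {
  nr <- nrow(allowed); nc <- ncol(allowed)
  reach <- matrix(FALSE, nr, nc)
  reach[sid] <- TRUE
  repeat {
    grown <- reach
    # 4 + 4 diagonal shifts
    grown[-1, ] <- grown[-1, ] | reach[-nr, ]
    grown[-nr, ] <- grown[-nr, ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -nc]
    grown[, -nc] <- grown[, -nc] | reach[, -1]
    grown[-1, -1] <- grown[-1, -1] | reach[-nr, -nc]
    grown[-nr, -nc] <- grown[-nr, -nc] | reach[-1, -1]
    grown[-1, -nc] <- grown[-1, -nc] | reach[-nr, -1]
    grown[-nr, -1] <- grown[-nr, -1] | reach[-1, -nc]
    grown <- grown & allowed
    if (grown[eid]) return(TRUE)
    if (identical(grown, reach)) return(FALSE)
    reach <- grown
  }
}

# barrier-only minimax by bisection over the sorted energy levels
.minimax_barrier_fast <- function(F, sid, eid, ok) {
  vals <- sort(unique(F[ok]))
  lo <- max(F[sid], F[eid])
  vals <- vals[vals >= lo]
  loi <- 1L; hii <- length(vals)
  if (.flood_connected(ok & F <= vals[loi], sid, eid))
    return(vals[loi] - F[sid])
  while (hii - loi > 1L) {
    mid <- (loi + hii) %/% 2L
    if (.flood_connected(ok & F <= vals[mid], sid, eid)) hii <- mid
    else loi <- mid
  }
  if (!.flood_connected(ok & F <= vals[hii], sid, eid))
    stop("start and end bins are disconnected through defined bins",
         call. = FALSE)
  vals[hii] - F[sid]
}

#' Per-channel barriers of a two-channel free-energy surface
#'
#' Splits the surface at `split_at` along dimension `split_dim` and runs a
#' minimax path within each half from the lowest defined bin on the
#' start side (dimension 1 below `progress_split`) to the lowest defined
#' bin on the end side.
#'
#' @param fes 2D `free_energy_surface` whose first dimension is the
#'   translocation progress coordinate and second the channel coordinate.
#' @param split_at Channel-coordinate value separating the channels
#'   (default 0).
#' @param progress_split Progress value separating start/end basins
#'   (default 0).
#' @param fast If TRUE (default) compute barriers only, by bisection over
#'   energy levels with flood-fill connectivity — same value as the
#'   minimax path, much faster on large grids or in bootstrap loops.
#' @return Named numeric: barriers of the channel above (`a`) and below
#'   (`b`) the split, kcal/mol.
#' @export
channel_barriers <- function(fes, split_at = 0, progress_split = 0,
                             fast = TRUE) {
  stopifnot(fes$dims == 2L)
  ctr <- fes_centers(fes)
  up <- outer(rep(TRUE, length(ctr[[1]])), ctr[[2]] > split_at)
  dn <- !up
  one <- function(msk) {
    Fm <- fes$F
    Fm[!msk] <- NA_real_
    sideS <- outer(ctr[[1]] < progress_split, rep(TRUE, length(ctr[[2]]))) & msk
    sideE <- outer(ctr[[1]] > progress_split, rep(TRUE, length(ctr[[2]]))) & msk
    if (all(is.na(Fm[sideS])) || all(is.na(Fm[sideE])))
      stop("a channel side has no defined bins", call. = FALSE)
    s_idx <- which(sideS & Fm == min(Fm[sideS], na.rm = TRUE))[1L]
    e_idx <- which(sideE & Fm == min(Fm[sideE], na.rm = TRUE))[1L]
    if (fast)
      .minimax_barrier_fast(Fm, s_idx, e_idx, !is.na(Fm))
    else
      minimax_path(fes, arrayInd(s_idx, dim(Fm)), arrayInd(e_idx, dim(Fm)),
                   mask = msk)$barrier
  }
  c(a = one(up), b = one(dn))
}

#' Compare two bootstrap barrier ensembles
#'
#' Means and standard deviations of per-round barriers plus a two-sided
#' Welch t-test for equality of the two ensembles' means.
#'
#' @param barriers_a,barriers_b Numeric vectors of bootstrap barrier
#'   values (>= 10 each).
#' @return A `barrier_comparison`: `barrier_a`, `barrier_b` (with `sd_a`,
#'   `sd_b`), `delta` (a - b), `p_value`.
#' @export
compare_barriers <- function(barriers_a, barriers_b) {
  stopifnot(length(barriers_a) >= 10, length(barriers_b) >= 10)
  va <- stats::var(barriers_a); vb <- stats::var(barriers_b)
  if (va == 0 && vb == 0) {
    p <- if (isTRUE(all.equal(mean(barriers_a), mean(barriers_b)))) 1 else 0
  } else {
    p <- stats::t.test(barriers_a, barriers_b)$p.value
  }
  structure(list(barrier_a = mean(barriers_a), sd_a = stats::sd(barriers_a),
                 barrier_b = mean(barriers_b), sd_b = stats::sd(barriers_b),
                 delta = mean(barriers_a) - mean(barriers_b),
                 p_value = p,
                 n_a = length(barriers_a), n_b = length(barriers_b)),
            class = "barrier_comparison")
}

#' @export
print.barrier_comparison <- function(x, ...) {
  cat(sprintf("Barriers: %.2f +/- %.2f vs %.2f +/- %.2f kcal/mol (delta %.2f, p = %.3g)\n",
              x$barrier_a, x$sd_a, x$barrier_b, x$sd_b, x$delta, x$p_value))
  invisible(x)
}

#' Write a free-energy surface as CSV
#'
#' One row per bin: centre coordinates, `F`, counts, and `F_err` when
#' present.
#'
#' @param fes A `free_energy_surface`.
#' @param file Path.
#' @export
write_fes_csv <- function(fes, file) {
  ctr <- fes_centers(fes)
  if (fes$dims == 1L) {
    df <- data.frame(x = ctr[[1]], F = as.numeric(fes$F),
                     n = as.numeric(fes$counts))
  } else {
    g <- expand.grid(x = ctr[[1]], y = ctr[[2]])
    df <- data.frame(g, F = as.numeric(fes$F), n = as.numeric(fes$counts))
  }
  if (!is.null(fes$F_err)) df$F_err <- as.numeric(fes$F_err)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
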