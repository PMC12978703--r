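# Markov state model estimation: sliding-window counts, connectivity
# trimming, reversible maximum-likelihood transition matrices.

.as_dtraj_list <- function(dtrajs) {
  if (inherits(dtrajs, "discretization")) return(dtrajs$dtrajs)
  if (is.list(dtrajs)) return(lapply(dtrajs, as.integer))
  list(as.integer(dtrajs))
}

#' Sliding-window transition counts
#'
#' Counts pairs `(t, t + lag)` within each discrete trajectory; pairs are
#' never formed across trajectory boundaries.
#'
#' @param dtrajs A `discretization`, a list of integer vectors, or one
#'   integer vector (1-based state labels).
#' @param lag Lag in frames (>= 1).
#' @param n_states Number of states (default: maximum observed label).
#' @return A `count_matrix`: list with `counts` (k x k), `lag`, `mode`
#'   (`"sliding"`), and `n_states`.
#' @export
count_transitions <- function(dtrajs, lag, n_states = NULL) {
  dt <- .as_dtraj_list(dtrajs)
  .check_scalar(lag, "lag", positive = TRUE)
  if (is.null(n_states)) n_states <- max(unlist(dt, use.names = FALSE))
  if (!any(vapply(dt, length, integer(1)) > lag))
    stop("no countable pairs: all trajectories are shorter than the lag",
         call. = FALSE)
  C <- matrix(0, n_states, n_states)
  for (d in dt)
    if (length(d) > lag)
      C <- C + count_pairs_cpp(d, as.integer(lag), as.integer(n_states))
  structure(list(counts = C, lag = as.integer(lag), mode = "sliding",
                 n_states = as.integer(n_states)),
            class = "count_matrix")
}

#' Largest strongly connected set of a count matrix
#'
#' States in the largest strongly connected component of the directed
#' graph with an edge wherever `counts > 0`. Among equally large
#' components the one containing the lowest state index wins.
#'
#' @param C A `count_matrix` or a non-negative square matrix.
#' @return Sorted integer vector of state indices (1-based).
#' @export
largest_connected_set <- function(C) {
  M <- if (inherits(C, "count_matrix")) C$counts else as.matrix(C)
  if (!nrow(M)) stop("empty count matrix", call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix((M > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie: component containing the lowest state index
    first_member <- vapply(best, function(b) min(which(comp$membership == b)),
                           integer(1))
    best <- best[which.min(first_member)]
  }
  sort(which(comp$membership == best))
}

new_msm <- function(T, pi, lag, active_set, frame_time = 1,
                    estimator = "reversible_mle", meta = list()) {
  stopifnot(all(abs(rowSums(T) - 1) < 1e-12))
  structure(list(T = T, pi = pi, lag = as.integer(lag),
                 active_set = as.integer(active_set),
                 frame_time = frame_time, estimator = estimator,
                 meta = meta),
            class = "msm_model")
}

#' @export
print.msm_model <- function(x, ...) {
  cat(sprintf("MSM: %d active states, lag %d frames (%.4g ns), estimator %s\n",
              nrow(x$T), x$lag, x$lag * x$frame_time, x$estimator))
  ev <- msm_eigenvalues(x, min(4L, nrow(x$T)))
  cat("  leading eigenvalues:", paste(signif(ev, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Reversible maximum-likelihood MSM estimation
#'
#' Maximum-likelihood transition matrix satisfying detailed balance, by
#' fixed-point iteration on the symmetric auxiliary variables
#' `x_ij <- (c_ij + c_ji) / (c_i / x_i + c_j / x_j)` until the maximum
#' relative change falls below `tol`. The stationary distribution comes
#' from the row sums of `x`.
#'
#' @param C A `count_matrix` (or plain matrix); estimation runs on the
#'   largest component of the symmetrized count graph (`C + t(C)`), the
#'   connectivity the reversible estimator actually requires — a pair of
#'   states is estimable as soon as transitions are observed in either
#'   direction, detailed balance supplying the reverse rate.
#' @param tol Convergence threshold on the maximum relative change
#'   (default 1e-10).
#' @param max_iter Sweep cap (default 1e6); non-convergence at the cap is
#'   an error reporting the residual.
#' @param frame_time Physical time per frame (ns) so lag and timescales
#'   are reportable in physical units.
#' @return An `msm_model` with row-stochastic `T`, stationary `pi`
#'   (`pi %*% T = pi` within 1e-10), `lag`, `active_set`, `frame_time`.
#' @export
estimate_reversible <- function(C, tol = 1e-10, max_iter = 1e6,
                                frame_time = 1) {
  cm <- if (inherits(C, "count_matrix")) C
        else structure(list(counts = as.matrix(C), lag = 1L,
                            n_states = nrow(as.matrix(C))),
                       class = "count_matrix")
  active <- largest_connected_set(cm$counts + t(cm$counts))
  M <- cm$counts[active, active, drop = FALSE]
  csym <- M + t(M)
  ci <- rowSums(M)
  fp <- reversible_mle_cpp(csym, ci, tol, max_iter)
  if (!fp$converged)
    stop(sprintf("reversible MLE did not converge: residual %.3g after %d sweeps",
                 fp$residual, as.integer(fp$iterations)), call. = FALSE)
  x <- fp$x
  it <- fp$iterations
  res <- fp$residual
  xi <- rowSums(x)
  T <- x / xi
  # exact row normalization against accumulated round-off
  T <- T / rowSums(T)
  pi <- xi / sum(xi)
  new_msm(T, pi, cm$lag, active, frame_time = frame_time,
          meta = list(sweeps = it, residual = res,
                      counted_frames = sum(cm$counts),
                      active_fraction = sum(cm$counts[active, active]) / sum(cm$counts)))
}

#' Eigenvalues of a reversible MSM
#'
#' Computed through the symmetrized similarity transform
#' `diag(sqrt(pi)) T diag(1/sqrt(pi))`, so the spectrum is real and sorted
#' descending.
#'
#' @param model An `msm_model`.
#' @param k Number of leading eigenvalues (default all).
#' @return Numeric vector, descending; the first entry is 1.
#' @export
msm_eigenvalues <- function(model, k = NULL) {
  s <- sqrt(model$pi)
  S <- (model$T * outer(s, 1 / s)) # diag(s) %*% T %*% diag(1/s)
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (!is.null(k)) ev <- ev[seq_len(min(k, length(ev)))]
  ev
}

#' Implied timescales of an estimated model
#'
#' `t_i = -tau / ln(lambda_i)` for the leading non-unit eigenvalues, in
#' physical time. Eigenvalues above `1 - 1e-12` give `Inf`.
#'
#' @param model An `msm_model`.
#' @param n_timescales Number of timescales.
#' @return Numeric vector of timescales (physical time units).
#' @export
model_timescales <- function(model, n_timescales = 5L) {
  ev <- msm_eigenvalues(model)[-1]
  ev <- ev[seq_len(min(n_timescales, length(ev)))]
  tau <- model$lag * model$frame_time
  ts <- ifelse(ev >= 1 - 1e-12, Inf,
               ifelse(ev <= 0, NA_real_, -tau / log(ev)))
  ts
}

#' Implied timescales as a function of lag
#'
#' Estimates a reversible MSM at each lag and reports the top implied
#' timescales; flat curves beyond some lag indicate Markovian behaviour at
#' that lag (the usual lag-selection diagnostic).
#'
#' @param dtrajs Discrete trajectories (see [count_transitions()]).
#' @param lags Integer vector of lags (frames).
#' @param n_timescales Timescales per lag.
#' @param frame_time Physical time per frame.
#' @return An `its_result`: data.frame with columns `lag`, `timescale_1`..
#' @export
implied_timescales <- function(dtrajs, lags, n_timescales = 3L,
                               frame_time = 1) {
  rows <- lapply(lags, function(L) {
    m <- tryCatch(
      estimate_reversible(count_transitions(dtrajs, L),
                          frame_time = frame_time),
      error = function(e) NULL)
    ts <- if (is.null(m)) rep(NA_real_, n_timescales)
          else {
            v <- model_timescales(m, n_timescales)
            c(v, rep(NA_real_, n_timescales - length(v)))
          }
    c(lag = L, ts)
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("lag", paste0("timescale_", seq_len(n_timescales)))
  class(out) <- c("its_result", "data.frame")
  out
}

#' VAMP2 score of an MSM
#'
#' Sum of squares of the largest `min(k_top, n_states)` transition-matrix
#' eigenvalues, including the unit eigenvalue — so any valid model scores
#' at least 1.
#'
#' @param model An `msm_model`.
#' @param k_top Number of eigenvalues (default 5).
#' @return Numeric score.
#' @export
vamp2_score <- function(model, k_top = 5L) {
  ev <- msm_eigenvalues(model, k_top)
  sum(ev^2)
}

#' Grid search over the number of cluster states
#'
#' For each candidate `k`: discretize the projected data by k-means,
#' estimate a reversible MSM at `lag`, and score it with VAMP2; the best
#' `k` maximizes the score. Candidates whose MSM fails (e.g. loses
#' connectivity) score `NA` rather than aborting the search.
#'
#' @param X Projected data (matrix, `feature_matrix`, or list of
#'   per-trajectory matrices).
#' @param k_candidates Integer vector of candidate state counts (each >= 2).
#' @param lag MSM lag in frames.
#' @param seed Master seed; each candidate uses a derived seed.
#' @param k_top VAMP2 truncation.
#' @param frame_time Physical time per frame.
#' @return List with `best_k` and `scores` (data.frame `k`, `vamp2`).
#' @export
grid_search_states <- function(X, k_candidates, lag, seed = 1L, k_top = 5L,
                               frame_time = 1) {
  stopifnot(all(k_candidates >= 2))
  scores <- vapply(seq_along(k_candidates), function(i) {
    k <- k_candidates[i]
    tryCatch({
      disc <- kmeans_fit(X, k, seed = derive_seed(seed, "grid", i))
      m <- estimate_reversible(count_transitions(disc, lag),
                               frame_time = frame_time)
      vamp2_score(m, k_top)
    }, error = function(e) NA_real_)
  }, numeric(1))
  tab <- data.frame(k = k_candidates, vamp2 = scores)
  best <- if (all(is.na(scores))) NA_integer_
          else k_candidates[which.max(scores)]
  list(best_k = best, scores = tab)
}

#' Bootstrap ensemble of MSMs
#'
#' Re-estimates the MSM `n_rounds` times, each time on
#' `ceil(fraction * n_traj)` trajectories drawn without replacement —
#' whole trajectories, to respect temporal correlation. All rounds share
#' the full-data state definition; states disconnected in a round are
#' inactive for that round, and rounds whose count matrix has no usable
#' pairs are skipped and counted.
#'
#' @param dtrajs Discrete trajectories (>= 2).
#' @param n_rounds Bootstrap rounds (default 200).
#' @param fraction Fraction of trajectories per round (default 0.8).
#' @param lag MSM lag in frames.
#' @param seed Master seed.
#' @param n_states Shared state-space size (default from data).
#' @param frame_time Physical time per frame.
#' @return A `bootstrap_ensemble`: list of `msm_model`s plus metadata
#'   (`n_rounds`, `fraction`, `seed`, `n_skipped`).
#' @export
bootstrap_msm <- function(dtrajs, n_rounds = 200L, fraction = 0.8, lag,
                          seed = 1L, n_states = NULL, frame_time = 1,
                          tol = 1e-10) {
  dt <- .as_dtraj_list(dtrajs)
  if (length(dt) < 2L)
    stop("bootstrap requires at least two trajectories", call. = FALSE)
  if (is.null(n_states)) n_states <- max(unlist(dt, use.names = FALSE))
  n_take <- ceiling(fraction * length(dt))
  # per-trajectory count matrices once; each round sums a subset
  per_traj <- lapply(dt, function(d)
    if (length(d) > lag) count_pairs_cpp(d, as.integer(lag),
                                         as.integer(n_states))
    else matrix(0, n_states, n_states))
  models <- vector("list", n_rounds)
  skipped <- 0L
  for (r in seq_len(n_rounds)) {
    set.seed(derive_seed(seed, "bootstrap", r))
    idx <- sample.int(length(dt), n_take)
    C <- Reduce(`+`, per_traj[idx])
    cm <- structure(list(counts = C, lag = as.integer(lag),
                         mode = "sliding", n_states = as.integer(n_states)),
                    class = "count_matrix")
    m <- tryCatch(
      estimate_reversible(cm, frame_time = frame_time, tol = tol),
      error = function(e) NULL)
    if (is.null(m)) skipped <- skipped + 1L
    models[[r]] <- m
  }
  structure(list(models = models[!vapply(models, is.null, logical(1))],
                 n_rounds = as.integer(n_rounds), fraction = fraction,
                 seed = as.integer(seed), n_skipped = skipped,
                 lag = as.integer(lag), n_states = as.integer(n_states),
                 frame_time = frame_time),
            class = "bootstrap_ensemble")
}

#' @export
print.bootstrap_ensemble <- function(x, ...) {
  cat(sprintf("Bootstrap ensemble: %d/%d rounds (fraction %.2f, %d skipped)\n",
              length(x$models), x$n_rounds, x$fraction, x$n_skipped))
  invisible(x)
}

# stationary-weighted set-to-set transition probability under T^k
.set_transition <- function(T, pi, states, A, B, k = 1L) {
  Tk <- T
  if (k > 1L) for (i in seq_len(k - 1L)) Tk <- Tk %*% T
  ia <- which(states %in% A)
  ib <- which(states %in% B)
  if (!length(ia) || !length(ib)) return(NA_real_)
  w <- pi[ia] / sum(pi[ia])
  sum(w * rowSums(Tk[ia, ib, drop = FALSE]))
}

#' Chapman-Kolmogorov test
#'
#' Compares set-to-set transition probabilities predicted by `T(tau)^k`
#' against probabilities re-estimated from the data at lag `k * tau`, for
#' each factor `k`, with bootstrap confidence bands on the re-estimated
#' values. Agreement across factors is the standard check that the model
#' is Markovian at its lag.
#'
#' @param model Reference `msm_model` at lag `tau`.
#' @param dtrajs The discrete trajectories the model was estimated from.
#' @param macro_sets Named list of disjoint, non-empty state sets
#'   (1-based, in the full state numbering).
#' @param factors Integer factors `k` (default 1:5); `k * tau` must fit in
#'   the data.
#' @param n_boot Bootstrap rounds for the bands (default 100).
#' @param conf Band coverage (default 0.95).
#' @param seed Master seed for the bootstrap.
#' @return A `ck_result`: data.frame with columns `factor`, `from`, `to`,
#'   `predicted`, `estimated`, `lower`, `upper`.
#' @export
ck_test <- function(model, dtrajs, macro_sets, factors = 1:5,
                    n_boot = 100L, conf = 0.95, seed = 1L) {
  stopifnot(inherits(model, "msm_model"), length(macro_sets) >= 2)
  if (is.null(names(macro_sets)))
    names(macro_sets) <- paste0("set", seq_along(macro_sets))
  if (length(unique(unlist(macro_sets))) != length(unlist(macro_sets)))
    stop("macro sets must be disjoint", call. = FALSE)
  dt <- .as_dtraj_list(dtrajs)
  n_states <- model$meta$n_states %||% max(unlist(dt, use.names = FALSE))
  alpha <- (1 - conf) / 2
  rows <- list()
  for (k in factors) {
    lag_k <- model$lag * k
    if (!any(vapply(dt, length, integer(1)) > lag_k))
      stop(sprintf("factor %d exceeds trajectory lengths", k), call. = FALSE)
    est_model <- estimate_reversible(count_transitions(dt, lag_k, n_states),
                                     frame_time = model$frame_time)
    boots <- lapply(seq_len(n_boot), function(b) {
      set.seed(derive_seed(seed, "ck", k * 1000L + b))
      idx <- sample.int(length(dt), length(dt), replace = TRUE)
      tryCatch(
        estimate_reversible(count_transitions(dt[idx], lag_k, n_states),
                            frame_time = model$frame_time),
        error = function(e) NULL)
    })
    boots <- boots[!vapply(boots, is.null, logical(1))]
    for (a in names(macro_sets)) for (b in names(macro_sets)) {
      pred <- .set_transition(model$T, model$pi, model$active_set,
                              macro_sets[[a]], macro_sets[[b]], k)
      est <- .set_transition(est_model$T, est_model$pi, est_model$active_set,
                             macro_sets[[a]], macro_sets[[b]], 1L)
      bs <- vapply(boots, function(m)
        .set_transition(m$T, m$pi, m$active_set,
                        macro_sets[[a]], macro_sets[[b]], 1L), numeric(1))
      bs <- bs[is.finite(bs)]
      qs <- if (length(bs) >= 10)
        stats::quantile(bs, c(alpha, 1 - alpha), names = FALSE)
      else c(NA_real_, NA_real_)
      rows[[length(rows) + 1L]] <-
        data.frame(factor = k, from = a, to = b, predicted = pred,
                   estimated = est, lower = qs[1], upper = qs[2])
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ck_result", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize an MSM to JSON
#'
#' @param model An `msm_model`.
#' @param file Path.
#' @return `read_msm_json` returns an `msm_model`.
#' @export
write_msm_json <- function(model, file) {
  jsonlite::write_json(
    list(T = model$T, pi = model$pi, lag = model$lag,
         active_set = model$active_set, frame_time = model$frame_time,
         estimator = model$estimator),
    file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_msm_json
#' @export
read_msm_json <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  new_msm(as.matrix(j$T), j$pi, j$lag, j$active_set,
          frame_time = j$frame_time, estimator = j$estimator)
}
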