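# Transition path theory on estimated MSMs: committors, reactive fluxes,
# rates, mean first passage times.

.check_sets <- function(model, A, B, disjoint = TRUE) {
  states <- seq_len(nrow(model$T))
  A <- as.integer(A); B <- as.integer(B)
  if (!length(A) || !length(B))
    stop("A and B must be non-empty", call. = FALSE)
  if (!all(A %in% states) || !all(B %in% states))
    stop("A/B contain states outside the active set (use active-set indices)",
         call. = FALSE)
  if (disjoint && length(intersect(A, B)))
    stop("A and B must be disjoint", call. = FALSE)
  list(A = A, B = B)
}

#' Forward and backward committors
#'
#' Solves the committor linear system: `q+` is the probability of reaching
#' `B` before `A`; with boundary conditions `q+ = 0` on `A`, `1` on `B`,
#' and `q+_i = sum_j T_ij q+_j` on the intermediate states. For reversible
#' models the backward committor is `q- = 1 - q+`.
#'
#' State indices refer to the model's active-set positions (1-based rows
#' of `model$T`).
#'
#' @param model An `msm_model`.
#' @param A,B Disjoint, non-empty state sets.
#' @return A `committor_result`: `q_plus`, `q_minus`, `A`, `B`.
#' @export
committor <- function(model, A, B) {
  s <- .check_sets(model, A, B)
  T <- model$T
  n <- nrow(T)
  q <- numeric(n)
  q[s$B] <- 1
  inter <- setdiff(seq_len(n), c(s$A, s$B))
  if (length(inter)) {
    M <- diag(length(inter)) - T[inter, inter, drop = FALSE]
    rhs <- rowSums(T[inter, s$B, drop = FALSE])
    sol <- tryCatch(solve(M, rhs), error = function(e)
      stop("singular committor system (is B reachable?)", call. = FALSE))
    q[inter] <- sol
  }
  structure(list(q_plus = q, q_minus = 1 - q, A = s$A, B = s$B),
            class = "committor_result")
}

#' Reactive flux network (transition path theory)
#'
#' Gross reactive flux `f_ij = pi_i q-_i T_ij q+_j` (i != j), net flux
#' `max(0, f_ij - f_ji)`, total A->B flux `F = sum_{i in A, j not in A}
#' f_ij`, and rate `k_AB = F / (lag_time * sum_i pi_i q-_i)`.
#'
#' @param model An `msm_model`.
#' @param committors A `committor_result` from the same model/sets.
#' @return A `flux_network`: `gross` and `net` matrices (per lag time),
#'   `total_flux`, `rate` (per physical time unit), `A`, `B`.
#' @export
reactive_flux <- function(model, committors) {
  stopifnot(inherits(committors, "committor_result"))
  T <- model$T; pi <- model$pi
  qp <- committors$q_plus; qm <- committors$q_minus
  f <- (pi * qm) * T * rep(qp, each = nrow(T))
  diag(f) <- 0
  net <- pmax(f - t(f), 0)
  A <- committors$A
  total <- sum(f[A, setdiff(seq_len(nrow(T)), A), drop = FALSE])
  lag_time <- model$lag * model$frame_time
  rate <- total / (lag_time * sum(pi * qm))
  structure(list(gross = f, net = net, total_flux = total, rate = rate,
                 A = A, B = committors$B, lag_time = lag_time),
            class = "flux_network")
}

#' @export
print.flux_network <- function(x, ...) {
  cat(sprintf("Reactive flux: total %.4g per lag, rate %.4g per time unit\n",
              x$total_flux, x$rate))
  invisible(x)
}

#' Mean first passage time
#'
#' Solves `m_i = lag_time + sum_j T_ij m_j` for all states outside `B`
#' (with `m = 0` on `B`) and reports the average over `A` under the
#' stationary distribution restricted to `A`.
#'
#' @param model An `msm_model`.
#' @param A Source set (active-set indices).
#' @param B Target set (non-empty; must be reachable).
#' @return An `mfpt_result`: `value` (physical time), `per_state` (full
#'   vector of state MFPTs), `A`, `B`.
#' @export
mfpt <- function(model, A, B) {
  s <- .check_sets(model, A, B, disjoint = FALSE)
  T <- model$T
  n <- nrow(T)
  lag_time <- model$lag * model$frame_time
  m <- numeric(n)
  free <- setdiff(seq_len(n), s$B)
  if (length(free)) {
    M <- diag(length(free)) - T[free, free, drop = FALSE]
    sol <- tryCatch(solve(M, rep(lag_time, length(free))),
                    error = function(e)
                      stop("B unreachable from some source state", call. = FALSE))
    m[free] <- sol
  }
  Ao <- setdiff(s$A, s$B)
  if (!length(Ao)) Ao <- s$A
  w <- model$pi[Ao] / sum(model$pi[Ao])
  structure(list(value = sum(w * m[Ao]), per_state = m, err = NA_real_,
                 A = s$A, B = s$B, unit = "frame_time units"),
            class = "mfpt_result")
}

#' @export
print.mfpt_result <- function(x, ...) {
  if (is.na(x$err))
    cat(sprintf("MFPT: %.4g time units\n", x$value))
  else
    cat(sprintf("MFPT: %.4g +/- %.4g time units (%d rounds, %d skipped)\n",
                x$value, x$err, x$n_rounds, x$n_skipped))
  invisible(x)
}

#' MFPT with bootstrap error
#'
#' Mean and standard deviation of the MFPT over a bootstrap ensemble of
#' models. `A` and `B` are given in the full (shared) state numbering;
#' rounds in which the sets are not fully contained in the round's active
#' set, or `B` is unreachable, are skipped and counted.
#'
#' @param ensemble A `bootstrap_ensemble`.
#' @param A,B State sets in the full state numbering.
#' @param min_valid Minimum valid rounds required (default 10).
#' @return An `mfpt_result` with `value`, `err`, `n_rounds`, `n_skipped`.
#' @export
mfpt_with_error <- function(ensemble, A, B, min_valid = 10L) {
  stopifnot(inherits(ensemble, "bootstrap_ensemble"))
  vals <- vapply(ensemble$models, function(m) {
    Ai <- match(A, m$active_set); Bi <- match(B, m$active_set)
    if (anyNA(Bi) || all(is.na(Ai))) return(NA_real_)
    Ai <- Ai[!is.na(Ai)]
    tryCatch(mfpt(m, Ai, Bi)$value, error = function(e) NA_real_)
  }, numeric(1))
  ok <- is.finite(vals)
  if (sum(ok) < min_valid)
    stop(sprintf("only %d valid bootstrap rounds (need %d)", sum(ok),
                 min_valid), call. = FALSE)
  structure(list(value = mean(vals[ok]), err = stats::sd(vals[ok]),
                 per_state = NULL, A = A, B = B,
                 n_rounds = length(vals), n_skipped = sum(!ok),
                 unit = "frame_time units"),
            class = "mfpt_result")
}

#' Write a flux network as an edge-list CSV
#'
#' @param flux A `flux_network`.
#' @param file Path.
#' @param min_flux Drop edges with gross flux below this.
#' @export
write_flux_csv <- function(flux, file, min_flux = 0) {
  idx <- which(flux$gross > min_flux, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2],
                   gross = flux$gross[idx], net = flux$net[idx])
  df <- df[order(-df$gross), ]
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
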