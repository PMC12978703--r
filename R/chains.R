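# Discrete Markov chains and OU feature mixtures: oracle fixtures for the
# MSM and tICA estimators.

.check_stochastic <- function(T, tol = 1e-12) {
  T <- as.matrix(T)
  if (nrow(T) != ncol(T)) stop("transition matrix must be square", call. = FALSE)
  if (any(T < -tol)) stop("transition matrix has negative entries", call. = FALSE)
  if (any(abs(rowSums(T) - 1) > tol))
    stop("rows of the transition matrix must sum to 1", call. = FALSE)
  T
}

#' Sample a discrete Markov chain
#'
#' @param T Row-stochastic transition matrix (rows sum to 1 within 1e-12).
#' @param n_steps Number of transitions; the returned sequence has
#'   `n_steps + 1` states including the start.
#' @param seed Integer seed.
#' @param start_state Starting state (1-based).
#' @return Integer vector of 1-based states.
#' @export
make_markov_chain <- function(T, n_steps, seed = 1L, start_state = 1L) {
  T <- .check_stochastic(T)
  stopifnot(start_state >= 1L, start_state <= nrow(T))
  set.seed(seed)
  sample_chain_cpp(T, as.integer(n_steps), as.integer(start_state) - 1L) + 1L
}

#' Sample empirical first-passage times of a Markov chain
#'
#' Monte-Carlo oracle for mean-first-passage-time estimators: repeatedly
#' samples the chain from `start` until it first hits the target set.
#'
#' @param T Row-stochastic matrix.
#' @param start Start state (1-based).
#' @param B Target set (1-based states).
#' @param n_chains Number of independent chains.
#' @param seed Integer seed.
#' @param max_steps Abort a chain after this many steps (returned as NA).
#' @return Numeric vector of first-passage step counts.
#' @export
sample_first_passage <- function(T, start, B, n_chains = 1e5, seed = 1L,
                                 max_steps = 1e7) {
  T <- .check_stochastic(T)
  set.seed(seed)
  first_passage_cpp(T, as.integer(start) - 1L, as.integer(B) - 1L,
                    as.integer(n_chains), as.integer(max_steps))
}

#' Linearly mixed Ornstein-Uhlenbeck feature channels
#'
#' Generates independent discrete-time OU (AR(1)) channels
#' `y_t = exp(-1/tau_c) y_{t-1} + noise` with unit stationary variance and
#' mixes them with a full-rank matrix into observed features. The known
#' relaxation times make this the ground-truth fixture for tICA: at lag
#' `L`, the true tICA eigenvalues are `exp(-L / tau_c)`.
#'
#' @param relaxation_times Per-channel relaxation times, in steps (> 0).
#' @param mixing Square full-rank mixing matrix (default identity);
#'   observed features are `latent %*% t(mixing)`.
#' @param n_steps Number of frames.
#' @param seed Integer seed.
#' @return Matrix of observed features with attribute `"latent"` (the
#'   unmixed channels) and `"relaxation_times"`.
#' @export
make_ou_mixture <- function(relaxation_times, mixing = NULL, n_steps = 1e4,
                            seed = 1L) {
  stopifnot(all(relaxation_times > 0))
  m <- length(relaxation_times)
  if (is.null(mixing)) mixing <- diag(m)
  mixing <- as.matrix(mixing)
  stopifnot(nrow(mixing) == m, ncol(mixing) == m)
  if (abs(det(mixing)) < 1e-12)
    stop("mixing matrix must be full rank", call. = FALSE)
  set.seed(seed)
  a <- exp(-1 / relaxation_times)
  latent <- vapply(seq_len(m), function(j) {
    innov <- stats::rnorm(n_steps, sd = sqrt(1 - a[j]^2))
    y0 <- stats::rnorm(1) # stationary start, unit variance
    as.numeric(stats::filter(c(y0 * a[j] + innov[1], innov[-1]),
                             a[j], method = "recursive", init = 0))
  }, numeric(n_steps))
  # filter() above: y_t = a y_{t-1} + innov_t with y_1 seeded from y0
  observed <- latent %*% t(mixing)
  colnames(observed) <- paste0("f", seq_len(m))
  structure(observed, latent = latent, relaxation_times = relaxation_times)
}
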