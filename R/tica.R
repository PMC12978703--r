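# Time-lagged independent component analysis with reversible (symmetrized)
# covariance estimation.

#' Fit a tICA model
#'
#' Accumulates instantaneous (C0) and time-lagged (Ct) covariances over
#' lagged frame pairs `(t, t + lag)` formed within each trajectory only —
#' never across trajectory breaks. Estimation is symmetrized (reversible):
#' the mean and C0 pool both ends of every pair and Ct is symmetrized as
#' `(Ct + Ct')/2`, which bounds all eigenvalues by 1 in exact arithmetic.
#' A ridge `eps` on the C0 diagonal regularizes degenerate feature sets;
#' the generalized symmetric eigenproblem `Ct v = lambda C0 v` is solved by
#' Cholesky reduction. Components are C0-orthonormal.
#'
#' @param feature_matrices A `feature_matrix`, a numeric matrix, or a list
#'   of per-trajectory matrices (frames x features).
#' @param lag Lag in frames (>= 1); every trajectory must be longer.
#' @param n_components Components to retain (default all).
#' @param eps Ridge added to the C0 diagonal; default
#'   `1e-6 * trace(C0) / n_features`.
#' @param kinetic_map If TRUE, projections are scaled by their eigenvalues
#'   (kinetic-map convention). Default FALSE: plain tIC projection.
#' @return A `tica_model`: mean, eigenvalues (descending, clipped to
#'   `[-1, 1]` with a warning if clipping exceeds 1e-6), components
#'   (features x n_components), lag, eps.
#' @export
fit_tica <- function(feature_matrices, lag, n_components = NULL, eps = NULL,
                     kinetic_map = FALSE) {
  mats <- .as_mat_list(feature_matrices)
  .check_scalar(lag, "lag", positive = TRUE)
  p <- ncol(mats[[1]])
  usable <- vapply(mats, nrow, integer(1)) > lag
  if (!any(usable))
    stop("all trajectories are shorter than the lag", call. = FALSE)
  mats <- mats[usable]
  # pooled mean over both ends of all lagged pairs
  s <- numeric(p); n_pairs <- 0
  for (M in mats) {
    n <- nrow(M)
    X0 <- M[1:(n - lag), , drop = FALSE]
    Xt <- M[(1 + lag):n, , drop = FALSE]
    s <- s + colSums(X0) + colSums(Xt)
    n_pairs <- n_pairs + (n - lag)
  }
  mu <- s / (2 * n_pairs)
  C0 <- matrix(0, p, p); Ct <- matrix(0, p, p)
  for (M in mats) {
    n <- nrow(M)
    X0 <- sweep(M[1:(n - lag), , drop = FALSE], 2, mu)
    Xt <- sweep(M[(1 + lag):n, , drop = FALSE], 2, mu)
    C0 <- C0 + (crossprod(X0) + crossprod(Xt)) / 2
    Ct <- Ct + (crossprod(X0, Xt) + crossprod(Xt, X0)) / 2
  }
  C0 <- C0 / n_pairs
  Ct <- Ct / n_pairs
  if (is.null(eps)) eps <- 1e-6 * sum(diag(C0)) / p
  C0r <- C0 + diag(eps, p)
  U <- tryCatch(chol(C0r), error = function(e)
    stop("C0 not positive definite after regularization", call. = FALSE))
  Ui <- backsolve(U, diag(p))
  Msym <- t(Ui) %*% Ct %*% Ui
  Msym <- (Msym + t(Msym)) / 2
  eg <- eigen(Msym, symmetric = TRUE)
  lambda <- eg$values
  clip <- pmax(pmin(lambda, 1), -1)
  if (max(abs(clip - lambda)) > 1e-6)
    warning("tICA eigenvalues clipped to [-1, 1] by more than 1e-6")
  comps <- Ui %*% eg$vectors
  if (is.null(n_components)) n_components <- p
  n_components <- min(n_components, p)
  structure(list(mean = mu, eigenvalues = clip[seq_len(n_components)],
                 components = comps[, seq_len(n_components), drop = FALSE],
                 lag = as.integer(lag), regularization_eps = eps,
                 n_components = as.integer(n_components),
                 kinetic_map = kinetic_map, n_pairs = n_pairs),
            class = "tica_model")
}

.as_mat_list <- function(x) {
  if (inherits(x, "feature_matrix")) return(split_by_trajectory(x))
  if (is.matrix(x)) return(list(x))
  if (is.list(x)) return(lapply(x, .as_matrix))
  list(.as_matrix(x))
}

#' @export
print.tica_model <- function(x, ...) {
  cat(sprintf("tICA model: %d features -> %d components at lag %d\n",
              length(x$mean), x$n_components, x$lag))
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Project data onto tICA components
#'
#' `(X - mean) %*% components`; with a kinetic-map model the columns are
#' additionally scaled by their eigenvalues.
#'
#' @param model A `tica_model`.
#' @param X A `feature_matrix`, matrix, or list of matrices with the
#'   feature count the model was trained on.
#' @return A matrix (or list of matrices, matching the input shape) of
#'   projections, frames x n_components.
#' @export
tica_transform <- function(model, X) {
  stopifnot(inherits(model, "tica_model"))
  mats <- .as_mat_list(X)
  out <- lapply(mats, function(M) {
    if (ncol(M) != length(model$mean))
      stop("feature count does not match the tICA model", call. = FALSE)
    P <- sweep(M, 2, model$mean) %*% model$components
    if (isTRUE(model$kinetic_map))
      P <- sweep(P, 2, model$eigenvalues, "*")
    colnames(P) <- paste0("tic", seq_len(ncol(P)))
    P
  })
  if (is.matrix(X)) out[[1]] else out
}

#' Serialize / restore a tICA model as JSON
#'
#' @param model A `tica_model`.
#' @param file Path.
#' @return `read_tica_json` returns a `tica_model`.
#' @export
write_tica_json <- function(model, file) {
  jsonlite::write_json(
    list(mean = model$mean, eigenvalues = model$eigenvalues,
         components = model$components, lag = model$lag,
         regularization_eps = model$regularization_eps,
         n_components = model$n_components,
         kinetic_map = model$kinetic_map),
    file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_tica_json
#' @export
read_tica_json <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  structure(list(mean = j$mean, eigenvalues = j$eigenvalues,
                 components = as.matrix(j$components), lag = as.integer(j$lag),
                 regularization_eps = j$regularization_eps,
                 n_components = as.integer(j$n_components),
                 kinetic_map = isTRUE(j$kinetic_map)),
            class = "tica_model")
}
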