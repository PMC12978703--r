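# Analytic model potentials with stored ground truth. Units are fixed
# package-wide: lengths in angstrom, energies in kcal/mol.

new_potential <- function(form, params, dim, domain, analytic_truth = NULL) {
  stopifnot(is.matrix(domain), nrow(domain) == 2L, ncol(domain) == dim,
            all(domain[1, ] < domain[2, ]))
  structure(
    list(form = form, params = params, dim = as.integer(dim),
         domain = domain, analytic_truth = analytic_truth),
    class = "model_potential")
}

#' @export
print.model_potential <- function(x, ...) {
  cat(sprintf("Model potential '%s' (%dD)\n", x$form, x$dim))
  cat("  domain:", paste(sprintf("[%.3g, %.3g]", x$domain[1, ], x$domain[2, ]),
                         collapse = " x "), "\n")
  if (!is.null(x$analytic_truth))
    cat("  analytic truth:",
        paste(names(x$analytic_truth),
              vapply(x$analytic_truth, function(v) paste(signif(unlist(v), 5), collapse = ","), ""),
              sep = "=", collapse = "; "), "\n")
  invisible(x)
}

#' Symmetric (optionally tilted) quartic double-well potential
#'
#' `U(x) = barrier * ((x / half_separation)^2 - 1)^2`, with minima at
#' `+/- half_separation` (where `U = 0`) and `U(0) = barrier`. An optional
#' linear `tilt` lowers the right-hand basin by `tilt` kcal/mol, which is
#' how the tilted fixture that makes the product-side basin more stable is
#' built.
#'
#' @param barrier Barrier height, kcal/mol (> 0). Default 5.8, the lower of
#'   the two translocation barriers the analysis is designed to resolve.
#' @param half_separation Half-distance between the minima, angstrom (> 0).
#' @param tilt Energy by which the `+half_separation` basin is lowered
#'   relative to the `-half_separation` basin (kcal/mol, default 0).
#' @param domain_scale Reflecting walls at
#'   `+/- domain_scale * half_separation`.
#' @return A `model_potential`.
#' @export
make_double_well <- function(barrier = 5.8, half_separation = 2,
                             tilt = 0, domain_scale = 2.5) {
  .check_scalar(barrier, "barrier", positive = TRUE)
  .check_scalar(half_separation, "half_separation", positive = TRUE)
  .check_scalar(tilt, "tilt")
  dom <- matrix(c(-1, 1) * domain_scale * half_separation, ncol = 1)
  new_potential(
    "double_well",
    list(barrier = barrier, half_separation = half_separation, tilt = tilt),
    dim = 1L, domain = dom,
    analytic_truth = list(barrier = barrier,
                          minima = c(-half_separation, half_separation),
                          basin_offset = -tilt))
}

#' Two-channel translocation landscape
#'
#' A 2D potential `U(s, w)` on a rectangular domain with reflecting walls.
#' `s` is the translocation progress coordinate; two parallel channels at
#' `w = +/- channel_sep / 2` connect the shared start basin (`s < 0`) to
#' the shared end basin (`s > 0`). The channel structure — a Gaussian
#' barrier of height `barrier_a` across channel A (`w > 0`), `barrier_b`
#' across channel B (`w < 0`), and an inter-channel ridge higher than both
#' saddles — lives under a flat-topped quartic-exponential envelope
#' `exp(-s^4 / (2 sigma_s^4))`, so in the barrier region every crossing
#' commits to one channel while the basins are common to both. The flat
#' top makes the saddle an extended bottleneck corridor (as in a real
#' translocation tunnel) rather than a knife edge. This emulates a ligand that can translocate by two
#' distinct conduits of unequal barrier, e.g. entering a membrane receptor
#' from either leaflet.
#'
#' The barrier interpolation across `w` uses a smoothstep with zero slope at
#' the channel centres, so the saddle heights equal `barrier_a` and
#' `barrier_b` exactly (stored in `analytic_truth`).
#'
#' @param barrier_a,barrier_b Saddle heights of the two channels, kcal/mol.
#'   Defaults 5.8 and 6.5, the two translocation-pathway barriers the
#'   analysis is meant to resolve.
#' @param geometry Named list: `channel_sep` (distance between channel
#'   centres, angstrom, > 0), `s_half` (half-width of the `s` domain),
#'   `sigma_s` (Gaussian barrier width along `s`), `ridge` (inter-channel
#'   ridge height; default `max(barrier_a, barrier_b) + 3`).
#' @return A `model_potential` with `analytic_truth$barrier_a/b`.
#' @export
make_two_channel <- function(barrier_a = 5.8, barrier_b = 6.5,
                             geometry = list()) {
  .check_scalar(barrier_a, "barrier_a", positive = TRUE)
  .check_scalar(barrier_b, "barrier_b", positive = TRUE)
  geo <- utils::modifyList(
    list(channel_sep = 2, s_half = 3.2, sigma_s = 1.6, ridge = NULL), geometry)
  if (geo$channel_sep <= 0)
    stop("degenerate geometry: channel_sep must be > 0", call. = FALSE)
  if (is.null(geo$ridge)) geo$ridge <- max(barrier_a, barrier_b) + 3
  dom <- cbind(c(-geo$s_half, geo$s_half),
               c(-geo$channel_sep, geo$channel_sep))
  # the envelope leaves a residual floor of barrier * g(s_half) at the
  # domain edge, so the exact minimax barrier (saddle minus basin minimum)
  # is barrier * (1 - g(s_half)); both are stored
  g_edge <- exp(-geo$s_half^4 / (2 * geo$sigma_s^4))
  new_potential(
    "two_channel",
    list(barrier_a = barrier_a, barrier_b = barrier_b,
         channel_sep = geo$channel_sep, sigma_s = geo$sigma_s,
         ridge = geo$ridge),
    dim = 2L, domain = dom,
    analytic_truth = list(barrier_a = barrier_a * (1 - g_edge),
                          barrier_b = barrier_b * (1 - g_edge),
                          barrier_a_nominal = barrier_a,
                          barrier_b_nominal = barrier_b,
                          channel_w = c(a = geo$channel_sep / 2,
                                        b = -geo$channel_sep / 2)))
}

#' Harmonic potential
#'
#' `U(x) = sum_d 0.5 * k_d * (x_d - center_d)^2`.
#'
#' @param k Spring constant(s), kcal/mol/A^2 (recycled over dimensions).
#' @param dim Dimensionality.
#' @param center Minimum position (recycled).
#' @param half_width Reflecting walls at `center +/- half_width`.
#' @return A `model_potential`.
#' @export
make_harmonic <- function(k = 2, dim = 1L, center = 0, half_width = 50) {
  k <- rep_len(as.numeric(k), dim)
  center <- rep_len(as.numeric(center), dim)
  if (any(k <= 0)) stop("'k' must be positive", call. = FALSE)
  dom <- rbind(center - half_width, center + half_width)
  new_potential("harmonic", list(k = k, center = center), dim = dim,
                domain = dom, analytic_truth = list(variance_at = function(kT) kT / k))
}

#' Flat (zero) potential
#'
#' @param dim Dimensionality.
#' @param half_width Reflecting walls at `+/- half_width` (default wide
#'   enough to be effectively free diffusion).
#' @return A `model_potential`.
#' @export
make_flat <- function(dim = 1L, half_width = 1e6) {
  dom <- rbind(rep(-half_width, dim), rep(half_width, dim))
  new_potential("flat", list(), dim = dim, domain = dom)
}

#' Tabulated 1D potential with linear interpolation
#'
#' Energies between grid nodes are linearly interpolated; the gradient is
#' the segment slope. Useful for bespoke fixtures such as multi-well
#' landscapes with known minima.
#'
#' @param x Ascending grid, angstrom.
#' @param U Energies at the grid nodes, kcal/mol.
#' @return A `model_potential` with reflecting walls at `range(x)`.
#' @export
make_custom_grid <- function(x, U) {
  stopifnot(length(x) == length(U), length(x) >= 2, !is.unsorted(x, strictly = TRUE),
            all(is.finite(U)))
  new_potential("custom_grid", list(x = as.numeric(x), U = as.numeric(U)),
                dim = 1L, domain = matrix(range(x), ncol = 1))
}

#' Evaluate a model potential
#'
#' @param potential A `model_potential`.
#' @param X Points: vector (1D) or matrix with `dim(potential)` columns.
#' @return Energies in kcal/mol.
#' @export
potential_energy <- function(potential, X) {
  stopifnot(inherits(potential, "model_potential"))
  X <- .as_matrix(X)
  if (ncol(X) != potential$dim) stop("dimension mismatch", call. = FALSE)
  eval_potential_cpp(unclass(potential), X)
}

#' Evaluate the gradient of a model potential
#'
#' @inheritParams potential_energy
#' @return Matrix of gradients (kcal/mol/A), one row per point.
#' @export
potential_gradient <- function(potential, X) {
  stopifnot(inherits(potential, "model_potential"))
  X <- .as_matrix(X)
  if (ncol(X) != potential$dim) stop("dimension mismatch", call. = FALSE)
  grad_potential_cpp(unclass(potential), X)
}

#' Minimax (minimum-energy-path) barrier on a dense grid
#'
#' Evaluates the potential on a dense grid and returns the minimax barrier
#' between two regions: the lowest possible value of the maximum energy
#' along any grid path connecting them, minus the minimum energy of the
#' start region. Used to verify the stored analytic barriers of constructed
#' landscapes by direct enumeration.
#'
#' @param potential A 1D or 2D `model_potential`.
#' @param start_region,end_region Functions taking the grid coordinates
#'   (vector per point) and returning TRUE inside the region.
#' @param n Grid nodes per dimension.
#' @param mask Optional function of coordinates restricting the admissible
#'   grid (e.g. one channel of a two-channel landscape).
#' @return Barrier in kcal/mol.
#' @export
grid_minimax_barrier <- function(potential, start_region, end_region,
                                 n = 201, mask = NULL) {
  stopifnot(potential$dim %in% c(1L, 2L))
  dom <- potential$domain
  ax <- lapply(seq_len(potential$dim),
               function(d) seq(dom[1, d], dom[2, d], length.out = n))
  if (potential$dim == 1L) {
    X <- matrix(ax[[1]], ncol = 1)
  } else {
    X <- as.matrix(expand.grid(ax[[1]], ax[[2]]))
  }
  U <- potential_energy(potential, X)
  keep <- rep(TRUE, nrow(X))
  if (!is.null(mask)) keep <- apply(X, 1L, mask)
  Ug <- ifelse(keep, U, NA_real_)
  dim(Ug) <- if (potential$dim == 1L) c(n, 1L) else c(n, n)
  s_idx <- which(apply(X, 1L, start_region) & keep)
  e_idx <- which(apply(X, 1L, end_region) & keep)
  if (!length(s_idx) || !length(e_idx))
    stop("empty start or end region on the grid", call. = FALSE)
  sid <- s_idx[which.min(U[s_idx])]
  eid <- e_idx[which.min(U[e_idx])]
  .minimax_barrier_fast(Ug, sid, eid, !is.na(Ug))
}
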