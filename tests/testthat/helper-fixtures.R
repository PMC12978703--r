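# shared fixtures, all generated in code

two_state_T <- function(p = 0.1) {
  matrix(c(1 - p, p, p, 1 - p), 2, 2, byrow = TRUE)
}

# reversible 4-state transition matrix built from a symmetric count pattern
four_state_T <- function() {
  x <- matrix(c(8, 2, 0, 1,
                2, 6, 3, 0,
                0, 3, 7, 2,
                1, 0, 2, 9), 4, 4, byrow = TRUE)
  x / rowSums(x)
}

# two Gaussian blobs at +/- 5 (1D), sd 0.5
blob_data <- function(n = 1e4, seed = 42) {
  set.seed(seed)
  cbind(c(rnorm(n / 2, -5, 0.5), rnorm(n / 2, 5, 0.5)))
}

# 1D four-well landscape on a tabulated grid (wells at -6, -2, 2, 6)
four_well_potential <- function(barrier = 2.5) {
  x <- seq(-8, 8, length.out = 401)
  wells <- c(-6, -2, 2, 6)
  U <- rep(barrier, length(x))
  for (w in wells) U <- pmin(U, barrier * pmin((x - w)^2, 1))
  make_custom_grid(x, U)
}

# linear funnel pore: radius 10 -> 4 A over z in [0, 20]
funnel_structure <- function() {
  zs <- seq(0, 20, by = 1)
  make_pore_structure(data.frame(z = zs, radius = 10 - 0.3 * zs),
                      atoms_per_ring = 36)
}

# brute-force minimax barrier by DFS over all simple paths (8-connected)
brute_force_minimax <- function(F, start, end) {
  nr <- nrow(F); nc <- ncol(F)
  best <- Inf
  offs <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  offs <- offs[rowSums(offs == 0) < 2, , drop = FALSE]
  visit <- function(r, c, seen, mx) {
    mx <- max(mx, F[r, c])
    if (mx >= best) return(invisible()) # prune
    if (r == end[1] && c == end[2]) {
      best <<- mx
      return(invisible())
    }
    seen[r, c] <- TRUE
    for (o in seq_len(nrow(offs))) {
      r2 <- r + offs[o, 1]; c2 <- c + offs[o, 2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (seen[r2, c2] || is.na(F[r2, c2])) next
      visit(r2, c2, seen, mx)
    }
  }
  visit(start[1], start[2], matrix(FALSE, nr, nc), -Inf)
  best - F[start[1], start[2]]
}

# wrap a plain matrix as a free_energy_surface on unit bins
fes_from_matrix <- function(F, kT = 0.61603) {
  F <- as.matrix(F)
  edges <- list(seq(0, nrow(F)), seq(0, ncol(F)))
  if (ncol(F) == 1L) {
    structure(list(dims = 1L, bin_edges = edges[1], F = as.numeric(F),
                   counts = rep(1, nrow(F)), F_err = NULL, kT = kT),
              class = "free_energy_surface")
  } else {
    structure(list(dims = 2L, bin_edges = edges, F = F,
                   counts = array(1, dim(F)), F_err = NULL, kT = kT),
              class = "free_energy_surface")
  }
}
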