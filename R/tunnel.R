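# Sphere-probe tunnel radius profiling along a channel axis, plus the
# synthetic pore generator used to validate it. PDB I/O goes through bio3d.

#' Van der Waals radii for tunnel profiling
#'
#' Bondi radii for the common elements (C 1.70, N 1.55, O 1.52, S 1.80,
#' H 1.20, P 1.80 angstrom); unknown elements fall back to 1.70 with a
#' warning, the usual practice of pore-profiling tools.
#'
#' @param elements Character vector of element symbols.
#' @return Numeric vector of radii, angstrom.
#' @export
assign_vdw <- function(elements) {
  tab <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
  el <- toupper(trimws(elements))
  r <- unname(tab[el])
  if (anyNA(r)) {
    warning(sprintf("unknown element(s) %s assigned fallback vdW radius 1.70",
                    paste(unique(el[is.na(r)]), collapse = ", ")))
    r[is.na(r)] <- 1.70
  }
  r
}

new_structure_atoms <- function(coords, elements, vdw = NULL, labels = NULL) {
  coords <- .as_matrix(coords)
  stopifnot(ncol(coords) == 3L, nrow(coords) >= 1L)
  if (is.null(vdw)) vdw <- assign_vdw(elements)
  stopifnot(all(vdw > 0), length(elements) == nrow(coords),
            length(vdw) == nrow(coords))
  colnames(coords) <- c("x", "y", "z")
  structure(list(coords = coords, elements = elements, vdw = vdw,
                 labels = labels),
            class = "structure_atoms")
}

#' @export
print.structure_atoms <- function(x, ...) {
  cat(sprintf("Structure: %d atoms, z range [%.2f, %.2f] A\n",
              nrow(x$coords), min(x$coords[, 3]), max(x$coords[, 3])))
  invisible(x)
}

#' Build a synthetic pore structure from a radius profile
#'
#' Places rings of atoms (evenly spaced angularly) at stated `z` positions
#' and ring radii, giving a channel whose true clearance radius at each
#' ring is `radius - vdw(element)` — an analytic truth table for the
#' profiler.
#'
#' @param radius_profile Data frame with columns `z` (angstrom, unique) and
#'   `radius` (ring radius, angstrom, each > vdW radius of `element`).
#' @param atoms_per_ring Atoms per ring.
#' @param element Element symbol for all atoms.
#' @return A `structure_atoms` with attribute `"truth"` = data.frame(z,
#'   clearance).
#' @export
make_pore_structure <- function(radius_profile, atoms_per_ring = 24L,
                                element = "C") {
  stopifnot(is.data.frame(radius_profile),
            all(c("z", "radius") %in% names(radius_profile)))
  if (anyDuplicated(radius_profile$z))
    stop("overlapping rings: duplicated z values", call. = FALSE)
  rv <- assign_vdw(element)
  if (any(radius_profile$radius <= rv))
    stop("ring radius must exceed the element's vdW radius", call. = FALSE)
  ang <- 2 * pi * (seq_len(atoms_per_ring) - 1L) / atoms_per_ring
  coords <- do.call(rbind, lapply(seq_len(nrow(radius_profile)), function(i) {
    cbind(radius_profile$radius[i] * cos(ang),
          radius_profile$radius[i] * sin(ang),
          radius_profile$z[i])
  }))
  n <- nrow(coords)
  labels <- data.frame(chain = "A", resno = rep(seq_len(nrow(radius_profile)),
                                                each = atoms_per_ring),
                       elety = element, resid = "RNG")
  out <- new_structure_atoms(coords, rep(element, n), labels = labels)
  # exact on-axis clearance: neighbouring rings also constrain the probe
  # in 3D, so the slice clearance is the minimum over all rings of
  # sqrt(R_j^2 + (z_j - z)^2) - vdw, not just the local ring radius
  clearance <- vapply(radius_profile$z, function(z)
    min(sqrt(radius_profile$radius^2 + (radius_profile$z - z)^2)) - rv,
    numeric(1))
  attr(out, "truth") <- data.frame(z = radius_profile$z,
                                   clearance = clearance,
                                   ring_clearance = radius_profile$radius - rv)
  out
}

#' Write a structure as standard PDB ATOM records
#'
#' @param structure A `structure_atoms`.
#' @param file Output path.
#' @export
write_structure_pdb <- function(structure, file) {
  stopifnot(inherits(structure, "structure_atoms"))
  n <- nrow(structure$coords)
  lab <- structure$labels
  if (is.null(lab))
    lab <- data.frame(chain = "A", resno = seq_len(n),
                      elety = structure$elements, resid = "UNK")
  bio3d::write.pdb(file = file, xyz = as.numeric(t(structure$coords)),
                   type = rep("ATOM", n), eleno = seq_len(n),
                   elety = lab$elety, resid = lab$resid, chain = lab$chain,
                   resno = lab$resno, o = rep(1, n), b = rep(0, n),
                   elesy = structure$elements)
  invisible(file)
}

#' Load a PDB file into a structure for tunnel profiling
#'
#' Parses ATOM/HETATM records with bio3d. Elements come from the element
#' column when present; blank element fields fall back to the first
#' alphabetic character of the atom name (so "CA" in a protein residue is
#' carbon — the documented heuristic). Water and common ion residues are
#' dropped by default, since the profile characterises the protein cavity.
#'
#' @param file Path to a PDB file.
#' @param keep_solvent Keep water/ion records (default FALSE).
#' @return A `structure_atoms`.
#' @export
load_pdb <- function(file, keep_solvent = FALSE) {
  pdb <- bio3d::read.pdb(file)
  at <- pdb$atom
  if (nrow(at) == 0) stop("no ATOM/HETATM records found", call. = FALSE)
  if (!keep_solvent) {
    solvent <- c("HOH", "WAT", "TIP3", "SOL", "NA", "CL", "K", "SOD",
                 "CLA", "POT", "MG", "ZN", "CA2")
    at <- at[!(at$resid %in% solvent), , drop = FALSE]
    if (nrow(at) == 0) stop("structure contains only solvent records", call. = FALSE)
  }
  elesy <- trimws(at$elesy)
  blank <- is.na(elesy) | elesy == ""
  if (any(blank)) {
    guess <- vapply(at$elety[blank], function(nm) {
      ch <- regmatches(nm, regexpr("[A-Za-z]", nm))
      if (length(ch)) toupper(ch) else "C"
    }, character(1))
    elesy[blank] <- guess
  }
  new_structure_atoms(cbind(at$x, at$y, at$z), elesy,
                      labels = data.frame(chain = at$chain, resno = at$resno,
                                          elety = at$elety, resid = at$resid))
}

# clearance of probe centre p (3-vector) given atom coords/vdw
.clearance <- function(p, coords, vdw) {
  d <- sqrt((coords[, 1] - p[1])^2 + (coords[, 2] - p[2])^2 +
            (coords[, 3] - p[3])^2)
  min(d - vdw)
}

#' Profile the tunnel radius of a structure along the z axis
#'
#' For each slice at fixed z the in-plane probe position is optimized to
#' maximize the clearance `min_i(||p - a_i|| - vdw_i)` (3D point-to-atom
#' distances). Each slice is warm-started from the previous slice's centre
#' and refined by multi-start Nelder-Mead; the multi-start guards against
#' channels that wander off-axis. Radii are clamped to `[0, r_max]`;
#' slices reaching `r_max` are flagged capped (no confining atoms).
#'
#' @param structure A `structure_atoms`.
#' @param z_range Length-2 numeric, angstrom.
#' @param z_step Slice spacing, angstrom (default 0.5).
#' @param seed_point_xy In-plane starting point for the first slice.
#' @param r_max Radius cap, angstrom (default 15).
#' @param n_starts Local-optimization restarts per slice (default 5).
#' @param seed Seed for the restart offsets.
#' @return A `tunnel_profile`: data.frame `z, cx, cy, radius, capped` with
#'   class attribute; `diameter` is `2 * radius`.
#' @export
profile_tunnel <- function(structure, z_range, z_step = 0.5,
                           seed_point_xy = c(0, 0), r_max = 15,
                           n_starts = 5L, seed = 1L) {
  stopifnot(inherits(structure, "structure_atoms"), length(z_range) == 2L,
            z_range[1] < z_range[2], z_step > 0, r_max > 0)
  zs <- seq(z_range[1], z_range[2], by = z_step)
  set.seed(seed)
  coords <- structure$coords
  vdw <- structure$vdw
  centre <- as.numeric(seed_point_xy)
  res <- vector("list", length(zs))
  for (i in seq_along(zs)) {
    z <- zs[i]
    obj <- function(p) -.clearance(c(p, z), coords, vdw)
    starts <- rbind(centre,
                    matrix(rep(centre, each = n_starts - 1L) +
                           stats::rnorm(2L * (n_starts - 1L), sd = 1.5),
                           ncol = 2L))
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      fit <- tryCatch(
        stats::optim(starts[s, ], obj, method = "Nelder-Mead",
                     control = list(maxit = 400, reltol = 1e-10)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
    if (is.null(best)) { # optimizer failure: flag and continue
      res[[i]] <- data.frame(z = z, cx = NA_real_, cy = NA_real_,
                             radius = NA_real_, capped = NA)
      next
    }
    r <- min(max(-best$value, 0), r_max)
    centre <- best$par
    res[[i]] <- data.frame(z = z, cx = centre[1], cy = centre[2],
                           radius = r, capped = -best$value >= r_max)
  }
  out <- do.call(rbind, res)
  class(out) <- c("tunnel_profile", "data.frame")
  out
}

#' Write a tunnel profile as a sphere-per-slice PDB for visualization
#'
#' One pseudo-atom per slice at the optimized centre, with the clearance
#' radius in the B-factor column, so molecular viewers can render the
#' tunnel as spheres.
#'
#' @param profile A `tunnel_profile`.
#' @param file Output path.
#' @export
write_profile_pdb <- function(profile, file) {
  ok <- !is.na(profile$radius)
  n <- sum(ok)
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(cbind(profile$cx[ok], profile$cy[ok],
                                            profile$z[ok]))),
                   type = rep("HETATM", n), eleno = seq_len(n),
                   elety = rep("PRB", n), resid = rep("TUN", n),
                   chain = rep("T", n), resno = seq_len(n),
                   o = rep(1, n), b = profile$radius[ok],
                   elesy = rep("H", n))
  invisible(file)
}
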