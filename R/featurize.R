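# Featurization: raw per-frame coordinates -> translocation metrics
# (center of mass, tilt angle with the membrane plane, group distances).

#' Define an atom group
#'
#' @param indices 1-based atom indices (unique, positive).
#' @param masses Optional masses in amu (default 1 each).
#' @param label Text label.
#' @return An `atom_group`.
#' @export
atom_group <- function(indices, masses = NULL, label = "group") {
  indices <- as.integer(indices)
  if (!length(indices) || any(indices < 1L) || anyDuplicated(indices))
    stop("indices must be unique positive integers", call. = FALSE)
  if (is.null(masses)) masses <- rep(1, length(indices))
  stopifnot(length(masses) == length(indices), all(masses > 0))
  structure(list(indices = indices, masses = as.numeric(masses),
                 label = label), class = "atom_group")
}

#' Mass-weighted centre of mass of an atom group
#'
#' @param frame_coords Matrix of atom coordinates (atoms x 3) for one frame.
#' @param group An `atom_group`.
#' @return 3-vector, angstrom.
#' @export
center_of_mass <- function(frame_coords, group) {
  stopifnot(inherits(group, "atom_group"))
  frame_coords <- .as_matrix(frame_coords)
  if (max(group$indices) > nrow(frame_coords))
    stop("atom index beyond structure bounds", call. = FALSE)
  w <- group$masses / sum(group$masses)
  colSums(frame_coords[group$indices, , drop = FALSE] * w)
}

#' Tilt angle of a ligand with the membrane (x-y) plane
#'
#' The orientation vector runs tail -> head:
#' `v = COM(head) - COM(tail)`; the tilt is `asin(v_z / |v|)` in degrees,
#' in `[-90, +90]`. +90 means the head group points along +z
#' (extracellular); -90 means it points straight down.
#'
#' @param frame_coords Atoms x 3 matrix for one frame.
#' @param tail_group,head_group `atom_group`s with distinct centres of mass.
#' @return Angle in degrees.
#' @export
tilt_angle <- function(frame_coords, tail_group, head_group) {
  v <- center_of_mass(frame_coords, head_group) -
       center_of_mass(frame_coords, tail_group)
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("tail and head centres of mass coincide", call. = FALSE)
  asin(v[3] / nv) * 180 / pi
}

#' Minimum pairwise distance between two atom groups
#'
#' @param frame_coords Atoms x 3 matrix for one frame.
#' @param groupA,groupB `atom_group`s with disjoint indices.
#' @return Minimum Euclidean distance, angstrom.
#' @export
min_distance <- function(frame_coords, groupA, groupB) {
  stopifnot(inherits(groupA, "atom_group"), inherits(groupB, "atom_group"))
  if (length(intersect(groupA$indices, groupB$indices)))
    stop("groups must be disjoint", call. = FALSE)
  frame_coords <- .as_matrix(frame_coords)
  A <- frame_coords[groupA$indices, , drop = FALSE]
  B <- frame_coords[groupB$indices, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(min(d2), 0))
}

#' Declare a feature
#'
#' @param kind One of `"com_coordinate"`, `"tilt_angle"`, `"min_distance"`,
#'   `"raw_column"`.
#' @param groups List of `atom_group`s (`tilt_angle` and `min_distance`
#'   need exactly two: tail/head resp. A/B).
#' @param axis For `com_coordinate`: `"x"`, `"y"` or `"z"`.
#' @param column For `raw_column`: name or index of the trajectory column.
#' @param name Feature label; defaults to a descriptive one.
#' @return A `feature_spec`.
#' @export
feature_spec <- function(kind = c("com_coordinate", "tilt_angle",
                                  "min_distance", "raw_column"),
                         groups = list(), axis = "z", column = NULL,
                         name = NULL) {
  kind <- match.arg(kind)
  need <- c(com_coordinate = 1L, tilt_angle = 2L, min_distance = 2L,
            raw_column = 0L)[[kind]]
  if (length(groups) != need)
    stop(sprintf("'%s' requires exactly %d group(s)", kind, need), call. = FALSE)
  if (kind == "raw_column" && is.null(column))
    stop("'raw_column' requires 'column'", call. = FALSE)
  if (is.null(name))
    name <- switch(kind,
                   raw_column = paste0("raw_", column),
                   com_coordinate = paste0("com_", axis),
                   kind)
  structure(list(kind = kind, groups = groups,
                 axis = match.arg(axis, c("x", "y", "z")),
                 column = column, name = name),
            class = "feature_spec")
}

.eval_spec <- function(spec, traj) {
  if (spec$kind == "raw_column") {
    col <- spec$column
    vals <- traj$coords[, col]
    return(as.numeric(vals))
  }
  if (is.null(traj$xyz))
    stop("atom-based features require per-frame atom coordinates (traj$xyz)",
         call. = FALSE)
  nf <- dim(traj$xyz)[1]
  vapply(seq_len(nf), function(f) {
    fc <- traj$xyz[f, , ]
    switch(spec$kind,
           com_coordinate = center_of_mass(fc, spec$groups[[1]])[
             match(spec$axis, c("x", "y", "z"))],
           tilt_angle = tilt_angle(fc, spec$groups[[1]], spec$groups[[2]]),
           min_distance = min_distance(fc, spec$groups[[1]], spec$groups[[2]]))
  }, numeric(1))
}

#' Compute a feature matrix over trajectories
#'
#' Evaluates each feature spec on every frame of every trajectory, in input
#' order, producing one row per frame with full `(trajectory, frame)`
#' provenance. Rows are in (trajectory, frame) lexicographic order.
#'
#' @param trajectories List of `trajectory` objects. Atom-based features
#'   require each trajectory to carry `xyz` (frames x atoms x 3).
#' @param specs List of `feature_spec`s (non-empty).
#' @return A `feature_matrix`: list with `values` (frames x features),
#'   `names`, and `provenance` (data.frame `traj`, `frame`; frames 1-based).
#' @export
compute_features <- function(trajectories, specs) {
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  if (inherits(trajectories, "synthetic_dataset"))
    trajectories <- trajectories$trajectories
  if (inherits(specs, "feature_spec")) specs <- list(specs)
  if (!length(specs)) stop("at least one feature spec required", call. = FALSE)
  blocks <- lapply(trajectories, function(tr) {
    vals <- vapply(specs, .eval_spec, numeric(nrow(tr$coords)), traj = tr)
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
    vals
  })
  values <- do.call(rbind, blocks)
  if (anyNA(values)) stop("NaN/NA in computed features", call. = FALSE)
  nm <- vapply(specs, `[[`, character(1), "name")
  colnames(values) <- nm
  prov <- do.call(rbind, lapply(seq_along(trajectories), function(i) {
    data.frame(traj = trajectories[[i]]$id,
               frame = seq_len(nrow(blocks[[i]])))
  }))
  structure(list(values = values, names = nm, provenance = prov,
                 n_traj = length(trajectories),
                 block_rows = vapply(blocks, nrow, integer(1))),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d frames x %d features (%s) from %d trajectories\n",
              nrow(x$values), ncol(x$values),
              paste(x$names, collapse = ", "), x$n_traj))
  invisible(x)
}

#' Split a pooled feature matrix back into per-trajectory matrices
#'
#' @param fm A `feature_matrix`.
#' @return List of numeric matrices, one per source trajectory.
#' @export
split_by_trajectory <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  ends <- cumsum(fm$block_rows)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_along(ends), function(i)
    fm$values[starts[i]:ends[i], , drop = FALSE])
}

#' Write a feature matrix as CSV with a JSON provenance sidecar
#'
#' @param fm A `feature_matrix`.
#' @param file CSV path; provenance goes to `paste0(file, ".prov.json")`.
#' @export
write_feature_csv <- function(fm, file) {
  utils::write.csv(as.data.frame(fm$values), file, row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(fm$provenance, paste0(file, ".prov.json"),
                       dataframe = "columns")
  invisible(file)
}
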