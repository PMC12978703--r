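# Overdamped (Brownian) Langevin simulation on model potentials.

#' Langevin simulation configuration
#'
#' Bundles the parameters of one overdamped Langevin run. Inertia is
#' irrelevant for the configurational observables this package targets, so
#' the propagator is the Euler--Maruyama Brownian scheme
#' `x <- x - (D/kT) * grad(U) * dt + sqrt(2 D dt) * eta`.
#'
#' @param kT Thermal energy, kcal/mol. Default `kT_at(310)` = 0.61603, the
#'   physiological temperature the emulated simulations are run at.
#' @param D Diffusion coefficient, A^2/ns.
#' @param dt Time step, ns.
#' @param n_steps Number of integration steps.
#' @param x0 Initial coordinates, angstrom.
#' @param seed Integer seed; fully determines the trajectory.
#' @param thin Save every `thin`-th frame (frame 0 always saved);
#'   `n_steps` must be divisible by `thin`.
#' @return A `langevin_config`.
#' @export
langevin_config <- function(kT = kT_at(310), D = 1, dt = 0.001,
                            n_steps = 1000L, x0 = 0, seed = 1L, thin = 1L) {
  .check_scalar(kT, "kT", positive = TRUE)
  .check_scalar(D, "D", positive = TRUE)
  .check_scalar(dt, "dt", positive = TRUE)
  .check_scalar(n_steps, "n_steps", positive = TRUE)
  .check_scalar(seed, "seed")
  .check_scalar(thin, "thin", positive = TRUE)
  if (n_steps %% thin != 0) stop("'n_steps' must be divisible by 'thin'", call. = FALSE)
  structure(list(kT = kT, D = D, dt = dt, n_steps = as.integer(n_steps),
                 x0 = as.numeric(x0), seed = as.integer(seed),
                 thin = as.integer(thin)),
            class = "langevin_config")
}

#' Simulate an overdamped Langevin trajectory
#'
#' Propagates Brownian dynamics on a model potential with reflecting walls
#' at the potential's domain boundaries. The drift per step is validated
#' against the domain size so the integration cannot silently step over
#' landscape features.
#'
#' @param potential A `model_potential`.
#' @param config A `langevin_config`; `x0` must match the potential's
#'   dimensionality.
#' @param id Trajectory identifier carried into feature provenance.
#' @return A `trajectory`: list with `coords` (saved frames x dim matrix,
#'   including the initial frame), `frame_time` (ns between saved frames),
#'   `config`, and `id`.
#' @export
simulate_langevin <- function(potential, config, id = "traj") {
  stopifnot(inherits(potential, "model_potential"),
            inherits(config, "langevin_config"))
  if (length(config$x0) != potential$dim)
    stop("x0 dimensionality does not match the potential", call. = FALSE)
  # drift-step sanity: typical diffusive step must resolve the domain
  step_len <- sqrt(2 * config$D * config$dt)
  min_extent <- min(potential$domain[2, ] - potential$domain[1, ])
  if (step_len > min_extent / 10)
    warning("diffusive step length is large relative to the domain; reduce dt")
  set.seed(config$seed)
  coords <- simulate_langevin_cpp(unclass(potential), config$x0,
                                  config$n_steps, config$dt, config$D,
                                  config$kT, config$thin)
  colnames(coords) <- c("x", "y", "z")[seq_len(potential$dim)]
  new_trajectory(coords, frame_time = config$dt * config$thin, id = id,
                 config = config)
}

new_trajectory <- function(coords, frame_time, id = "traj", config = NULL,
                           xyz = NULL) {
  structure(list(coords = coords, frame_time = frame_time, id = id,
                 config = config, xyz = xyz),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory '%s': %d frames x %d coordinates, %.4g ns/frame\n",
              x$id, nrow(x$coords), ncol(x$coords), x$frame_time))
  invisible(x)
}

#' Write / read a trajectory as headered CSV
#'
#' Columns are `t` (ns) followed by the coordinate columns.
#'
#' @param traj A `trajectory`.
#' @param file Path.
#' @return `read_trajectory_csv` returns a `trajectory`.
#' @export
write_trajectory_csv <- function(traj, file) {
  stopifnot(inherits(traj, "trajectory"))
  df <- data.frame(t = (seq_len(nrow(traj$coords)) - 1) * traj$frame_time,
                   traj$coords, check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_trajectory_csv
#' @param id Identifier for the loaded trajectory.
#' @export
read_trajectory_csv <- function(file, id = basename(file)) {
  df <- utils::read.csv(file, check.names = FALSE)
  if (!"t" %in% names(df)) stop("trajectory CSV must have a 't' column", call. = FALSE)
  ft <- if (nrow(df) > 1) df$t[2] - df$t[1] else 1
  coords <- as.matrix(df[setdiff(names(df), "t")])
  new_trajectory(coords, frame_time = ft, id = id)
}

#' Generate a synthetic multi-trajectory dataset with known ground truth
#'
#' Runs `n_traj` Langevin trajectories from supplied (or basin-default)
#' starting points, with per-trajectory seeds derived from one master seed
#' by the fixed splitting rule. The returned dataset carries the potential
#' (and hence its analytic barriers) as the ground-truth ledger for
#' downstream validation.
#'
#' @param potential A `model_potential`.
#' @param n_traj Number of trajectories.
#' @param n_steps Steps per trajectory.
#' @param starts Matrix of starting coordinates (rows recycled over
#'   trajectories). Default: the domain centre.
#' @param master_seed Master seed; trajectory `i` uses
#'   `derive_seed(master_seed, "langevin", i)`.
#' @param dt,D,kT,thin Passed to [langevin_config()].
#' @return A `synthetic_dataset`: list of trajectories plus `truth` and
#'   `seeds_used`.
#' @export
make_dataset <- function(potential, n_traj, n_steps, starts = NULL,
                         master_seed = 1L, dt = 0.001, D = 1,
                         kT = kT_at(310), thin = 1L) {
  if (is.null(starts))
    starts <- matrix(colMeans(potential$domain), nrow = 1)
  starts <- .as_matrix(starts)
  seeds <- vapply(seq_len(n_traj), function(i)
    derive_seed(master_seed, "langevin", i), integer(1))
  trajs <- lapply(seq_len(n_traj), function(i) {
    x0 <- starts[(i - 1L) %% nrow(starts) + 1L, ]
    cfg <- langevin_config(kT = kT, D = D, dt = dt, n_steps = n_steps,
                           x0 = x0, seed = seeds[i], thin = thin)
    simulate_langevin(potential, cfg, id = sprintf("traj%03d", i))
  })
  structure(list(trajectories = trajs, truth = potential,
                 seeds_used = seeds, master_seed = as.integer(master_seed)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %d trajectories on a '%s' potential\n",
              length(x$trajectories), x$truth$form))
  invisible(x)
}
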