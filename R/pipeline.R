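# End-to-end orchestration: simulate (with least-counts adaptive rounds)
# -> featurize -> tICA -> cluster -> MSM -> reweighted FES / barriers ->
# TPT kinetics, from a single config with one master seed.

#' Default pipeline configuration
#'
#' The defaults emulate a two-pathway ligand-translocation study: a
#' two-channel landscape with saddles of 5.8 and 6.5 kcal/mol at
#' kT = 0.616 kcal/mol (310 K), sampled by adaptively seeded rounds of
#' short Langevin trajectories (least-counts restarts), analysed by
#' tICA + k-means + reversible MSM, with MSM-reweighted surfaces, minimax
#' barriers and TPT kinetics.
#'
#' @param master_seed Master seed for every stochastic stage.
#' @param output_dir Where stage outputs are written (`NULL`: nowhere).
#' @return Nested named list of stage configs.
#' @export
default_pipeline_config <- function(master_seed = 1L, output_dir = NULL) {
  list(
    master_seed = as.integer(master_seed),
    output_dir = output_dir,
    potential = list(form = "two_channel", barrier_a = 5.8, barrier_b = 6.5),
    simulate = list(n_stage_traj = 80L, n_rounds = 2L, traj_per_round = 10L,
                    n_steps = 2e5, dt = 0.005, D = 1, kT = kT_at(310),
                    thin = 4L, adapt_k = 200L),
    tica = list(lag = 60L, n_components = 2L),
    cluster = list(k = 100L, max_iter = 50L, flatten_cells = 48L,
                   per_cell = 25L, n_layouts = 3L),
    msm = list(lag = 2L, tol = 1e-6),
    fes = list(n_bins = c(32L, 20L), min_count = 2L),
    bootstrap = list(n_rounds = 200L, fraction = 0.8),
    tpt = list(start_below = -2, end_above = 2)
  )
}

#' Read / write a pipeline config as YAML
#'
#' @param file Path.
#' @param config Config list.
#' @return `read_pipeline_config` returns the config list.
#' @export
read_pipeline_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  utils::modifyList(default_pipeline_config(), cfg)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, file) {
  yaml::write_yaml(config, file)
  invisible(file)
}

# Adaptive-sampling simulation. The first (stage-seeded) block starts
# trajectories at points spread along both channels — emulating the
# stage-wise starting structures a steered setup places along the
# translocation pathway — and the following rounds restart from
# least-counts frames (k-means on small data, mini-batch k-means once the
# pool grows, as is standard for adaptive sampling at scale).
.simulate_adaptive <- function(potential, sim, master_seed) {
  dom <- potential$domain
  wA <- potential$params$channel_sep / 2
  n1 <- sim$n_stage_traj
  # ladder of stage seeds along each channel: rungs uniform in s across
  # the saddle plateau and flanks (out to where the envelope has dropped
  # to ~5% of the saddle height), mirrored on both sides; the basins are
  # filled by the descents themselves
  m <- max(1L, ceiling(n1 / 4))
  s_max <- potential$params$sigma_s * (-2 * log(0.05))^0.25
  s_mag <- seq(0, s_max, length.out = m)
  s_pts <- c(s_mag, -s_mag) # every rung on both sides of the saddle
  pathway_starts <- rbind(cbind(s_pts, wA), cbind(s_pts, -wA))
  run_block <- function(starts, round) {
    lapply(seq_len(nrow(starts)), function(i) {
      idx <- round * 1000L + i
      cfg <- langevin_config(kT = sim$kT, D = sim$D, dt = sim$dt,
                             n_steps = sim$n_steps, x0 = starts[i, ],
                             seed = derive_seed(master_seed, "langevin", idx),
                             thin = sim$thin)
      simulate_langevin(potential, cfg, id = sprintf("r%02d_t%03d", round, i))
    })
  }
  trajs <- run_block(pathway_starts[rep_len(seq_len(nrow(pathway_starts)),
                                            n1), , drop = FALSE], 0L)
  for (round in seq_len(sim$n_rounds)) {
    pooled <- lapply(trajs, function(tr) tr$coords)
    n_pool <- sum(vapply(pooled, nrow, integer(1)))
    disc <- if (n_pool <= 3e5)
      kmeans_fit(pooled, sim$adapt_k,
                 seed = derive_seed(master_seed, "adapt", round),
                 max_iter = 30L)
    else
      minibatch_kmeans_fit(pooled, sim$adapt_k, batch_size = 4000L,
                           seed = derive_seed(master_seed, "adapt", round),
                           n_batches = 75L)
    sel <- least_counts_select(disc, sim$traj_per_round,
                               seed = derive_seed(master_seed, "select", round))
    starts <- t(vapply(seq_len(nrow(sel)), function(i)
      trajs[[sel$traj[i]]]$coords[sel$frame[i], ], numeric(potential$dim)))
    trajs <- c(trajs, run_block(starts, round))
  }
  structure(list(trajectories = trajs, truth = potential,
                 seeds_used = NULL, master_seed = master_seed),
            class = "synthetic_dataset")
}

#' Run the full translocation analysis pipeline
#'
#' Executes simulate -> featurize -> tICA -> cluster -> MSM -> reweighted
#' FES with per-channel minimax barriers and bootstrap comparison -> TPT
#' (committor, flux, MFPT with bootstrap errors). Stages run in dependency
#' order; any failure aborts with a stage-tagged error. All stochastic
#' stages derive their seeds from `config$master_seed`.
#'
#' @param config Config list (see [default_pipeline_config()]); missing
#'   entries take defaults.
#' @param verbose Print stage progress.
#' @return A `pipeline_result`: list with `dataset`, `tica`, `disc`,
#'   `model`, `fes`, `barriers`, `barrier_comparison`, `tpt`, and
#'   `manifest` (per-stage parameters, wall times and output hashes).
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         verbose = TRUE) {
  config <- utils::modifyList(default_pipeline_config(), config)
  say <- function(...) if (verbose) message(sprintf(...))
  manifest <- list(master_seed = config$master_seed,
                   tool_version = as.character(utils::packageVersion("msmflux")),
                   stages = list())
  tick <- function(stage, params) {
    manifest$stages[[stage]] <<- list(params = params,
                                      started = Sys.time())
  }
  tock <- function(stage) {
    manifest$stages[[stage]]$wall_s <<-
      as.numeric(difftime(Sys.time(), manifest$stages[[stage]]$started,
                          units = "secs"))
    manifest$stages[[stage]]$started <<- NULL
  }
  stage_fail <- function(stage, e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)

  # -- simulate ------------------------------------------------------
  tick("simulate", config$simulate)
  say("stage simulate: %d stage-seeded + %d rounds x %d adaptive trajectories",
      config$simulate$n_stage_traj, config$simulate$n_rounds,
      config$simulate$traj_per_round)
  pot <- tryCatch(
    make_two_channel(config$potential$barrier_a, config$potential$barrier_b),
    error = function(e) stage_fail("simulate", e))
  dataset <- tryCatch(
    .simulate_adaptive(pot, config$simulate, config$master_seed),
    error = function(e) stage_fail("simulate", e))
  tock("simulate")

  # -- featurize -----------------------------------------------------
  tick("featurize", list(features = c("x", "y")))
  fm <- tryCatch(
    compute_features(dataset, list(feature_spec("raw_column", column = "x"),
                                   feature_spec("raw_column", column = "y"))),
    error = function(e) stage_fail("featurize", e))
  tock("featurize")

  # -- tica ----------------------------------------------------------
  tick("tica", config$tica)
  say("stage tica: lag %d", config$tica$lag)
  tica <- tryCatch(
    fit_tica(fm, lag = config$tica$lag,
             n_components = config$tica$n_components),
    error = function(e) stage_fail("tica", e))
  proj <- tica_transform(tica, fm)
  tock("tica")

  # -- cluster -------------------------------------------------------
  # several density-flattened k-means layouts; thermodynamic readings are
  # averaged over layouts to damp discretization-layout noise
  tick("cluster", config$cluster)
  say("stage cluster: k = %d (%d layouts)", config$cluster$k,
      config$cluster$n_layouts)
  discs <- tryCatch(
    lapply(seq_len(config$cluster$n_layouts), function(ly)
      flattened_kmeans(proj, config$cluster$k,
                       cells = config$cluster$flatten_cells,
                       per_cell = config$cluster$per_cell,
                       seed = derive_seed(config$master_seed, "cluster", ly),
                       max_iter = config$cluster$max_iter)),
    error = function(e) stage_fail("cluster", e))
  disc <- discs[[1]]
  tock("cluster")

  # -- msm -----------------------------------------------------------
  tick("msm", config$msm)
  frame_time <- config$simulate$dt * config$simulate$thin
  models <- tryCatch(
    lapply(discs, function(d)
      estimate_reversible(count_transitions(d, config$msm$lag),
                          frame_time = frame_time, tol = config$msm$tol)),
    error = function(e) stage_fail("msm", e))
  model <- models[[1]]
  say("stage msm: %d active states at lag %d frames", nrow(model$T),
      config$msm$lag)
  tock("msm")

  # -- fes + barriers ------------------------------------------------
  tick("fes", config$fes)
  coords <- do.call(rbind, lapply(dataset$trajectories, function(t) t$coords))
  dom <- pot$domain
  edges <- list(seq(dom[1, 1], dom[2, 1], length.out = config$fes$n_bins[1] + 1L),
                seq(dom[1, 2], dom[2, 2], length.out = config$fes$n_bins[2] + 1L))
  coarse <- list(
    seq(dom[1, 1], dom[2, 1], length.out = config$fes$n_bins[1] %/% 2 + 1L),
    seq(dom[1, 2], dom[2, 2], length.out = config$fes$n_bins[2] %/% 2 + 1L))
  barrier_one <- function(d, m) {
    f <- reweighted_fes(coords, d, m, edges, kT = config$simulate$kT,
                        min_count = config$fes$min_count)
    cb <- tryCatch(channel_barriers(f), error = function(e) NULL)
    if (is.null(cb) && config$fes$min_count > 1L) {
      # sparse saddle coverage: count every frame
      f1 <- reweighted_fes(coords, d, m, edges, kT = config$simulate$kT,
                           min_count = 1L)
      cb <- tryCatch(channel_barriers(f1), error = function(e) NULL)
      if (!is.null(cb)) f <- f1
    }
    if (is.null(cb)) {
      # still gapped: halve the grid resolution (the saddle plateau is
      # flat, so coarser bins cost little accuracy there)
      f2 <- reweighted_fes(coords, d, m, coarse, kT = config$simulate$kT,
                           min_count = 1L)
      cb <- channel_barriers(f2)
      f <- f2
    }
    list(fes = f, barriers = cb)
  }
  fes_all <- tryCatch(
    Map(barrier_one, discs, models),
    error = function(e) stage_fail("fes", e))
  fes <- fes_all[[1]]$fes
  barrier_mat <- vapply(fes_all, function(x) x$barriers, numeric(2))
  barriers <- rowMeans(barrier_mat)
  names(barriers) <- c("a", "b")
  say("stage fes: channel barriers a = %.2f, b = %.2f kcal/mol",
      barriers["a"], barriers["b"])
  tock("fes")

  # -- bootstrap barrier comparison ---------------------------------
  tick("bootstrap", config$bootstrap)
  ens <- tryCatch(
    bootstrap_msm(disc, n_rounds = config$bootstrap$n_rounds,
                  fraction = config$bootstrap$fraction,
                  lag = config$msm$lag,
                  seed = derive_seed(config$master_seed, "bootstrap"),
                  frame_time = frame_time, tol = config$msm$tol),
    error = function(e) stage_fail("bootstrap", e))
  boot_barriers <- tryCatch(
    bootstrap_channel_barriers(coords, disc, ens, edges,
                               kT = config$simulate$kT,
                               min_count = config$fes$min_count),
    error = function(e) stage_fail("bootstrap", e))
  if (length(boot_barriers$a) < 10)
    boot_barriers <- tryCatch(
      bootstrap_channel_barriers(coords, disc, ens, edges,
                                 kT = config$simulate$kT, min_count = 1L),
      error = function(e) stage_fail("bootstrap", e))
  cmp <- tryCatch(
    compare_barriers(boot_barriers$a, boot_barriers$b),
    error = function(e) stage_fail("bootstrap", e))
  say("stage bootstrap: delta = %.2f kcal/mol, p = %.3g", cmp$delta,
      cmp$p_value)
  tock("bootstrap")

  # -- tpt -----------------------------------------------------------
  tick("tpt", config$tpt)
  state_x <- state_mean_coordinate(coords[, 1], disc, model)
  A <- which(state_x < config$tpt$start_below)
  B <- which(state_x > config$tpt$end_above)
  tpt <- tryCatch({
    if (!length(A) || !length(B))
      stop("no states in the start/end basins")
    q <- committor(model, A, B)
    fl <- reactive_flux(model, q)
    mf_fwd <- mfpt(model, A, B)
    mf_rev <- mfpt(model, B, A)
    mf_err <- tryCatch(
      mfpt_with_error(ens, model$active_set[A], model$active_set[B]),
      error = function(e) NULL)
    list(committor = q, flux = fl, mfpt_forward = mf_fwd,
         mfpt_reverse = mf_rev, mfpt_bootstrap = mf_err, A = A, B = B)
  }, error = function(e) stage_fail("tpt", e))
  say("stage tpt: MFPT fwd %.4g ns, rate %.3g /ns", tpt$mfpt_forward$value,
      tpt$flux$rate)
  tock("tpt")

  result <- structure(
    list(dataset = dataset, tica = tica, disc = disc, model = model,
         fes = fes, barriers = barriers, barrier_layouts = barrier_mat,
         barrier_comparison = cmp, bootstrap_barriers = boot_barriers,
         ensemble = ens, tpt = tpt, config = config, manifest = manifest),
    class = "pipeline_result")
  if (!is.null(config$output_dir))
    result$manifest <- write_pipeline_outputs(result, config$output_dir)
  result
}

#' Mean coordinate of each MSM state
#'
#' Average of a frame coordinate over the frames assigned to each active
#' state — used to map abstract states back onto a physical axis (e.g. to
#' define start/end basins).
#'
#' @param coord Numeric vector, pooled frame order.
#' @param disc The `discretization` the model came from.
#' @param model An `msm_model`.
#' @return Numeric vector, one mean per active state.
#' @export
state_mean_coordinate <- function(coord, disc, model) {
  s <- unlist(.as_dtraj_list(disc), use.names = FALSE)
  stopifnot(length(s) == length(coord))
  vapply(model$active_set, function(st) mean(coord[s == st]), numeric(1))
}

#' Per-channel barriers for every bootstrap round
#'
#' Rebuilds the reweighted surface with each bootstrap model's stationary
#' distribution and extracts both channel barriers, giving the barrier
#' samples that [compare_barriers()] tests.
#'
#' @param coords Pooled frame coordinates (2 columns).
#' @param dtrajs Discrete trajectories (pooled order matching `coords`).
#' @param ensemble A `bootstrap_ensemble`.
#' @param bin_edges List of two edge vectors.
#' @param kT Thermal energy.
#' @return List with numeric vectors `a` and `b` (kcal/mol) and
#'   `n_failed`.
#' @export
bootstrap_channel_barriers <- function(coords, dtrajs, ensemble, bin_edges,
                                       kT = kT_at(310), min_count = 1L) {
  # The bin-by-state frame histogram H is identical for every round; a
  # round's bin masses are H %*% (pi_s / N_s), which avoids re-binning
  # 10^6-frame coordinate sets 200 times. Algebraically identical to
  # channel_barriers(reweighted_fes(...)) per round (unit-tested).
  coords <- .as_matrix(coords)
  st <- unlist(.as_dtraj_list(dtrajs), use.names = FALSE)
  n_states <- max(st)
  b1 <- .bin_index(coords[, 1], bin_edges[[1]])
  b2 <- .bin_index(coords[, 2], bin_edges[[2]])
  nb1 <- length(bin_edges[[1]]) - 1L
  nb2 <- length(bin_edges[[2]]) - 1L
  inb <- !is.na(b1) & !is.na(b2)
  bin <- (b2[inb] - 1L) * nb1 + b1[inb]
  H <- matrix(0, nb1 * nb2, n_states)
  tab <- rowsum(matrix(1, sum(inb)), bin * (n_states + 1L) + st[inb])
  key <- as.numeric(rownames(tab))
  H[cbind(key %/% (n_states + 1L), key %% (n_states + 1L))] <- tab
  N_s <- tabulate(st, nbins = n_states)
  one <- function(m) {
    w <- numeric(n_states)
    w[m$active_set] <- m$pi / N_s[m$active_set]
    mass <- H %*% w
    cnt <- rowSums(H[, m$active_set, drop = FALSE])
    F <- -kT * log(mass)
    F[!is.finite(F)] <- NA_real_
    F[cnt < min_count] <- NA_real_
    F <- F - min(F, na.rm = TRUE)
    fes <- new_fes(matrix(F, nb1, nb2), matrix(cnt, nb1, nb2),
                             bin_edges, kT)
    tryCatch(channel_barriers(fes),
             error = function(e) c(a = NA_real_, b = NA_real_))
  }
  vals <- lapply(ensemble$models, one)
  a <- vapply(vals, `[[`, numeric(1), "a")
  b <- vapply(vals, `[[`, numeric(1), "b")
  ok <- is.finite(a) & is.finite(b)
  list(a = a[ok], b = b[ok], n_failed = sum(!ok))
}

#' Write pipeline outputs and return the completed manifest
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory.
#' @return The manifest with per-file md5 hashes added.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    fes = write_fes_csv(result$fes, file.path(dir, "fes.csv")),
    msm = write_msm_json(result$model, file.path(dir, "msm.json")),
    flux = write_flux_csv(result$tpt$flux, file.path(dir, "flux.csv")))
  jsonlite::write_json(
    list(barriers = as.list(result$barriers),
         delta = result$barrier_comparison$delta,
         p_value = result$barrier_comparison$p_value,
         mfpt_forward = result$tpt$mfpt_forward$value,
         mfpt_reverse = result$tpt$mfpt_reverse$value),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  files <- c(files, summary = file.path(dir, "summary.json"))
  man <- result$manifest
  man$outputs <- as.list(tools::md5sum(files))
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, force = TRUE)
  man
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Translocation pipeline result\n")
  cat(sprintf("  trajectories: %d; active states: %d\n",
              length(x$dataset$trajectories), nrow(x$model$T)))
  cat(sprintf("  channel barriers: a = %.2f, b = %.2f kcal/mol (p = %.3g)\n",
              x$barriers["a"], x$barriers["b"],
              x$barrier_comparison$p_value))
  cat(sprintf("  MFPT forward %.4g, reverse %.4g (frame-time units)\n",
              x$tpt$mfpt_forward$value, x$tpt$mfpt_reverse$value))
  invisible(x)
}

#' Plain-text report of a pipeline run
#'
#' Tables of barriers, MFPTs and stage provenance, written to a file.
#'
#' @param result A `pipeline_result`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
pipeline_report <- function(result, file) {
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("Translocation analysis report (msmflux %s)",
    as.character(utils::packageVersion("msmflux")))
  w("master seed: %d", result$config$master_seed)
  w("")
  w("Barriers (kcal/mol):")
  w("  channel a: %.3f +/- %.3f", result$barrier_comparison$barrier_a,
    result$barrier_comparison$sd_a)
  w("  channel b: %.3f +/- %.3f", result$barrier_comparison$barrier_b,
    result$barrier_comparison$sd_b)
  w("  delta a-b: %.3f (Welch p = %.4g)", result$barrier_comparison$delta,
    result$barrier_comparison$p_value)
  w("")
  w("Kinetics (frame-time units):")
  w("  MFPT forward: %.5g", result$tpt$mfpt_forward$value)
  w("  MFPT reverse: %.5g", result$tpt$mfpt_reverse$value)
  if (!is.null(result$tpt$mfpt_bootstrap))
    w("  MFPT forward bootstrap: %.5g +/- %.5g",
      result$tpt$mfpt_bootstrap$value, result$tpt$mfpt_bootstrap$err)
  w("  TPT rate: %.5g", result$tpt$flux$rate)
  w("")
  w("Stages:")
  for (nm in names(result$manifest$stages))
    w("  %-10s %8.2fs", nm, result$manifest$stages[[nm]]$wall_s)
  invisible(file)
}
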