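#' Read / write a pipeline configuration file
#'
#' Single structured (YAML) config covering the flight parameters, the
#' kinematic-program sampling controls and the seed.  Waveforms themselves
#' are code, not configuration; the config selects the packaged default
#' program shapes.
#'
#' @param path YAML file.
#' @return `read_pipeline_config` returns a validated list with elements
#'   `flight` (a [flight_config()]), `program` (a [kinematic_program()])
#'   and `seed`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  fl <- raw$flight
  need <- c("U", "rho", "M", "f_beat", "beta", "Phi", "R", "S_ref", "chi_b", "dt")
  for (nm in need)
    if (is.null(fl[[nm]]))
      stop("read_pipeline_config: flight config is missing field `", nm, "`",
           call. = FALSE)
  if (is.null(fl$Re) && is.null(fl$nu))
    stop("read_pipeline_config: flight config is missing field `Re` (or `nu`)",
         call. = FALSE)
  cfg <- flight_config(U = fl$U, rho = fl$rho, M = fl$M,
                       g = if (is.null(fl$g)) 9.81 else fl$g,
                       f_beat = fl$f_beat, beta = fl$beta, Phi = fl$Phi,
                       R = fl$R, S_ref = fl$S_ref, chi_b = fl$chi_b,
                       dt = fl$dt, Re = fl$Re, nu = fl$nu)
  pr <- raw$program
  prog <- default_kinematic_program(
    cfg,
    n_frames_per_cycle = if (is.null(pr$n_frames_per_cycle)) 22L else pr$n_frames_per_cycle,
    n_cycles = if (is.null(pr$n_cycles)) 3L else pr$n_cycles,
    noise_sd = if (is.null(pr$noise_sd)) 2e-4 else pr$noise_sd)
  list(flight = cfg, program = prog,
       seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed))
}

#' @rdname read_pipeline_config
#' @param config list as returned by `read_pipeline_config` (or built from
#'   [default_calliope_config()] / [default_kinematic_program()]).
#' @export
write_pipeline_config <- function(config, path) {
  fl <- config$flight
  yaml::write_yaml(list(
    flight = fl[c("U", "rho", "M", "g", "f_beat", "beta", "Phi", "R",
                  "S_ref", "chi_b", "dt", "Re")],
    program = config$program[c("n_frames_per_cycle", "n_cycles", "noise_sd")],
    seed = config$seed), path)
  invisible(path)
}

# wrap a pipeline stage so errors carry the stage name
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage ", stage, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the kinematics pipeline
#'
#' End-to-end: synthetic marker generation, wing-surface reconstruction for
#' both wings, temporal refinement, kinematic descriptors and cycle
#' summaries.  Deterministic for a fixed seed.
#'
#' @param config list with `flight`, `program`, `seed` (see
#'   [read_pipeline_config()]); defaults to the calliope configuration.
#' @param target_elements triangle-count target per wing frame.
#' @param refinement_factor temporal refinement of the marker frames.
#' @param out_dir optional directory for marker/metric tables and the
#'   manifest.
#' @return List: `markers`, `meshes` (left/right refined [wing_mesh()]),
#'   `series` (left-wing [kinematics_series()]), `summaries`
#'   ([cycle_summaries()] plus twist extrema), `manifest`.
#' @export
run_kinematics_pipeline <- function(config = NULL, target_elements = 340L,
                                    refinement_factor = 4L, out_dir = NULL) {
  if (is.null(config))
    config <- list(flight = default_calliope_config(),
                   program = default_kinematic_program(default_calliope_config()),
                   seed = 1L)
  cfg <- config$flight; prog <- config$program

  markers <- run_stage("generate", generate_markers(cfg, prog, seed = config$seed))
  meshes <- run_stage("reconstruct", {
    lapply(list(left = "left", right = "right"), function(w)
      refine_in_time(reconstruct_wing_series(markers, w, target_elements),
                     prog$n_frames_per_cycle, refinement_factor))
  })
  series <- run_stage("metrics", kinematics_series(meshes$left, cfg))
  summaries <- run_stage("summaries", {
    cs <- cycle_summaries(series, cfg)
    pa <- phase_average(series$twist, series$time_s, cfg$f_beat, n_bins = 44L)
    cs$twist_min <- min(pa$mean, na.rm = TRUE)
    cs$twist_max <- max(pa$mean, na.rm = TRUE)
    cs$twist_min_phase <- pa$phase[which.min(pa$mean)]
    cs$twist_max_phase <- pa$phase[which.max(pa$mean)]
    cs
  })
  manifest <- list(
    pipeline = "kinematics",
    package_version = as.character(utils::packageVersion("flapwing")),
    seed = config$seed,
    n_frames_per_cycle = prog$n_frames_per_cycle,
    n_cycles = prog$n_cycles,
    noise_sd = prog$noise_sd,
    target_elements = target_elements,
    refinement_factor = refinement_factor,
    summaries = summaries)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_markers(markers, file.path(out_dir, "markers.csv"))
    write.csv(series, file.path(out_dir, "kinematics_series.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(markers = markers, meshes = meshes, series = series,
       summaries = summaries, manifest = manifest)
}

#' Grid/solver profile for the flow pipeline
#'
#' `desk`: reduced Reynolds number (300) and resolution sized to run on a
#' single CPU in minutes; `production-emulation`: the full-scale
#' configuration (Reynolds number 3000, 1/60 cm fine spacing, 5 us step,
#' hundreds of millions of points) documented for completeness -- running
#' it requires cluster-class resources and an explicit opt-in.
#'
#' @param profile `"desk"` or `"production-emulation"`.
#' @param config a [flight_config()].
#' @return List of grid and solver parameters.
#' @export
flow_profile <- function(profile = c("desk", "production-emulation"),
                         config = default_calliope_config()) {
  profile <- match.arg(profile)
  cb <- config$c_bar
  if (profile == "desk") {
    list(profile = profile, Re = 300,
         domain = list(c(-0.075, 0.105), c(-0.07, 0.07), c(-0.06, 0.06)),
         fine_block = list(c(-0.036, 0.036), c(-0.056, 0.056), c(-0.046, 0.038)),
         h_fine = cb / 5, stretch = 1.1, cfl = 0.45,
         ib_support = 0.4 * cb / 5, sponge_eps = 0.08,
         poisson_tol = 1e-5, target_elements = 340L)
  } else {
    list(profile = profile, Re = 3000,
         domain = list(c(-0.11, 0.14), c(-0.10, 0.10), c(-0.08, 0.08)),
         fine_block = list(c(-0.045, 0.045), c(-0.06, 0.06), c(-0.05, 0.045)),
         h_fine = 1 / 6000, stretch = 1.05, cfl = 0.5,
         ib_support = NULL, sponge_eps = 0,
         poisson_tol = 1e-6, target_elements = 1335L)
  }
}

#' Run the flow-simulation pipeline
#'
#' Simulates the flow around the flapping wings and body (mode `"full"`)
#' or around the isolated static body with identical mesh, orientation and
#' grid (mode `"isolated_body"`), then post-processes surface tractions
#' into the coefficient series and derived performance summary.
#'
#' The first `transient_cycles` wingbeats are excluded from averages.
#'
#' @param kin result of [run_kinematics_pipeline()] (ignored in
#'   isolated-body mode except for configuration).
#' @param config list with `flight` (and optionally `seed`); defaults to
#'   the calliope configuration.
#' @param profile `"desk"` (default) or `"production-emulation"` (refused
#'   without `opt_in_production = TRUE`: the full-scale run needs cluster
#'   resources).
#' @param mode `"full"` or `"isolated_body"`.
#' @param n_cycles wingbeat cycles to simulate.
#' @param transient_cycles initial cycles excluded from averages.
#' @param force_every evaluate tractions every this many steps.
#' @param opt_in_production explicit opt-in for the production profile.
#' @param out_dir optional output directory (force table, summary, VTK
#'   snapshot, manifest).
#' @param snapshot_phase cycle phase (of the last cycle) at which to export
#'   a VTK field snapshot when `out_dir` is set; NULL disables.
#' @param verbose print per-cycle progress.
#' @param overrides named list overriding profile entries (e.g. `h_fine`).
#' @return List of class `flow_run`: `force_series`, `averages`
#'   (stroke-resolved means), `performance` (full mode), `grid`, `manifest`,
#'   and `state` (final [flow_state()]).
#' @export
run_flow_pipeline <- function(kin = NULL, config = NULL,
                              profile = "desk", mode = c("full", "isolated_body"),
                              n_cycles = 2, transient_cycles = 1,
                              force_every = 2L, opt_in_production = FALSE,
                              out_dir = NULL, snapshot_phase = NULL,
                              verbose = interactive(), overrides = list()) {
  mode <- match.arg(mode)
  if (is.null(config))
    config <- list(flight = default_calliope_config(), seed = 1L)
  cfg <- config$flight
  prof <- flow_profile(profile, cfg)
  if (prof$profile == "production-emulation" && !opt_in_production)
    stop("run_flow_pipeline: the production-emulation profile needs ",
         "hundreds of millions of grid points and cluster-class resources; ",
         "pass opt_in_production = TRUE to proceed anyway", call. = FALSE)
  prof[names(overrides)] <- overrides

  if (mode == "full" && is.null(kin))
    stop("run_flow_pipeline: full mode needs a kinematics pipeline result", call. = FALSE)

  grid <- run_stage("grid", build_grid(prof$domain, prof$fine_block, prof$h_fine,
                                       stretch = prof$stretch, Uin = cfg$U))
  body <- run_stage("body", build_body(cfg))
  nu_run <- cfg$U * cfg$c_bar / prof$Re

  # time step from the expected peak speed (freestream + wingtip)
  v_ref <- cfg$U + pi * cfg$f_beat * deg2rad(cfg$Phi) * cfg$R
  dt <- prof$cfl * min(grid$h_fine) / v_ref
  period <- 1 / cfg$f_beat
  n_steps <- ceiling(n_cycles * period / dt)
  settings <- solver_settings(dt = dt, nu = nu_run, rho = cfg$rho,
                              poisson_tol = prof$poisson_tol,
                              cfl_max = 1)
  if (!is.null(prof$sponge_eps) && prof$sponge_eps > 0)
    settings$sponge <- list(w_u = sponge_weights(grid, 1),
                            w_v = sponge_weights(grid, 2),
                            w_w = sponge_weights(grid, 3),
                            eps = prof$sponge_eps)

  motions <- NULL
  if (mode == "full") {
    nfpc_dense <- dim(kin$meshes$left$nodes)[3] / kin$markers$program$n_cycles
    motions <- lapply(kin$meshes, mesh_motion, n_frames_per_cycle = nfpc_dense)
  }
  ib_static <- classify_cells(grid, body = body)

  state <- flow_state(grid)
  rows <- list()
  q <- 0.5 * cfg$rho * cfg$U^2 * cfg$S_ref
  wing_tris <- if (mode == "full") kin$meshes$left$triangles else NULL

  t_wall0 <- Sys.time()
  for (s in seq_len(n_steps)) {
    t_now <- state$t
    ib <- ib_static
    wings <- list()
    if (mode == "full") {
      wings <- lapply(names(motions), function(w) {
        wing_mesh(motions[[w]]$position(t_now), wing_tris,
                  node_velocities = motions[[w]]$velocity(t_now), side = w)
      })
      names(wings) <- names(motions)
      ib <- classify_cells(grid, body = body, wings = wings,
                           support = prof$ib_support,
                           include_center = FALSE)
    }
    # adaptive sub-stepping: transient velocity spikes near the forced
    # membrane occasionally exceed the nominal CFL budget; split the step
    # (first-order restart) rather than aborting the run
    vmax <- max(abs(state$u), abs(state$v), abs(state$w))
    n_sub <- max(1L, ceiling(vmax * dt / (0.7 * min(grid$h_fine))))
    state <- run_stage("simulate", {
      take <- function(st0, n_sub) {
        if (n_sub == 1L) return(advance_timestep(st0, grid, settings, ib))
        sub <- settings
        sub$dt <- dt / n_sub
        for (ss in seq_len(n_sub)) st0 <- advance_timestep(st0, grid, sub, ib)
        st0
      }
      done <- FALSE; attempt <- state
      while (!done && n_sub <= 16L) {
        attempt <- tryCatch({ done <- TRUE; take(state, n_sub) },
                            error = function(e) {
                              if (!grepl("CFL", conditionMessage(e))) stop(e)
                              done <<- FALSE
                              n_sub <<- n_sub * 2L
                              NULL
                            })
      }
      if (!done) stop("time step failed repeatedly at t = ", state$t)
      attempt
    })

    if (s %% force_every == 0L) {
      phase <- (state$t * cfg$f_beat) %% 1
      row <- list(time_s = state$t, phase = phase,
                  stroke = if (phase < 0.5) "down" else "up")
      tb <- surface_traction(state, grid, body, cfg$rho, nu_run, closed = TRUE)
      fb <- integrate_forces(tb$traction, tb$areas)
      row$C_Z_b <- fb[["F_Z"]] / q
      row$C_D_b <- fb[["F_X"]] / q
      row$C_Y_b <- fb[["F_Y"]] / q
      if (mode == "full") {
        for (w in names(wings)) {
          tw <- surface_traction(state, grid, wings[[w]], cfg$rho, nu_run,
                                 closed = FALSE)
          fw <- integrate_forces(tw$traction, tw$areas)
          tri <- wings[[w]]$triangles
          nv <- wings[[w]]$node_velocities
          cvel <- (nv[tri[, 1], ] + nv[tri[, 2], ] + nv[tri[, 3], ]) / 3
          cp <- power_coefficient(-tw$traction, cvel, tw$areas, cfg)
          row[[paste0("C_Z_", w)]] <- fw[["F_Z"]] / q
          row[[paste0("C_T_", w)]] <- fw[["F_T"]] / q
          row[[paste0("C_Y_", w)]] <- fw[["F_Y"]] / q
          row[[paste0("C_P_", w)]] <- cp
        }
      }
      rows[[length(rows) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
    if (verbose && s %% max(1L, round(n_steps / n_cycles / 4)) == 0L)
      message(sprintf("  step %d/%d (t = %.4g s, %.1f s wall, Poisson %d it)",
                      s, n_steps, state$t,
                      as.numeric(difftime(Sys.time(), t_wall0, units = "secs")),
                      state$poisson$iterations))
  }
  fs <- do.call(rbind, rows)
  if (mode == "full") {
    fs$C_Z <- (fs$C_Z_left + fs$C_Z_right) / 2
    fs$C_T <- (fs$C_T_left + fs$C_T_right) / 2
    fs$C_P <- (fs$C_P_left + fs$C_P_right) / 2
    fs$C_Y_total <- fs$C_Y_left + fs$C_Y_right + fs$C_Y_b
  }
  fs <- force_series(fs)

  measured <- fs[fs$time_s > transient_cycles * period - 1e-12, , drop = FALSE]
  avg_cols <- intersect(c("C_Z", "C_T", "C_P", "C_Y_total", "C_Z_b", "C_D_b"),
                        names(measured))
  averages <- stroke_averages(measured, cols = avg_cols)
  performance <- NULL
  if (mode == "full")
    performance <- performance_summary(
      C_Z = averages["whole_cycle", "C_Z"], C_T = averages["whole_cycle", "C_T"],
      C_P = averages["whole_cycle", "C_P"],
      C_Z_b = averages["whole_cycle", "C_Z_b"],
      C_D_b = averages["whole_cycle", "C_D_b"], config = cfg)

  manifest <- list(
    pipeline = "flow", mode = mode, profile = prof$profile,
    package_version = as.character(utils::packageVersion("flapwing")),
    Re = prof$Re, nu = nu_run, dt = dt, n_steps = n_steps,
    n_cycles = n_cycles, transient_cycles = transient_cycles,
    grid_dims = grid$dims, h_fine = prof$h_fine,
    seed = if (is.null(config$seed)) NA else config$seed,
    wall_time_s = as.numeric(difftime(Sys.time(), t_wall0, units = "secs")))

  out <- list(force_series = fs, averages = averages, performance = performance,
              grid = grid, manifest = manifest, state = state,
              classification = if (mode == "full") NULL else ib_static)
  class(out) <- "flow_run"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(fs, file.path(out_dir, paste0("forces_", mode, ".csv")),
              row.names = FALSE)
    write.csv(averages, file.path(out_dir, paste0("averages_", mode, ".csv")))
    jsonlite::write_json(manifest, file.path(out_dir, paste0("manifest_", mode, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(snapshot_phase)) {
      cv <- cpp_center_velocity(state$u, state$v, state$w, grid_cpp(grid))
      write_vtk(file.path(out_dir, paste0("snapshot_", mode, ".vtk")), grid,
                scalars = list(p = array(state$p, grid$dims),
                               swirl = swirl_field(state, grid)),
                velocity = cv)
    }
  }
  out
}

#' @export
print.flow_run <- function(x, ...) {
  cat(sprintf("<flow_run> %s / %s: %d force samples, grid %s\n",
              x$manifest$profile, x$manifest$mode, nrow(x$force_series),
              paste(x$manifest$grid_dims, collapse = "x")))
  print(round(x$averages, 4))
  if (!is.null(x$performance)) print(x$performance)
  invisible(x)
}
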