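#' Create a flow state on a staggered grid
#'
#' Velocity components live on face centres (MAC layout), pressure at cell
#' centres.  The state starts as a uniform stream `u = Uin` (or a supplied
#' initial condition) with zero pressure.
#'
#' @param grid a [build_grid()] result.
#' @param u0,v0,w0 optional initial arrays with the staggered dimensions.
#' @return Object of class `flow_state`: arrays `u`, `v`, `w`, `p`, time
#'   `t`, and the previous-step tendencies used by the Adams-Bashforth
#'   scheme.
#' @export
flow_state <- function(grid, u0 = NULL, v0 = NULL, w0 = NULL) {
  mk <- function(comp, init) {
    d <- stag_dims(grid, comp)
    if (is.null(init)) array(if (comp == 1) grid$Uin else 0, d)
    else {
      stopifnot(all(dim(init) == d))
      init
    }
  }
  structure(list(u = mk(1, u0), v = mk(2, v0), w = mk(3, w0),
                 p = array(0, grid$dims), t = 0,
                 rhs_prev = NULL, n_step = 0L),
            class = "flow_state")
}

#' @export
print.flow_state <- function(x, ...) {
  cat(sprintf("<flow_state> t = %.6g s, step %d, max|u| = %.4g m/s\n",
              x$t, x$n_step, max(abs(x$u), abs(x$v), abs(x$w))))
  invisible(x)
}

#' Solver settings
#'
#' @param dt time step, s.
#' @param nu kinematic viscosity, m^2/s.
#' @param rho fluid density, kg/m^3 (used to report pressure in Pa).
#' @param poisson_tol relative residual tolerance of the pressure solve.
#' @param poisson_max_cycles multigrid V-cycle cap before the solver raises
#'   a divergence error.
#' @param cfl_max maximum admissible convective CFL number.
#' @return List of class `solver_settings`.
#' @export
solver_settings <- function(dt, nu, rho = 1, poisson_tol = 1e-6,
                            poisson_max_cycles = 60L, cfl_max = 1) {
  structure(list(dt = dt, nu = nu, rho = rho, poisson_tol = poisson_tol,
                 poisson_max_cycles = as.integer(poisson_max_cycles),
                 cfl_max = cfl_max),
            class = "solver_settings")
}

#' Classify grid cells against immersed bodies
#'
#' Cells inside a closed body surface are solid (ray-parity test); staggered
#' velocity faces inside the body, or within `support` of a zero-thickness
#' wing membrane, are forcing points that carry the local surface velocity.
#' Fresh cells (solid-to-fluid transitions between consecutive
#' classifications) are obtained by comparing with a previous
#' classification.
#'
#' @param grid a [build_grid()].
#' @param body optional closed [wing_mesh()] (watertight; static, zero
#'   velocity).
#' @param wings list of membrane [wing_mesh()] objects.
#' @param it frame index into time-resolved meshes.
#' @param support forcing support distance for membranes, m; default
#'   0.6 of the fine spacing.
#' @param previous optional previous classification for fresh-cell flags.
#' @param include_center compute the cell-centre classification array
#'   (skippable inside the time loop, where only face forcing is needed).
#' @return Object of class `cell_class`: `center` integer array (0 fluid,
#'   1 solid, 2 interface; NULL when skipped), `forcing` (per component
#'   `u`/`v`/`w`: 1-based linear `idx` into the staggered array and target
#'   velocity `val`), and `fresh` (logical array or NULL).
#' @export
classify_cells <- function(grid, body = NULL, wings = list(), it = 1L,
                           support = NULL, previous = NULL,
                           include_center = TRUE) {
  if (is.null(support)) support <- 0.6 * min(grid$h_fine)
  dims <- grid$dims
  center <- if (include_center) array(0L, dims) else NULL
  coords <- list(u = list(grid$xf[seq_len(stag_dims(grid, 1)[1])], grid$yc, grid$zc),
                 v = list(grid$xc, grid$yf[seq_len(stag_dims(grid, 2)[2])], grid$zc),
                 w = list(grid$xc, grid$yc, grid$zf[seq_len(stag_dims(grid, 3)[3])]))
  # accumulate (idx, dist, val) per component; nearest surface wins,
  # body-solid points (dist -1) always win
  acc <- list(u = NULL, v = NULL, w = NULL)
  add <- function(a, idx, dist, val) {
    if (is.null(a)) return(list(idx = idx, dist = dist, val = val))
    list(idx = c(a$idx, idx), dist = c(a$dist, dist), val = c(a$val, val))
  }

  if (!is.null(body)) {
    if (!is_watertight(body))
      stop("classify_cells: body mesh is not watertight", call. = FALSE)
    nd <- mesh_frame_nodes(body, 1L)
    if (include_center) {
      solid_c <- cpp_classify_solid(grid$xc, grid$yc, grid$zc, nd, body$triangles)
      center[array(solid_c, dims)] <- 1L
    }
    for (cm in c("u", "v", "w")) {
      co <- coords[[cm]]
      sm <- which(cpp_classify_solid(co[[1]], co[[2]], co[[3]], nd, body$triangles))
      acc[[cm]] <- add(acc[[cm]], sm, rep(-1, length(sm)), rep(0, length(sm)))
    }
  }

  for (wg in wings) {
    nd <- mesh_frame_nodes(wg, it)
    vel <- if (!is.null(wg$node_velocities)) {
      if (length(dim(wg$node_velocities)) == 3) wg$node_velocities[, , it]
      else wg$node_velocities
    } else matrix(0, nrow(nd), 3)
    if (include_center) {
      cl_c <- cpp_classify_membrane(grid$xc, grid$yc, grid$zc, nd, vel,
                                    wg$triangles, support)
      iface <- cl_c$idx[center[cl_c$idx] == 0L]
      center[iface] <- 2L
    }
    for (cm in c("u", "v", "w")) {
      co <- coords[[cm]]
      cl <- cpp_classify_membrane(co[[1]], co[[2]], co[[3]], nd, vel,
                                  wg$triangles, support)
      acc[[cm]] <- add(acc[[cm]], cl$idx, cl$dist, cl[[cm]])
    }
  }

  forcing <- lapply(acc, function(a) {
    if (is.null(a)) return(list(idx = integer(0), val = numeric(0)))
    o <- order(a$idx, a$dist)
    keep <- o[!duplicated(a$idx[o])]
    list(idx = a$idx[keep], val = a$val[keep])
  })

  fresh <- NULL
  if (!is.null(previous) && !is.null(previous$center) && !is.null(center))
    fresh <- previous$center != 0L & center == 0L
  structure(list(center = center, forcing = forcing,
                 fresh = fresh, support = support),
            class = "cell_class")
}

#' Solve the pressure Poisson equation by geometric multigrid
#'
#' Cell-centred V-cycle multigrid with red-black Gauss-Seidel smoothing on
#' the non-uniform grid; Neumann conditions at non-periodic boundaries.  For
#' all-Neumann/periodic problems the right-hand side is made compatible by
#' subtracting its volume mean, which is reported.
#'
#' @param rhs right-hand-side array (`grid$dims`).
#' @param grid a [build_grid()].
#' @param tol relative residual tolerance.
#' @param max_cycles V-cycle cap.
#' @param compat_threshold error if the compatibility correction exceeds
#'   this fraction of the rhs RMS (`Inf` disables the check).
#' @return List: `p` (zero-mean solution array), `iterations`, `relres`,
#'   `residual_history`, `compat_correction`.
#' @export
solve_poisson_multigrid <- function(rhs, grid, tol = 1e-7, max_cycles = 60L,
                                    compat_threshold = Inf) {
  sol <- cpp_poisson_mg(as.vector(rhs), grid_cpp(grid), tol, as.integer(max_cycles))
  rms <- sqrt(mean(as.vector(rhs)^2))
  if (is.finite(compat_threshold) && rms > 0 &&
      abs(sol$compat_correction) > compat_threshold * rms)
    stop("solve_poisson_multigrid: incompatible rhs (correction ",
         signif(sol$compat_correction, 4), " exceeds threshold)", call. = FALSE)
  if (sol$relres > tol)
    stop("solve_poisson_multigrid: no convergence in ", max_cycles,
         " V-cycles (relative residual ", signif(sol$relres, 3), ")", call. = FALSE)
  sol
}

#' Advance the flow by one time step
#'
#' Fractional-step update: explicit second-order Adams-Bashforth
#' convection + diffusion to a provisional velocity; direct-forcing
#' immersed-boundary correction imposing the local surface velocity at
#' forcing faces; physical boundary conditions (uniform inflow, zero-
#' gradient outflow with global mass balance, free-slip lateral); pressure
#' Poisson solve; projection to a divergence-free field.
#'
#' @param state a [flow_state()].
#' @param grid a [build_grid()].
#' @param settings a [solver_settings()].
#' @param ib optional [classify_cells()] result for the current time.
#' @return Updated `flow_state` (with `p` the projection pressure field,
#'   `poisson` diagnostics and the step count advanced).
#' @export
advance_timestep <- function(state, grid, settings, ib = NULL) {
  dt <- settings$dt
  cfl <- max(abs(state$u), abs(state$v), abs(state$w)) * dt /
    min(diff(grid$xf), diff(grid$yf), diff(grid$zf))
  if (!is.finite(cfl) || cfl > settings$cfl_max)
    stop("advance_timestep: CFL = ", signif(cfl, 3), " exceeds ",
         settings$cfl_max, " (unstable step or diverged state)", call. = FALSE)

  g <- grid_cpp(grid)
  rhs <- cpp_conv_diff(state$u, state$v, state$w, g, settings$nu)
  if (is.null(state$rhs_prev)) {
    us <- state$u + dt * rhs$du
    vs <- state$v + dt * rhs$dv
    ws <- state$w + dt * rhs$dw
  } else {
    # variable-step Adams-Bashforth weights (reduce to 3/2, -1/2 for a
    # constant step) keep second order across adaptive step changes
    r <- dt / state$dt_prev
    w1 <- 1 + r / 2; w0 <- -r / 2
    us <- state$u + dt * (w1 * rhs$du + w0 * state$rhs_prev$du)
    vs <- state$v + dt * (w1 * rhs$dv + w0 * state$rhs_prev$dv)
    ws <- state$w + dt * (w1 * rhs$dw + w0 * state$rhs_prev$dw)
  }
  bc <- cpp_apply_bc(us, vs, ws, g, dt)
  us <- bc$u; vs <- bc$v; ws <- bc$w

  if (!is.null(ib)) {
    us[ib$forcing$u$idx] <- ib$forcing$u$val
    vs[ib$forcing$v$idx] <- ib$forcing$v$val
    ws[ib$forcing$w$idx] <- ib$forcing$w$val
  }

  div <- cpp_divergence(us, vs, ws, g)
  p0 <- if (state$n_step > 0L) as.vector(state$p) / settings$rho else NULL
  if (is.null(grid$cache$mgctx)) grid$cache$mgctx <- cpp_mg_setup(g)
  sol <- cpp_poisson_mg(as.vector(div) / dt, g, settings$poisson_tol,
                        settings$poisson_max_cycles, p0 = p0,
                        ctx_ptr = grid$cache$mgctx)
  if (sol$relres > settings$poisson_tol)
    stop("advance_timestep: Poisson solver failed to converge (relative residual ",
         signif(sol$relres, 3), "); residual history: ",
         paste(signif(sol$residual_history, 3), collapse = " "), call. = FALSE)
  pr <- cpp_project(us, vs, ws, sol$p, g, dt)

  state$u <- pr$u; state$v <- pr$v; state$w <- pr$w
  if (!is.null(settings$sponge)) {
    sp <- settings$sponge
    state$u <- sponge_filter(state$u, sp$w_u, sp$eps)
    state$v <- sponge_filter(state$v, sp$w_v, sp$eps)
    state$w <- sponge_filter(state$w, sp$w_w, sp$eps)
  }
  state$p <- array(sol$p * settings$rho, grid$dims)   # physical pressure, Pa
  state$t <- state$t + dt
  state$n_step <- state$n_step + 1L
  state$rhs_prev <- rhs
  state$dt_prev <- dt
  state$poisson <- list(iterations = sol$iterations, relres = sol$relres)
  state
}

#' Absorbing-layer smoothing for the stretched outer grid
#'
#' Weak local averaging applied only where the grid is coarse (an absorbing
#' "sponge" ahead of the outflow and lateral boundaries): damps grid-scale
#' oscillations in regions whose resolution is sacrificed anyway, leaving
#' the fine block untouched.
#'
#' @param arr staggered velocity array.
#' @param w per-point sponge weight in \[0,1\] (0 inside the fine block).
#' @param eps smoothing strength per step.
#' @return Filtered array.
#' @keywords internal
sponge_filter <- function(arr, w, eps) {
  if (eps <= 0 || max(w) <= 0) return(arr)
  d <- dim(arr)
  sh <- function(axis, off) {
    i <- pmin(pmax(seq_len(d[axis]) + off, 1L), d[axis])
    ii <- rep(list(quote(expr = )), 3); ii[[axis]] <- i
    do.call(`[`, c(list(arr), ii, list(drop = FALSE)))
  }
  avg <- (sh(1, 1) + sh(1, -1) + sh(2, 1) + sh(2, -1) + sh(3, 1) + sh(3, -1)) / 6
  arr + (eps * w) * (avg - arr)
}

# per-point sponge weights for one staggered component: ramps from 0 where
# all local spacings are near the fine spacing to 1 in the coarse regions
sponge_weights <- function(grid, comp, ramp_lo = 1.25, ramp_hi = 2.0) {
  d <- stag_dims(grid, comp)
  coords <- list(
    list(grid$xf[seq_len(d[1])], grid$yc, grid$zc),
    list(grid$xc, grid$yf[seq_len(d[2])], grid$zc),
    list(grid$xc, grid$yc, grid$zf[seq_len(d[3])]))[[comp]]
  spac <- list(x = diff(grid$xf), y = diff(grid$yf), z = diff(grid$zf))
  h0 <- min(grid$h_fine)
  wax <- function(ax_coords, faces, dxv) {
    idx <- pmin(pmax(findInterval(ax_coords, faces), 1L), length(dxv))
    pmin(pmax((dxv[idx] / h0 - ramp_lo) / (ramp_hi - ramp_lo), 0), 1)
  }
  w1 <- wax(coords[[1]], grid$xf, spac$x)
  w2 <- wax(coords[[2]], grid$yf, spac$y)
  w3 <- wax(coords[[3]], grid$zf, spac$z)
  arr <- array(0, d)
  arr <- pmax(array(w1, d),
              aperm(array(rep(w2, each = 1), d[c(2, 1, 3)]), c(2, 1, 3)),
              aperm(array(w3, d[c(3, 2, 1)]), c(3, 2, 1)))
  arr
}

#' Discrete divergence of the velocity field
#'
#' @param state a [flow_state()].
#' @param grid a [build_grid()].
#' @return Array of per-cell divergence (1/s).
#' @export
divergence <- function(state, grid) {
  array(cpp_divergence(state$u, state$v, state$w, grid_cpp(grid)), grid$dims)
}

#' Sample the velocity field at arbitrary points
#'
#' Trilinear interpolation of each staggered component.
#'
#' @param state a [flow_state()].
#' @param grid a [build_grid()].
#' @param points `n x 3` matrix of coordinates, m.
#' @return `n x 3` matrix of velocities, m/s.
#' @export
interp_velocity <- function(state, grid, points) {
  cpp_interp_velocity(state$u, state$v, state$w, grid_cpp(grid),
                      as.matrix(points))
}

#' Surface traction on an immersed mesh
#'
#' Evaluates the fluid traction (Pa) on each triangle by probing pressure
#' and velocity gradients a short distance along the triangle normal.  For
#' zero-thickness membranes both sides are probed and the traction is the
#' jump; for closed surfaces only the outside (along the outward normal) is
#' probed.
#'
#' @param state a [flow_state()].
#' @param grid a [build_grid()].
#' @param mesh a [wing_mesh()].
#' @param rho fluid density, kg/m^3 (dynamic viscosity is `rho * nu`).
#' @param nu kinematic viscosity, m^2/s.
#' @param it frame index.
#' @param closed TRUE for a watertight body, FALSE for a membrane.
#' @param offset probe distance, m; default 1.4 of the fine spacing.
#' @return List: `traction` (`m x 3`, Pa), `areas` (m^2), `normals`,
#'   `centroids`.
#' @export
surface_traction <- function(state, grid, mesh, rho, nu, it = 1L,
                             closed = identical(mesh$side, "body"),
                             offset = NULL) {
  if (is.null(offset)) offset <- 1.4 * min(grid$h_fine)
  cen <- triangle_centroids(mesh, it)
  nrm <- triangle_normals(mesh, it)
  ar <- triangle_areas(mesh, it)
  m <- nrow(cen)
  dom <- rbind(range(grid$xf), range(grid$yf), range(grid$zf))
  if (any(cen[, 1] < dom[1, 1] | cen[, 1] > dom[1, 2] |
          cen[, 2] < dom[2, 1] | cen[, 2] > dom[2, 2] |
          cen[, 3] < dom[3, 1] | cen[, 3] > dom[3, 2]))
    stop("surface_traction: triangle outside the grid", call. = FALSE)
  g <- grid_cpp(grid)
  mu <- rho * nu
  h <- min(grid$h_fine)

  probe_side <- function(sgn) {
    pts <- cen + sgn * offset * nrm
    p <- cpp_interp_center(as.vector(state$p), g, pts)
    # velocity gradient at the probe by central differencing of samples
    allpts <- matrix(0, m * 6, 3)
    for (d in 1:3) {
      e <- diag(3)[d, ]
      allpts[(d - 1) * 2 * m + seq_len(m), ] <- sweep(pts, 2, 0.5 * h * e, "+")
      allpts[(d - 1) * 2 * m + m + seq_len(m), ] <- sweep(pts, 2, 0.5 * h * e, "-")
    }
    vel <- cpp_interp_velocity(state$u, state$v, state$w, g, allpts)
    gradu <- array(0, c(m, 3, 3))   # gradu[,i,j] = d u_i / d x_j
    for (d in 1:3) {
      vp <- vel[(d - 1) * 2 * m + seq_len(m), , drop = FALSE]
      vm <- vel[(d - 1) * 2 * m + m + seq_len(m), , drop = FALSE]
      gradu[, , d] <- (vp - vm) / h
    }
    # viscous traction mu (grad u + grad u^T) . n
    tv <- matrix(0, m, 3)
    for (i in 1:3)
      for (j in 1:3)
        tv[, i] <- tv[, i] + mu * (gradu[, i, j] + gradu[, j, i]) * nrm[, j]
    list(p = p, tv = tv)
  }

  if (closed) {
    # two probe distances, linearly extrapolated to the surface: the shear
    # varies quickly across the boundary layer and a single off-surface
    # sample under-reads the viscous traction
    out1 <- probe_side(+1)
    offset2 <- offset + 0.8 * h
    pts2 <- cen + offset2 * nrm
    save_offset <- offset
    offset <- offset2
    out2 <- probe_side(+1)
    offset <- save_offset
    wex <- offset2 / (offset2 - offset)    # extrapolation weights to 0
    traction <- -(wex * out1$p + (1 - wex) * out2$p) * nrm +
      (wex * out1$tv + (1 - wex) * out2$tv)
  } else {
    plus <- probe_side(+1)
    minus <- probe_side(-1)
    traction <- (minus$p - plus$p) * nrm + (plus$tv - minus$tv)
  }
  list(traction = traction, areas = ar, normals = nrm, centroids = cen)
}
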