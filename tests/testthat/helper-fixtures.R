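# shared fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

deg2rad_ <- function(x) x * pi / 180

# UV-sphere triangle mesh (watertight, outward normals)
uv_sphere <- function(r = 0.02, centre = c(0, 0, 0), n_ax = 40L, n_ci = 48L) {
  xi <- seq(0, pi, length.out = n_ax)
  th <- 2 * pi * (seq_len(n_ci) - 1) / n_ci
  nodes <- matrix(0, (n_ax - 2) * n_ci + 2, 3)
  nodes[1, ] <- centre + c(0, 0, -r)
  k <- 1L
  for (i in 2:(n_ax - 1))
    for (j in seq_len(n_ci)) {
      k <- k + 1L
      nodes[k, ] <- centre + r * c(sin(xi[i]) * cos(th[j]),
                                   sin(xi[i]) * sin(th[j]), -cos(xi[i]))
    }
  nodes[k + 1L, ] <- centre + c(0, 0, r)
  ring <- function(i) 1L + (i - 1L) * n_ci + seq_len(n_ci)
  tris <- list()
  r1 <- ring(1L)
  for (j in seq_len(n_ci))
    tris[[length(tris) + 1L]] <- c(1L, r1[j %% n_ci + 1L], r1[j])
  for (i in seq_len(n_ax - 3L)) {
    ra <- ring(i); rb <- ring(i + 1L)
    for (j in seq_len(n_ci)) {
      jn <- j %% n_ci + 1L
      tris[[length(tris) + 1L]] <- rbind(c(ra[j], rb[j], rb[jn]),
                                         c(ra[j], rb[jn], ra[jn]))
    }
  }
  hp <- (n_ax - 2L) * n_ci + 2L
  rl <- ring(n_ax - 2L)
  for (j in seq_len(n_ci))
    tris[[length(tris) + 1L]] <- c(hp, rl[j], rl[j %% n_ci + 1L])
  m <- wing_mesh(nodes, do.call(rbind, tris), side = "body")
  if (mesh_volume(m) < 0) m$triangles <- m$triangles[, c(1, 3, 2)]
  m
}

# noiseless default-program kinematics run (the expensive shared fixture)
fixture_kin <- function() {
  if (is.null(.fixture_env$kin)) {
    cfg <- default_calliope_config()
    prog <- default_kinematic_program(cfg, n_cycles = 2L, noise_sd = 0)
    .fixture_env$kin <- run_kinematics_pipeline(
      list(flight = cfg, program = prog, seed = 1L), target_elements = 340L)
  }
  .fixture_env$kin
}

# periodic cube grid for Taylor-Green style tests
tg_grid <- function(n) {
  per <- c(xlo = "periodic", xhi = "periodic", ylo = "periodic",
           yhi = "periodic", zlo = "periodic", zhi = "periodic")
  build_grid(list(c(0, 2 * pi), c(0, 2 * pi), c(0, 2 * pi)),
             h_fine = 2 * pi / n, bc = per)
}

# Taylor-Green initial state (2D pattern, exact Navier-Stokes solution)
tg_state <- function(grid) {
  d <- grid$dims
  u <- array(0, d); v <- array(0, d); w <- array(0, d)
  for (k in seq_len(d[3]))
    for (j in seq_len(d[2])) {
      u[, j, k] <- cos(grid$xf[seq_len(d[1])]) * sin(grid$yc[j])
      v[, j, k] <- -sin(grid$xc) * cos(grid$yf[j])
    }
  flow_state(grid, u0 = u, v0 = v, w0 = w)
}

tg_kinetic_energy <- function(state, grid) {
  cv <- flapwing:::cpp_center_velocity(state$u, state$v, state$w,
                                       flapwing:::grid_cpp(grid))
  mean(cv$u^2 + cv$v^2 + cv$w^2) / 2
}

# all-slip (Neumann-pressure) box grid
neumann_box <- function(n, L = 1) {
  build_grid(list(c(0, L), c(0, L), c(0, L)), h_fine = L / n,
             bc = c(xlo = "slip", xhi = "slip", ylo = "slip",
                    yhi = "slip", zlo = "slip", zhi = "slip"))
}

# evaluate a centre-coordinate function on the grid as a 3D array
grid_eval <- function(grid, f) {
  d <- grid$dims
  X <- array(grid$xc, d)
  Y <- aperm(array(grid$yc, d[c(2, 1, 3)]), c(2, 1, 3))
  Z <- aperm(array(grid$zc, d[c(3, 2, 1)]), c(3, 2, 1))
  f(X, Y, Z)
}

cell_volumes <- function(grid) {
  d <- grid$dims
  array(diff(grid$xf), d) *
    aperm(array(diff(grid$yf), d[c(2, 1, 3)]), c(2, 1, 3)) *
    aperm(array(diff(grid$zf), d[c(3, 2, 1)]), c(3, 2, 1))
}
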