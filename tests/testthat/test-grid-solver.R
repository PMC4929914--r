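cfg <- default_calliope_config()

test_that("grid builder honours fine block, stretching and boundary pairing", {
  g <- build_grid(list(c(0, 1), c(0, 1), c(0, 1)), h_fine = 0.05,
                  bc = c(xlo = "slip", xhi = "slip", ylo = "slip",
                         yhi = "slip", zlo = "slip", zhi = "slip"))
  expect_equal(g$dims, c(20L, 20L, 20L))
  expect_true(all(abs(diff(g$xf) - 0.05) < 1e-12))   # uniform request

  g2 <- build_grid(list(c(-0.1, 0.1), c(-0.1, 0.1), c(-0.1, 0.1)),
                   fine_block = list(c(-0.02, 0.02), c(-0.02, 0.02), c(-0.02, 0.02)),
                   h_fine = 0.002, stretch = 1.08)
  # at least W/h cells inside the fine block
  inside <- g2$xf >= -0.02 - 1e-12 & g2$xf <= 0.02 + 1e-12
  expect_gte(sum(inside) - 1L, 20L)
  # outward expansion bounded by the stretch ratio
  dx <- diff(g2$xf)
  fine_idx <- which(dx < 0.002 * 1.0001)
  right <- dx[max(fine_idx):length(dx)]
  expect_true(all(right[-1] / right[-length(right)] <= 1.08 + 1e-9))

  expect_error(build_grid(list(c(0, 1), c(0, 1), c(0, 1)), h_fine = 0.1,
                          stretch = 1.3), "stretch")
  expect_error(build_grid(list(c(0, 1), c(0, 1), c(0, 1)), h_fine = 0.1,
                          bc = c(xlo = "periodic", xhi = "slip", ylo = "slip",
                                 yhi = "slip", zlo = "slip", zhi = "slip")),
               "pair")
})

test_that("uniform inflow with no bodies stays exactly uniform", {
  g <- build_grid(list(c(0, 0.1), c(0, 0.08), c(0, 0.08)), h_fine = 0.005,
                  Uin = 1.5)
  st <- flow_state(g)
  set <- solver_settings(dt = 1e-3, nu = 1e-5, poisson_tol = 1e-10)
  for (i in 1:5) st <- advance_timestep(st, g, set)
  expect_equal(max(abs(st$u - 1.5)), 0, tolerance = 1e-12)
  expect_equal(max(abs(st$v)), 0, tolerance = 1e-12)
  expect_equal(max(abs(st$w)), 0, tolerance = 1e-12)
  expect_equal(max(abs(st$p)), 0, tolerance = 1e-10)
})

test_that("the time stepper rejects CFL violations", {
  g <- build_grid(list(c(0, 0.1), c(0, 0.1), c(0, 0.1)), h_fine = 0.01, Uin = 1)
  st <- flow_state(g)
  set <- solver_settings(dt = 0.02, nu = 1e-5)   # CFL = 2
  expect_error(advance_timestep(st, g, set), "CFL")
})

test_that("solid classification captures a sphere volume within 5%", {
  sph <- uv_sphere(r = 0.02)
  expect_true(is_watertight(sph))
  g <- build_grid(list(c(-0.05, 0.05), c(-0.05, 0.05), c(-0.05, 0.05)),
                  h_fine = 0.002)
  cl <- classify_cells(g, body = sph)
  vol <- sum((cl$center == 1L) * cell_volumes(g))
  expect_equal(vol, 4 / 3 * pi * 0.02^3, tolerance = 0.05)
  # no bodies: everything fluid, no forcing
  cl0 <- classify_cells(g)
  expect_true(all(cl0$center == 0L))
  expect_length(cl0$forcing$u$idx, 0L)
})

test_that("membrane classification marks cells near the wing with its velocity", {
  kin <- fixture_kin()
  g <- build_grid(list(c(-0.06, 0.06), c(-0.07, 0.07), c(-0.06, 0.06)),
                  h_fine = 0.004)
  wing <- kin$meshes$left
  it <- 12L
  cl <- classify_cells(g, wings = list(wing), it = it)
  expect_gt(length(cl$forcing$u$idx), 50L)
  expect_true(any(cl$center == 2L))
  # forcing targets are bounded by the actual surface speeds
  vmax <- max(abs(kin$meshes$left$node_velocities[, , it]))
  expect_lte(max(abs(cl$forcing$u$val)), vmax + 1e-9)

  # fresh cells: only appear where a solid/interface cell was vacated
  cl2 <- classify_cells(g, wings = list(wing), it = it + 8L, previous = cl)
  expect_true(any(cl2$fresh))
  expect_true(all(cl$center[cl2$fresh] != 0L))
})

test_that("flow past a sphere satisfies no-penetration and momentum balance", {
  sph <- uv_sphere(r = 0.012, n_ax = 30L, n_ci = 36L)
  U <- 1; h <- 0.00125
  g <- build_grid(list(c(-0.04, 0.08), c(-0.04, 0.04), c(-0.04, 0.04)),
                  fine_block = list(c(-0.02, 0.025), c(-0.02, 0.02), c(-0.02, 0.02)),
                  h_fine = h, stretch = 1.1, Uin = U)
  nu <- U * 2 * 0.012 / 50                 # Reynolds number 50 on the diameter
  cl <- classify_cells(g, body = sph)
  st <- flow_state(g)
  set <- solver_settings(dt = h / (5 * U), nu = nu, poisson_tol = 1e-6)
  vols <- cell_volumes(g)
  mom_x <- function(s) {
    cv <- flapwing:::cpp_center_velocity(s$u, s$v, s$w, flapwing:::grid_cpp(g))
    sum(array(cv$u, g$dims) * vols)
  }
  for (i in 1:190) st <- advance_timestep(st, g, set, ib = cl)
  m1 <- mom_x(st)
  for (i in 1:10) st <- advance_timestep(st, g, set, ib = cl)
  m2 <- mom_x(st)

  # divergence-free after projection
  dv <- divergence(st, g)
  expect_lt(max(abs(dv)) * set$dt, 1e-3)

  # no-penetration: sampled fluid velocity at the surface has a small
  # normal component relative to the freestream
  nrm <- flapwing:::triangle_normals(sph)
  vel <- interp_velocity(st, g, flapwing:::triangle_centroids(sph))
  vn <- abs(rowSums(vel * nrm))
  expect_lt(mean(vn), 0.02 * U)

  # control-volume momentum balance on the whole box:
  # Drag = -dMx/dt - (outflow - inflow) momentum flux - (p_out - p_in) area
  # force (lateral slip faces carry neither x-momentum flux nor x-pressure)
  d <- g$dims
  dA <- outer(diff(g$yf), diff(g$zf))
  u_in <- st$u[1, , ]; u_out <- st$u[d[1] + 1, , ]
  p_in <- st$p[1, , ]; p_out <- st$p[d[1], , ]
  drag_cv <- -(m2 - m1) / (10 * set$dt) -
    (sum(u_out^2 * dA) - sum(u_in^2 * dA)) -
    (sum(p_out * dA) - sum(p_in * dA))
  tr <- surface_traction(st, g, sph, rho = 1, nu = nu, closed = TRUE)
  drag_surface <- integrate_forces(tr$traction, tr$areas)[["F_X"]]
  expect_gt(drag_surface, 0)
  expect_lt(abs(drag_surface - drag_cv) / abs(drag_cv), 0.15)
})

test_that("interpolators reproduce linear fields", {
  g <- build_grid(list(c(0, 0.1), c(0, 0.1), c(0, 0.1)), h_fine = 0.01, Uin = 0)
  st <- flow_state(g)
  # p = 2 x - y + 3 z is reproduced exactly by trilinear interpolation
  st$p <- grid_eval(g, function(x, y, z) 2 * x - y + 3 * z)
  set.seed(4)
  pts <- cbind(runif(50, 0.02, 0.08), runif(50, 0.02, 0.08), runif(50, 0.02, 0.08))
  got <- flapwing:::cpp_interp_center(as.vector(st$p), flapwing:::grid_cpp(g), pts)
  expect_equal(got, 2 * pts[, 1] - pts[, 2] + 3 * pts[, 3], tolerance = 1e-10)
})
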