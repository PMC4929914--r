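test_that("swirling strength matches hand-built spectra", {
  # solid-body rotation about Z at 2 rad/s: eigenvalues 0, +-2i
  rot <- matrix(c(0, 2, 0, -2, 0, 0, 0, 0, 0), 3, 3)
  expect_equal(swirling_strength(rot), 2, tolerance = 1e-12)
  # pure strain: real spectrum
  expect_equal(swirling_strength(diag(c(1, -1, 0))), 0)
  # symmetric tensors always have real spectra
  set.seed(5)
  for (i in 1:20) {
    s <- matrix(rnorm(9), 3, 3); s <- s + t(s)
    expect_equal(swirling_strength(s), 0)
  }
  expect_error(swirling_strength(matrix(c(NA, rep(0, 8)), 3, 3)), "finite")
})

test_that("swirling strength agrees with an eigenvalue oracle and is rotation-invariant", {
  set.seed(6)
  tensors <- matrix(rnorm(300 * 9, sd = 3), 300, 9)
  got <- swirling_strength(tensors)
  oracle <- vapply(seq_len(nrow(tensors)), function(i) {
    ev <- eigen(matrix(tensors[i, ], 3, 3), only.values = TRUE)$values
    max(abs(Im(ev)))
  }, 0)
  expect_lt(max(abs(got - oracle)), 1e-8 * max(1, max(oracle)))

  # invariance under random rotations of the frame
  rand_rot <- function() qr.Q(qr(matrix(rnorm(9), 3, 3)))
  for (i in 1:10) {
    A <- matrix(rnorm(9, sd = 2), 3, 3)
    Q <- rand_rot()
    expect_equal(swirling_strength(Q %*% A %*% t(Q)), swirling_strength(A),
                 tolerance = 1e-8)
  }
})

test_that("swirl field vanishes in uniform flow and peaks on a vortex axis", {
  g <- build_grid(list(c(-0.05, 0.05), c(-0.05, 0.05), c(-0.05, 0.05)),
                  h_fine = 0.004, Uin = 2)
  st <- flow_state(g)                      # uniform stream
  lam <- swirl_field(st, g)
  expect_equal(max(abs(lam)), 0, tolerance = 1e-10)

  # Lamb-Oseen vortex along z: lambda_ci maximal at the axis, decaying out
  gamma <- 0.02; rc <- 0.012
  vth <- function(r) gamma / (2 * pi * pmax(r, 1e-9)) * (1 - exp(-r^2 / rc^2))
  d <- g$dims
  u <- array(0, flapwing:::stag_dims(g, 1))
  v <- array(0, flapwing:::stag_dims(g, 2))
  for (k in seq_len(d[3]))
    for (j in seq_len(d[2])) {
      r <- sqrt(g$xf[seq_len(d[1] + 1)]^2 + g$yc[j]^2)
      u[, j, k] <- (-g$yc[j] / r * vth(r))[seq_len(dim(u)[1])]
    }
  for (k in seq_len(d[3]))
    for (j in seq_len(d[2] + 1)) {
      if (j > dim(v)[2]) next
      r <- sqrt(g$xc^2 + g$yf[j]^2)
      v[, j, k] <- g$xc / r * vth(r)
    }
  stv <- flow_state(g, u0 = u, v0 = v, w0 = array(0, flapwing:::stag_dims(g, 3)))
  lamv <- swirl_field(stv, g)
  mid <- ceiling(d / 2)
  core <- lamv[mid[1], mid[2], mid[3]]
  edge <- lamv[2, 2, mid[3]]
  expect_gt(core, 0)
  expect_lt(edge, 0.1 * core)
  # axial symmetry of the core slice
  expect_equal(lamv[mid[1] + 3, mid[2], mid[3]], lamv[mid[1] - 3, mid[2], mid[3]],
               tolerance = 0.05 * core)
})

test_that("pressure slices interpolate exactly for linear fields", {
  g <- build_grid(list(c(0, 0.1), c(0, 0.08), c(0, 0.06)), h_fine = 0.005)
  st <- flow_state(g)
  st$p <- grid_eval(g, function(x, y, z) x)      # p = x
  sl <- pressure_slice(st, g, axis = "y", value = 0.033)
  expect_equal(as.vector(sl$p), rep(g$xc, times = g$dims[3]), tolerance = 1e-12)

  st$p <- array(4.2, g$dims)
  sl2 <- pressure_slice(st, g, axis = "z", value = 0.02)
  expect_true(all(abs(sl2$p - 4.2) < 1e-12))

  expect_error(pressure_slice(st, g, axis = "x", value = 0.2), "outside")
})

test_that("velocity-gradient trace respects incompressibility after projection", {
  g <- tg_grid(24L)
  st <- tg_state(g)
  set <- solver_settings(dt = 0.02, nu = 0.05, poisson_tol = 1e-8)
  for (i in 1:5) st <- advance_timestep(st, g, set)
  vg <- velocity_gradient(st, g)
  tr <- vg$grad[, 1] + vg$grad[, 5] + vg$grad[, 9]
  scale <- max(abs(vg$grad))
  expect_lt(max(abs(tr)), 0.02 * scale)
})

test_that("VTK export writes a parseable rectilinear file", {
  g <- build_grid(list(c(0, 0.02), c(0, 0.02), c(0, 0.02)), h_fine = 0.005)
  st <- flow_state(g)
  st$p <- grid_eval(g, function(x, y, z) x + y)
  path <- tempfile(fileext = ".vtk")
  write_vtk(path, g, scalars = list(p = st$p))
  lines <- readLines(path)
  expect_true(any(grepl("DATASET RECTILINEAR_GRID", lines)))
  expect_true(any(grepl("SCALARS p double", lines)))
  dims <- as.integer(strsplit(grep("DIMENSIONS", lines, value = TRUE), " ")[[1]][-1])
  expect_equal(dims, g$dims)
})
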