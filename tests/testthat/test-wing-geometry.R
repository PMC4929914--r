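cfg <- default_calliope_config()

# markers of one noiseless frame of the default program
frame_markers <- function(phase = 0.1) {
  st <- flapwing:::marker_stations()
  prog <- default_kinematic_program(cfg, noise_sd = 0)
  pts <- flapwing:::wing_boundary_points(st$t_deg, phase, cfg, prog)
  rownames(pts) <- st$marker_id
  pts
}

test_that("outline interpolates every marker and tracks an analytic ellipse", {
  # markers on a plane ellipse at the anatomical stations
  st <- flapwing:::marker_stations()
  t <- deg2rad_(st$t_deg)
  Ra <- 0.02; Rb <- 0.008
  pts <- cbind(Ra * cos(t), -Rb * sin(t), 0 * t)
  rownames(pts) <- st$marker_id
  ol <- reconstruct_outline(pts)

  # passes through the input markers
  hits <- ol$point(ol$s_markers)
  expect_lt(max(abs(hits - pts[names(ol$s_markers), ])), 1e-12)

  # dense outline samples lie within 1% of the ellipse size (major diameter)
  dense <- ol$point(seq(0, 1, length.out = 400)[-400])
  tt <- seq(0, 2 * pi, length.out = 4000)
  ell <- cbind(Ra * cos(tt), -Rb * sin(tt))
  dmin <- apply(dense, 1, function(p)
    min(sqrt((ell[, 1] - p[1])^2 + (ell[, 2] - p[2])^2 + p[3]^2)))
  expect_lt(max(dmin), 0.01 * 2 * Ra)
})

test_that("degenerate marker sets are rejected", {
  st <- flapwing:::marker_stations()
  collinear <- cbind(seq_len(9), 2 * seq_len(9), 0 * seq_len(9))
  rownames(collinear) <- st$marker_id
  expect_error(reconstruct_outline(collinear), "collinear")

  pts <- frame_markers()
  dup <- pts; dup["LE2", ] <- dup["LE1", ]
  expect_error(reconstruct_outline(dup), "degenerate")

  expect_error(reconstruct_outline(pts[1:8, ]), "9 markers")
})

test_that("triangulation meets element-count and area targets", {
  ol <- reconstruct_outline(frame_markers(0.1))
  mesh <- triangulate_wing(ol, 1335L)
  expect_lt(abs(nrow(mesh$triangles) - 1335) / 1335, 0.15)
  expect_lt(abs(nrow(mesh$nodes) - 718) / 718, 0.15)

  prog <- default_kinematic_program(cfg, noise_sd = 0)
  target_area <- cfg$S_ref * prog$area_fun(0.1)
  expect_lt(abs(mesh_area(mesh) - target_area) / target_area, 0.05)
  expect_gt(mesh_area(mesh), 4e-4)   # hummingbird scale: 4 to 7 cm^2
  expect_lt(mesh_area(mesh), 7e-4)

  # triangle normals are consistently oriented (no flipped elements)
  nrm <- flapwing:::triangle_normals(mesh)
  mean_nrm <- colMeans(nrm)
  align <- nrm %*% (mean_nrm / sqrt(sum(mean_nrm^2)))
  expect_gt(min(align), 0)
})

test_that("triangulating a square outline reproduces its area", {
  # synthetic outline: unit square boundary with anatomical anchors
  sq <- function(s) {
    s <- s %% 1
    t(vapply(s, function(si) {
      p <- si * 4
      if (p < 1) c(p, 0, 0)
      else if (p < 2) c(1, p - 1, 0)
      else if (p < 3) c(3 - p, 1, 0)
      else c(0, 4 - p, 0)
    }, numeric(3)))
  }
  ol <- structure(list(
    point = sq,
    s_markers = c(LE1 = 0, LE2 = 0.05, LE3 = 0.1, LE4 = 0.15, LE5 = 0.2,
                  TIP = 0.25, TE3 = 0.5, TE2 = 0.625, TE1 = 0.75),
    markers = {
      m <- sq(c(0, 0.05, 0.1, 0.15, 0.2, 0.25, 0.5, 0.625, 0.75))
      rownames(m) <- c("LE1", "LE2", "LE3", "LE4", "LE5", "TIP", "TE3", "TE2", "TE1")
      m
    },
    length = 4), class = "wing_outline")
  mesh <- triangulate_wing(ol, 400L)
  expect_equal(mesh_area(mesh), 1, tolerance = 0.01)
})

test_that("reconstructed area follows the generator's area modulation", {
  kin <- fixture_kin()
  prog <- kin$markers$program
  phases <- (kin$series$time_s * cfg$f_beat) %% 1
  expected <- cfg$S_ref * prog$area_fun(phases)
  expect_lt(max(abs(kin$series$area - expected) / expected), 0.05)
})

test_that("temporal refinement reproduces analytic node motion and velocities", {
  # nodes moving as sin(2 pi f t), 22 samples/cycle, refine x10
  f <- 45.5
  n_nodes <- 5L; nfpc <- 22L
  t_in <- (seq_len(nfpc) - 1) / (nfpc * f)
  amp <- (1:n_nodes) * 1e-3
  nodes <- array(0, c(n_nodes, 3, nfpc))
  for (it in seq_len(nfpc))
    nodes[, 1, it] <- amp * sin(2 * pi * f * t_in[it])
  mesh <- wing_mesh(nodes, cbind(1:3, 2:4, 3:5), times = t_in)
  ref <- refine_in_time(mesh, nfpc, 10L)

  exact <- outer(amp, sin(2 * pi * f * ref$times))
  expect_lt(max(abs(ref$nodes[, 1, ] - exact)), 1e-4 * max(amp))

  vex <- outer(amp * 2 * pi * f, cos(2 * pi * f * ref$times))
  expect_lt(max(abs(ref$node_velocities[, 1, ] - vex)) / max(abs(vex)), 2e-3)

  # velocities agree with centred differences of refined positions to O(dt^2)
  dtr <- ref$times[2] - ref$times[1]
  n_t <- length(ref$times)
  fd <- (ref$nodes[, 1, 3:n_t] - ref$nodes[, 1, 1:(n_t - 2)]) / (2 * dtr)
  expect_lt(max(abs(ref$node_velocities[, 1, 2:(n_t - 1)] - fd)) / max(abs(vex)),
            (2 * pi * f * dtr)^2)

  # refinement_factor = 1 keeps positions unchanged
  id <- refine_in_time(mesh, nfpc, 1L)
  expect_equal(id$nodes, mesh$nodes, tolerance = 1e-12)
})

test_that("phase averaging recovers identical cycles and damps noise", {
  f <- 45.5
  t <- (0:219) / (22 * f)
  base <- sin(2 * pi * f * t)
  # identical cycles: the average IS one cycle
  pa <- phase_average(base, t, f, n_bins = 22L)
  expect_equal(pa$mean, base[1:22], tolerance = 1e-12)

  # constant series stays constant
  pc <- phase_average(rep(3.5, length(t)), t, f, n_bins = 10L)
  expect_true(all(abs(pc$mean - 3.5) < 1e-12))

  # sinusoid + noise over 10 cycles: amplitude recovered within the
  # standard-error bound 3 sd / sqrt(n_cycles)
  set.seed(11)
  noise_sd <- 0.2
  noisy <- base + rnorm(length(t), 0, noise_sd)
  pn <- phase_average(noisy, t, f, n_bins = 22L)
  expect_lt(max(abs(pn$mean - base[1:22])), 3 * noise_sd / sqrt(10))

  # fewer than two cycles is an error
  expect_error(phase_average(base[1:30], t[1:30], f), "2 complete cycles")

  # linearity: commutes with linear maps
  pl <- phase_average(2 * noisy + 1, t, f, n_bins = 22L)
  expect_equal(pl$mean, 2 * pn$mean + 1, tolerance = 1e-12)
})

test_that("body surface is watertight, oriented and pitched at chi_b", {
  body <- build_body(cfg)
  expect_true(is_watertight(body))
  expect_gt(mesh_volume(body), 0)

  # principal axis of the node cloud pitches nose-up at the body angle
  nd <- body$nodes
  pc <- prcomp(nd)
  ax <- pc$rotation[, 1]
  if (ax[1] > 0) ax <- -ax          # point towards the head (upstream)
  pitch <- atan2(ax[3], -ax[1]) * 180 / pi
  expect_equal(pitch, cfg$chi_b, tolerance = 0.5)

  # scale matches the reported body mesh
  expect_equal(nrow(body$triangles), 3560, tolerance = 0.05)
  expect_equal(nrow(body$nodes), 1782, tolerance = 0.05)
})

test_that("mesh I/O round-trips through OBJ and PLY", {
  body <- build_body(cfg, n_axial = 10L, n_circ = 12L)
  for (fmt in c("obj", "ply")) {
    path <- tempfile(fileext = paste0(".", fmt))
    if (fmt == "obj") write_obj(body, path) else write_ply(body, path)
    back <- if (fmt == "obj") read_obj(path) else read_ply(path)
    expect_equal(back$nodes, unname(body$nodes), tolerance = 1e-9)
    expect_equal(back$triangles, body$triangles)
  }
})
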