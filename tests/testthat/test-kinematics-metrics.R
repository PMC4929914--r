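cfg <- default_calliope_config()

# rectangular planform membrane mesh: span along +Y from the shoulder,
# chord along +X, optional uniform pitch psi (deg); the outermost node row
# collapses to the spanwise axis so the wingtip sits on it exactly
rect_wing <- function(span = 0.04, chord = 0.01, psi = 0, n_s = 20L, n_c = 6L,
                      shoulder = c(0, 0.006, 0)) {
  cd <- flapwing:::chord_dir(psi)
  u <- seq(0, 1, length.out = n_s + 1)
  v <- seq(0, 1, length.out = n_c + 1)
  nodes <- matrix(0, (n_s + 1) * (n_c + 1), 3)
  k <- 0L
  for (i in seq_along(u))
    for (j in seq_along(v)) {
      k <- k + 1L
      fac <- if (i == n_s + 1L) 0 else 1
      nodes[k, ] <- shoulder + u[i] * span * c(0, 1, 0) +
        fac * (v[j] - 0.25) * chord * cd
    }
  nid <- function(i, j) (i - 1L) * (n_c + 1L) + j
  tris <- list()
  for (i in seq_len(n_s))
    for (j in seq_len(n_c))
      tris[[length(tris) + 1L]] <- rbind(
        c(nid(i, j), nid(i, j + 1), nid(i + 1, j)),
        c(nid(i, j + 1), nid(i + 1, j + 1), nid(i + 1, j)))
  wing_mesh(nodes, do.call(rbind, tris), side = "left")
}

test_that("chord extraction recovers planform chords", {
  m <- rect_wing(chord = 0.012)
  sec <- extract_chord(m, 0.5)
  expect_equal(sqrt(sum((sec$te_point - sec$le_point)^2)), 0.012,
               tolerance = 1e-9)
  expect_error(extract_chord(m, 1.05), "outside")

  # elliptic planform: chord at r_hat = 0.9 follows the ellipse
  # (checked at mid-downstroke, where the spanwise axis is exactly lateral)
  kin <- fixture_kin()
  it_mid <- which.min(abs((kin$meshes$left$times * cfg$f_beat) %% 1 - 0.25))
  sec_d <- extract_chord(kin$meshes$left, 0.9, it = it_mid)
  prog <- kin$markers$program
  xi <- (0.9 - 0.55) / 0.45
  expected <- 2 * prog$area_fun(0.25) * cfg$S_ref / (pi * 0.45 * cfg$R) *
    sqrt(1 - xi^2)
  got <- sqrt(sum((sec_d$te_point - sec_d$le_point)^2))
  expect_equal(got, expected, tolerance = 0.02)
})

test_that("chord angle sign convention and recovery of prescribed pitching", {
  mk <- function(psi) chord_section(0.5, c(0, 0, 0), 0.01 * flapwing:::chord_dir(psi))
  expect_equal(chord_angle(mk(0), cfg), 0, tolerance = 1e-10)
  expect_equal(chord_angle(mk(45), cfg), 45, tolerance = 1e-10)
  expect_equal(chord_angle(mk(-30), cfg), -30, tolerance = 1e-10)
  expect_error(chord_angle(chord_section(0.5, c(0, 0, 0), c(0, 0.01, 0)), cfg),
               "zero length")

  # generator with prescribed uniform pitching psi(t) = 30 sin(2 pi phase):
  # the reconstructed chord angle matches the program to well under 0.5 deg
  prog <- kinematic_program(
    stroke_fun = function(ph) (cfg$Phi / 2) * cos(2 * pi * ph),
    twist_fun = function(ph, r_hat) 30 * sin(2 * pi * ph) + 0 * r_hat,
    n_frames_per_cycle = 22L, n_cycles = 1L, noise_sd = 0)
  ms <- generate_markers(cfg, prog, seed = 1)
  mesh <- refine_in_time(reconstruct_wing_series(ms, "left", 340L), 22L, 2L)
  ks <- kinematics_series(mesh, cfg)
  ph <- (ks$time_s * cfg$f_beat) %% 1
  expect_lt(max(abs(ks$psi_p - 30 * sin(2 * pi * ph))), 0.5)
  expect_lt(max(abs(ks$psi_d - 30 * sin(2 * pi * ph))), 0.5)
})

test_that("effective angle of attack combines freestream and section motion", {
  sec <- function(psi, vel) chord_section(0.5, c(0, 0, 0),
                                          0.01 * flapwing:::chord_dir(psi), vel)
  # static chord: alpha equals psi
  expect_equal(effective_aoa(sec(20, c(0, 0, 0)), cfg), 20, tolerance = 1e-10)
  # chord at psi = 0 translating straight down at U: alpha = +45
  expect_equal(effective_aoa(sec(0, c(0, 0, -cfg$U)), cfg), 45, tolerance = 1e-10)
  # chord at psi = +20 translating straight up at U: alpha = 20 - 45 = -25
  expect_equal(effective_aoa(sec(20, c(0, 0, cfg$U)), cfg), -25, tolerance = 1e-10)
  # vanishing relative flow is undefined
  expect_error(effective_aoa(sec(10, c(cfg$U, 0, 0)), cfg), "undefined")
})

test_that("alpha equals psi identically when the wing is motionless", {
  kin <- fixture_kin()
  mesh <- kin$meshes$left
  mesh$node_velocities <- array(0, dim(mesh$node_velocities))
  ks <- kinematics_series(mesh, cfg)
  expect_lt(max(abs(ks$alpha_p - ks$psi_p)), 1e-9)
  expect_lt(max(abs(ks$alpha_d - ks$psi_d)), 1e-9)
})

test_that("kinematic series has the reported qualitative structure", {
  kin <- fixture_kin()
  ks <- kin$series
  stroke <- stroke_segmentation(ks, cfg)
  # proximal chord angle and AoA positive throughout
  expect_true(all(ks$psi_p > 0))
  expect_true(all(ks$alpha_p > 0))
  # distal chord angle negative around mid-downstroke, positive at mid-upstroke
  ph <- (ks$time_s * cfg$f_beat) %% 1
  expect_lt(min(ks$psi_d[abs(ph - 0.25) < 0.1]), 0)
  expect_gt(max(ks$psi_d[abs(ph - 0.75) < 0.1]), 0)
  # distal AoA negative during fast upstroke
  expect_lt(min(ks$alpha_d[abs(ph - 0.75) < 0.1]), 0)
  # twist extremes at mid-downstroke / mid-upstroke
  expect_equal(ph[which.min(ks$twist)] %% 1, 0.25, tolerance = 0.08)
  expect_equal(ph[which.max(ks$twist)] %% 1, 0.75, tolerance = 0.08)
  # twist is identically psi_d - psi_p
  expect_equal(ks$twist, ks$psi_d - ks$psi_p, tolerance = 1e-12)
  # angles bounded and continuous (no 360-degree jumps)
  for (col in c("psi_p", "psi_d", "alpha_p", "alpha_d")) {
    expect_true(all(ks[[col]] > -180 & ks[[col]] <= 180))
    expect_lt(max(abs(diff(ks[[col]]))), 90)
  }
})

test_that("cycle summaries give the advance ratio and stroke-resolved areas", {
  kin <- fixture_kin()
  cs <- cycle_summaries(kin$series, cfg)
  expect_equal(cs$J, cfg$U / cs$U_tip, tolerance = 1e-12)

  # pure-sinusoid program: U_tip = 2 f Phi R, J = 1.13
  prog <- kinematic_program(
    stroke_fun = function(ph) (cfg$Phi / 2) * cos(2 * pi * ph),
    n_frames_per_cycle = 44L, n_cycles = 1L, noise_sd = 0)
  ms <- generate_markers(cfg, prog, seed = 1)
  mesh <- refine_in_time(reconstruct_wing_series(ms, "left", 340L), 44L, 4L)
  css <- cycle_summaries(kinematics_series(mesh, cfg), cfg)
  expect_equal(css$U_tip, 2 * cfg$f_beat * deg2rad_(cfg$Phi) * cfg$R,
               tolerance = 0.01 * 7.34)
  expect_equal(css$J, 1.13, tolerance = 0.015)

  # stroke-conditional areas reproduce the measured down/up asymmetry
  expect_equal(cs$S_down * 1e4, 5.34, tolerance = 0.05)
  expect_equal(cs$S_up * 1e4, 5.03, tolerance = 0.05)
  expect_equal(cs$S_mean * 1e4, 5.18, tolerance = 0.05)

  expect_error(cycle_summaries(kin$series[0, ], cfg), "empty")
})
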