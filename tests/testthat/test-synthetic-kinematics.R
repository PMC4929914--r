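cfg <- default_calliope_config()

sin_program <- function(n_frames = 128L, n_cycles = 2L, noise_sd = 0) {
  kinematic_program(
    stroke_fun = function(ph) (cfg$Phi / 2) * cos(2 * pi * ph),
    n_frames_per_cycle = n_frames, n_cycles = n_cycles, noise_sd = noise_sd)
}

test_that("program validation rejects non-periodic waveforms and bad area scales", {
  expect_error(kinematic_program(stroke_fun = function(ph) ph), "periodic")
  expect_error(kinematic_program(stroke_fun = function(ph) cos(2 * pi * ph),
                                 area_fun = function(ph) 1.1 + 0 * ph),
               "mean 1")
  expect_error(kinematic_program(stroke_fun = function(ph) cos(2 * pi * ph),
                                 n_frames_per_cycle = 5L), "10 frames")
})

test_that("sinusoidal stroke reproduces closed-form tip speeds", {
  ms <- generate_markers(cfg, sin_program(n_frames = 128L, n_cycles = 1L), seed = 1)
  tip <- t(ms$markers$left["TIP", , ])
  # periodic centred differences of tip position (body-relative speed)
  n <- nrow(tip)
  dt <- ms$times[2] - ms$times[1]
  ip <- c(2:n, 1); im <- c(n, 1:(n - 1))
  vel <- (tip[ip, ] - tip[im, ]) / (2 * dt)
  speed <- sqrt(rowSums(vel^2))
  peak_exact <- pi * cfg$f_beat * deg2rad_(cfg$Phi) * cfg$R
  mean_exact <- 2 * cfg$f_beat * deg2rad_(cfg$Phi) * cfg$R
  expect_equal(peak_exact, 11.53, tolerance = 1e-3)
  expect_equal(mean_exact, 7.34, tolerance = 1e-3)
  expect_lt(abs(max(speed) - peak_exact) / peak_exact, 1e-3)
  expect_lt(abs(mean(speed) - mean_exact) / mean_exact, 5e-3)
})

test_that("left and right wings are mirror images through the sagittal plane", {
  prog <- default_kinematic_program(cfg, n_cycles = 1L, noise_sd = 0)
  ms <- generate_markers(cfg, prog, seed = 1)
  mirrored <- ms$markers$right
  mirrored[, 2, ] <- -mirrored[, 2, ]
  expect_equal(ms$markers$left, mirrored, tolerance = 1e-14)
})

test_that("noiseless generation is deterministic; noise follows the seed", {
  prog0 <- default_kinematic_program(cfg, n_cycles = 1L, noise_sd = 0)
  a <- generate_markers(cfg, prog0, seed = 1)
  b <- generate_markers(cfg, prog0, seed = 999)
  expect_identical(a$markers, b$markers)

  progn <- default_kinematic_program(cfg, n_cycles = 1L, noise_sd = 2e-4)
  n1 <- generate_markers(cfg, progn, seed = 7)
  n2 <- generate_markers(cfg, progn, seed = 7)
  n3 <- generate_markers(cfg, progn, seed = 8)
  expect_identical(n1$markers, n2$markers)
  expect_false(identical(n1$markers, n3$markers))
  # noise magnitude is as configured
  expect_equal(sd(n1$markers$left - a$markers$left), 2e-4, tolerance = 0.1)
})

test_that("wingtip stays within the wing length of the shoulder", {
  prog <- default_kinematic_program(cfg, n_cycles = 2L, noise_sd = 0)
  ms <- generate_markers(cfg, prog, seed = 1)
  d <- sqrt(colSums((ms$markers$left["TIP", , ] - c(0, 0.006, 0))^2))
  expect_true(all(d <= cfg$R * (1 + 1e-9)))
})

test_that("mean planform area equals S_ref for any valid area modulation", {
  progs <- list(
    default_kinematic_program(cfg, n_cycles = 1L, noise_sd = 0),
    kinematic_program(stroke_fun = function(ph) (cfg$Phi / 2) * cos(2 * pi * ph),
                      area_fun = function(ph) 1 + 0.08 * sin(2 * pi * ph + 1),
                      n_frames_per_cycle = 64L, n_cycles = 1L))
  for (prog in progs) {
    ph <- (seq_len(64) - 1) / 64
    # generator planform area: analytic ellipse area times the modulation
    areas <- vapply(ph, function(p) {
      pts <- flapwing:::wing_boundary_points(seq(0, 359, by = 1.5), p, cfg, prog)
      # planar polygon area via the cross-product sum in 3D
      ctr <- colMeans(pts)
      s <- c(0, 0, 0)
      n <- nrow(pts)
      for (i in seq_len(n)) {
        a <- pts[i, ] - ctr; b <- pts[i %% n + 1, ] - ctr
        s <- s + c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
                   a[1] * b[2] - a[2] * b[1])
      }
      sqrt(sum(s^2)) / 2
    }, 0)
    expect_equal(mean(areas), cfg$S_ref, tolerance = 0.01)
  }
})

test_that("marker tables round-trip losslessly through CSV", {
  prog <- default_kinematic_program(cfg, n_cycles = 1L, noise_sd = 1e-4)
  ms <- generate_markers(cfg, prog, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_markers(ms, path)
  back <- read_markers(path)
  expect_equal(back$times, ms$times, tolerance = 1e-12)
  expect_lt(max(abs(back$markers$left - ms$markers$left)), 1e-12)
  expect_lt(max(abs(back$markers$right - ms$markers$right)), 1e-12)
})

test_that("marker parsing rejects malformed input with line information", {
  prog <- default_kinematic_program(cfg, n_cycles = 1L, noise_sd = 0)
  ms <- generate_markers(cfg, prog, seed = 1)
  path <- tempfile(fileext = ".csv")
  write_markers(ms, path)

  # drop one marker row -> frame with 8 markers
  lines <- readLines(path)
  writeLines(lines[-3], path)
  expect_error(read_markers(path), "expected 9")

  # malformed row
  writeLines(c(lines[1], "oops", lines[-1]), path)
  expect_error(read_markers(path), "line 2")

  # empty file
  writeLines(character(0), path)
  expect_error(read_markers(path), "empty")
})
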