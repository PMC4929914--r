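cfg <- default_calliope_config()

test_that("force integration matches a brute-force oracle", {
  set.seed(8)
  m <- 57L
  tr <- matrix(rnorm(m * 3), m, 3)
  ar <- runif(m, 1e-6, 5e-6)
  # independent per-triangle accumulation
  oracle <- c(0, 0, 0)
  for (i in seq_len(m)) oracle <- oracle + tr[i, ] * ar[i]
  got <- integrate_forces(tr, ar)
  expect_equal(unname(got[1:3]), oracle, tolerance = 1e-14)
  expect_equal(unname(got[["F_T"]]), -oracle[1], tolerance = 1e-14)

  # uniform traction on area A gives t0 * A; zero traction gives zero
  t0 <- c(1.5, -2, 0.5)
  unif <- matrix(rep(t0, each = m), m, 3)
  expect_equal(unname(integrate_forces(unif, ar)[1:3]), t0 * sum(ar),
               tolerance = 1e-12)
  expect_equal(unname(integrate_forces(0 * unif, ar)[1:3]), c(0, 0, 0))
  expect_error(integrate_forces(tr, ar[-1]), "differ")
})

test_that("coefficient normalisation is dimensionally consistent", {
  F <- c(0.013, -0.002, 0.021)
  C <- force_coefficient(F, cfg)
  expect_equal(C * 0.5 * cfg$rho * cfg$U^2 * cfg$S_ref, F, tolerance = 1e-14)
})

test_that("power coefficient follows the defining surface integral", {
  m <- 31L
  ar <- rep(2e-6, m)
  # motionless wing: zero power
  expect_equal(power_coefficient(matrix(1, m, 3), matrix(0, m, 3), ar, cfg), 0)
  # rigid translation: numerator reduces to F . u0
  set.seed(9)
  stress <- matrix(rnorm(m * 3), m, 3)
  u0 <- c(1.2, -0.4, 2)
  vel <- matrix(rep(u0, each = m), m, 3)
  Fnet <- colSums(stress * ar)
  got <- power_coefficient(stress, vel, ar, cfg)
  expect_equal(got, sum(Fnet * u0) / (0.5 * cfg$rho * cfg$U^3 * cfg$S_ref),
               tolerance = 1e-12)
})

test_that("stroke averages and ratios behave on symmetric synthetic series", {
  t <- seq(0, 1, length.out = 200)
  df <- force_series(data.frame(
    time_s = t, phase = t %% 1,
    stroke = ifelse(t %% 1 < 0.5, "down", "up"),
    C_Z = rep(c(0.4, 0.4), each = 100),
    C_T = rep(0.1, 200)))
  av <- stroke_averages(df)
  expect_equal(av["down_up_ratio", "C_Z"], 1, tolerance = 1e-12)
  expect_equal(av["down_up_ratio", "C_T"], 1, tolerance = 1e-12)
  expect_equal(av["whole_cycle", "C_Z"], 0.4, tolerance = 1e-12)
  expect_error(stroke_averages(data.frame(C_Z = 1)), "stroke")
})

test_that("reference coefficients reproduce the published derived quantities", {
  ref <- calliope_reference_coefficients()
  # whole-cycle row is the mean of the two half-strokes for every column,
  # to the 3-decimal precision the coefficients are printed with
  for (col in names(ref))
    expect_equal(ref["whole_cycle", col],
                 mean(c(ref["downstroke", col], ref["upstroke", col])),
                 tolerance = 0.007)

  # down-/upstroke ratios as printed
  expect_equal(ref["downstroke", "C_T"] / ref["upstroke", "C_T"], 2.15,
               tolerance = 0.005)
  expect_equal(ref["downstroke", "C_P"] / ref["upstroke", "C_P"], 2.88,
               tolerance = 0.005)
  expect_equal(ref["downstroke", "C_Z_b"] / ref["upstroke", "C_Z_b"], 1.81,
               tolerance = 0.005)
  expect_equal(ref["downstroke", "C_D_b"] / ref["upstroke", "C_D_b"], 1.08,
               tolerance = 0.005)

  perf <- performance_summary(C_Z = ref["whole_cycle", "C_Z"],
                              C_T = ref["whole_cycle", "C_T"],
                              C_P = ref["whole_cycle", "C_P"],
                              C_Z_b = ref["whole_cycle", "C_Z_b"],
                              C_D_b = ref["whole_cycle", "C_D_b"], cfg)
  expect_equal(perf$P * 1e3, 94.5, tolerance = 0.1)          # mW
  expect_equal(perf$P_massspec, 34, tolerance = 0.25)        # W/kg
  expect_equal(perf$weight_support_frac, 0.94, tolerance = 0.01)
  expect_equal(perf$thrust_to_body_drag, 1.52, tolerance = 0.01)
  expect_equal(perf$body_share, 0.222, tolerance = 0.001)

  # zero input gives zero output
  z <- performance_summary(0, 0, 0, 0, 0, cfg)
  expect_equal(unlist(z[c("P", "P_massspec", "weight_support_frac",
                          "thrust_to_body_drag", "body_share")]),
               c(P = 0, P_massspec = 0, weight_support_frac = 0,
                 thrust_to_body_drag = 0, body_share = 0))
  cfg_bad <- cfg; cfg_bad$M <- -1
  expect_error(performance_summary(1, 1, 1, 1, 1, cfg_bad), "positive")
})

test_that("grid-convergence reference stays below the 5% acceptance bound", {
  gc <- grid_convergence_reference()
  expect_equal(unname(gc$percent_diff[["C_Z"]]), 1.84, tolerance = 0.005)
  expect_equal(unname(gc$percent_diff[["C_T"]]), 4.27, tolerance = 0.005)
  expect_lt(gc$max_percent_diff, 5)
})

test_that("traction on a uniform-pressure field integrates to zero on a closed body", {
  sph <- uv_sphere(r = 0.015, n_ax = 24L, n_ci = 28L)
  g <- build_grid(list(c(-0.04, 0.04), c(-0.04, 0.04), c(-0.04, 0.04)),
                  h_fine = 0.003)
  st <- flow_state(g)
  st$p <- array(12.3, g$dims)
  tr <- surface_traction(st, g, sph, rho = 1.2, nu = 0, closed = TRUE)
  f <- integrate_forces(tr$traction, tr$areas)
  expect_lt(max(abs(f[1:3])), 1e-12 * 12.3 * pi * 0.015^2)

  # open membrane in a linear pressure field: the jump gives p-difference
  # times area along the normal
  plate <- wing_mesh(
    rbind(c(-0.01, -0.01, 0), c(0.01, -0.01, 0), c(0.01, 0.01, 0), c(-0.01, 0.01, 0)),
    rbind(c(1, 2, 3), c(1, 3, 4)), side = "left")
  st$p <- grid_eval(g, function(x, y, z) 100 * z)   # linear in z
  trp <- surface_traction(st, g, plate, rho = 1.2, nu = 0, closed = FALSE,
                          offset = 0.004)
  fp <- integrate_forces(trp$traction, trp$areas)
  # jump over 2*offset of a 100 Pa/m gradient, normal +z, area 4 cm^2
  expect_equal(unname(fp[["F_Z"]]), -100 * 2 * 0.004 * 4e-4, tolerance = 0.02 * 0.32e-3)
})
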