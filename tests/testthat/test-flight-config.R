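test_that("default calliope configuration derives chord and viscosity", {
  cfg <- default_calliope_config()
  expect_equal(cfg$Phi, 102.5)
  expect_equal(cfg$U, 8.3)
  expect_equal(cfg$f_beat, 45.5)
  expect_equal(cfg$c_bar, 5.18e-4 / 4.51e-2, tolerance = 1e-12)
  expect_equal(cfg$c_bar, 1.1486e-2, tolerance = 1e-4)
  expect_equal(cfg$nu, 8.3 * cfg$c_bar / 3000, tolerance = 1e-12)
  expect_equal(cfg$nu, 3.178e-5, tolerance = 1e-3)
})

test_that("Re and nu are interchangeable and exactly one must be given", {
  base <- list(U = 8.3, rho = 1.2, M = 2.8e-3, f_beat = 45.5, beta = 67.9,
               Phi = 102.5, R = 4.51e-2, S_ref = 5.18e-4, chi_b = 12, dt = 5e-6)
  via_re <- do.call(flight_config, c(base, list(Re = 3000)))
  via_nu <- do.call(flight_config, c(base, list(nu = via_re$nu)))
  expect_equal(via_nu$Re, 3000, tolerance = 1e-12)
  expect_error(do.call(flight_config, base), "exactly one")
  expect_error(do.call(flight_config, c(base, list(Re = 3000, nu = 1e-5))),
               "exactly one")
})

test_that("parameter invariants are enforced", {
  base <- list(U = 8.3, rho = 1.2, M = 2.8e-3, f_beat = 45.5, beta = 67.9,
               Phi = 102.5, R = 4.51e-2, S_ref = 5.18e-4, chi_b = 12,
               dt = 5e-6, Re = 3000)
  bad <- function(nm, val) {
    b <- base; b[[nm]] <- val
    expect_error(do.call(flight_config, b))
  }
  bad("U", -1); bad("rho", 0); bad("R", -0.01); bad("S_ref", 0)
  bad("beta", 95); bad("beta", -3); bad("Phi", 0); bad("Phi", 180)
})

test_that("steps per cycle matches the production time resolution", {
  cfg <- default_calliope_config()
  # 5 us step at 45.5 Hz gives approximately 4400 steps per wingbeat
  expect_equal(steps_per_cycle(cfg), 1 / (45.5 * 5e-6), tolerance = 1e-12)
  expect_equal(steps_per_cycle(cfg), 4400, tolerance = 0.01)
})
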