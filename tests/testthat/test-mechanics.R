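test_that("Bell off-rate reproduces the exponential law and saturates", {
  p <- clutch_params()
  expect_equal(bell_off_rate(0, p), 0.1)
  expect_equal(bell_off_rate(2, p), 0.1 * exp(1), tolerance = 1e-12)
  expect_equal(bell_off_rate(4, p), 0.1 * exp(2), tolerance = 1e-12)

  # strictly increasing in the force for F >= 0
  f <- seq(0, 20, by = 0.5)
  expect_true(all(diff(bell_off_rate(f, p)) > 0))

  # extreme forces saturate instead of overflowing
  expect_true(is.finite(bell_off_rate(1e6, p)))
  expect_equal(bell_off_rate(1e6, p), 0.1 * exp(50))

  # signed law: compression slows unbinding; magnitude option does not
  expect_lt(bell_off_rate(-4, p), bell_off_rate(0, p))
  pm <- clutch_params(bell_force = "magnitude")
  expect_equal(bell_off_rate(-4, pm), bell_off_rate(4, pm))
})

test_that("clutch force is Hookean in the extension", {
  expect_equal(clutch_force(10, 4, 0.8), 4.8)
  expect_equal(clutch_force(0, 5, 0.8), -4.0)
  expect_equal(clutch_force(7, 7, 0.8), 0)
  expect_equal(clutch_force(c(1, 2, 3), 1, 2), c(0, 2, 4))
})

test_that("substrate force matches the two-spring anchorage law", {
  p <- clutch_params(k_s = 1, k_s_eps0 = 1, l = 1000)
  expect_equal(substrate_force(0, p), 0)

  # undeformed spring: orthogonal term is third order in x_s / l
  r <- sqrt(1000^2 + 25)
  expect_equal(substrate_force(5, p), 5 + (r - 1000) * 5 / r,
               tolerance = 1e-12)
  expect_equal(substrate_force(5, p), 5.0000625, tolerance = 1e-7)

  # axially strained spring contributes a linear fraction eps0/(1+eps0)
  pa <- clutch_params(k_s = 1, k_s_eps0 = 1, l = 1000, eps0 = 3,
                      strain_mode = "axial")
  expect_equal(clutch_geometry(pa)$l_prime, 4000)
  expect_equal(substrate_force(10, pa), 17.500, tolerance = 1e-3)

  # odd in x_s when the spring is undeformed
  xs <- c(1, 10, 100, 900)
  expect_equal(substrate_force(-xs, p), -substrate_force(xs, p))

  # strictly increasing
  expect_true(all(diff(substrate_force(seq(0, 2000, 10), pa)) > 0))

  # canonical variant keeps only the linear substrate spring
  pc <- clutch_params(k_s = 1, model_variant = "canonical")
  expect_equal(substrate_force(c(5, 50, 500), pc), c(5, 50, 500))
})

test_that("transverse offset inverts the strain-offset relation exactly", {
  expect_equal(transverse_offset(0, 1000), 0)
  expect_equal(transverse_offset(1, 1000), 1000 * sqrt(3), tolerance = 1e-12)
  # roundtrip: strain from the offset recovers the input strain
  for (e in c(0.1, 0.25, 0.5, 1, 2, 3)) {
    x0 <- transverse_offset(e, 1000)
    expect_equal(sqrt(1000^2 + x0^2) / 1000 - 1, e, tolerance = 1e-12)
  }
  expect_true(all(diff(transverse_offset(seq(0, 3, 0.1), 1000)) > 0))
  expect_error(transverse_offset(-0.5, 1000), ">= 0")
})

test_that("transverse residual force combines both spring contributions", {
  p <- clutch_params(k_s = 1, k_s_eps0 = 1, l = 1000, eps0 = 1,
                     strain_mode = "transverse")
  expect_equal(residual_force_transverse(0, p), 0)
  expect_equal(residual_force_transverse(1, p), 1000 + 1000 * sqrt(3),
               tolerance = 1e-12)
  # eps0 = 0.25: 250 + 1000 * sqrt(1.25^2 - 1) = 250 + 750
  expect_equal(residual_force_transverse(0.25, p), 1000, tolerance = 1e-12)
})

test_that("equilibrium solver matches closed forms and certifies its root", {
  # no engaged clutches, no residual force: origin
  p <- clutch_params(k_s = 1, k_s_eps0 = 1, l = 1000)
  expect_equal(solve_equilibrium(numeric(0), p), 0)

  # canonical: linear closed form
  pc <- clutch_params(n_c = 2, k_s = 1, model_variant = "canonical")
  expect_equal(solve_equilibrium(c(10, 20), pc), 24 / 2.6, tolerance = 1e-12)

  # single engaged clutch, orthogonal term nearly negligible
  xs <- solve_equilibrium(10, p)
  expect_equal(xs, 8 / 1.8, tolerance = 1e-3)
  g <- clutch_geometry(p)
  expect_lt(abs(0.8 * (10 - xs) - substrate_force(xs, p, g)), 1e-9)

  # modified solver agrees with the linear solution in the long-spring limit
  pl <- clutch_params(n_c = 3, k_s = 1)
  pl$l <- 1e6
  pos <- c(5, 80, 300)
  closed <- 0.8 * sum(pos) / (1 + 3 * 0.8)
  expect_equal(solve_equilibrium(pos, pl), closed, tolerance = 1e-6)
})

test_that("equilibrium residual certificate holds on random configurations", {
  set.seed(42)
  for (i in 1:30) {
    eps0 <- sample(c(0, 0.25, 1, 3), 1)
    mode <- if (eps0 == 0) "none" else sample(c("axial", "transverse"), 1)
    p <- clutch_params(n_c = 30, k_s = sample(c(0.1, 1), 1), eps0 = eps0,
                       strain_mode = mode)
    geom <- clutch_geometry(p)
    pos <- random_engaged_config() + geom$x0
    xs <- solve_equilibrium(pos, p, geom)
    lhs <- geom$F0 + sum(clutch_force(pos, xs, p$k_c))
    rhs <- substrate_force(xs, p, geom)
    expect_lt(abs(lhs - rhs), 1e-9 * max(1, abs(rhs)))
  }
})

test_that("Hill velocity interpolates between free motion and stall", {
  p <- clutch_params(n_c = 50)
  expect_equal(hill_velocity(0, p), 120)
  expect_equal(hill_velocity(100, p), 0)        # ensemble stall: 50 * 2 pN
  expect_equal(hill_velocity(50, p), 60)
  # clamped: no motor reversal, no super-unloaded speeds
  expect_equal(hill_velocity(250, p), 0)
  expect_equal(hill_velocity(-40, p), 120)
})

test_that("parameter validation enforces the physical invariants", {
  expect_error(clutch_params(k_s = -1), "strictly positive")
  expect_error(clutch_params(eps0 = -0.5), ">= 0")
  expect_error(clutch_params(n_c = 0), ">= 1")
  expect_error(clutch_params(eps0 = 1), "strain_mode")
  expect_error(clutch_params(eps0 = 1, strain_mode = "axial",
                             model_variant = "canonical"), "canonical")
  # geometry invariants per mode
  g <- clutch_geometry(clutch_params(eps0 = 2, strain_mode = "axial"))
  expect_equal(g$l_prime, 3000)
  expect_equal(g$x0, 0)
  expect_equal(g$F0, 0)
  g0 <- clutch_geometry(clutch_params(eps0 = 0))
  expect_equal(unclass(g0), list(l_prime = 1000, x0 = 0, F0 = 0),
               ignore_attr = TRUE)
})
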