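test_that("event-time draws follow the exponential inverse CDF", {
  expect_equal(draw_event_time(0.3, exp(-1)), 1 / 0.3)
  expect_equal(draw_event_time(0.3, 0.5), log(2) / 0.3)
  expect_error(draw_event_time(0, 0.5), "positive")
  expect_error(draw_event_time(-1, 0.5), "positive")
  expect_error(draw_event_time(0.3, 0), "inside")
  expect_error(draw_event_time(0.3, 1), "inside")

  # Monte-Carlo mean of 1e5 draws at rate 0.1/s: 10 s within 3 SE
  set.seed(99)
  t <- draw_event_time(0.1, runif(1e5))
  expect_lt(abs(mean(t) - 10), 3 * 10 / sqrt(1e5))
})

test_that("a fixed seed reproduces the trace bit for bit", {
  p <- stiff_params(n_c = 30)
  a <- run_clutch_simulation(p, n_events = 2000, seed = 11)
  b <- run_clutch_simulation(p, n_events = 2000, seed = 11)
  expect_identical(a$trace, b$trace)
  expect_identical(a$failure_times, b$failure_times)
  expect_equal(a$summary, b$summary)
})

test_that("single-clutch system must engage first and stays conservative", {
  p1 <- clutch_params(n_c = 1)
  set.seed(1)
  st <- clutch_step(initial_clutch_state(p1), p1)
  expect_equal(sum(st$engaged), 1L)
  expect_gt(st$t, 0)

  sim <- run_clutch_simulation(stiff_params(n_c = 25), 3000, seed = 4)
  tr <- sim$trace
  expect_true(all(diff(tr$t) > 0))
  expect_true(all(tr$engaged >= 0 & tr$engaged <= 25))
  expect_true(all(tr$v_f >= 0 & tr$v_f <= 120))
  # engagement flips one clutch per event
  expect_true(all(abs(diff(tr$engaged)) == 1))
  # disengaged clutches ride with the substrate
  fs <- sim$final_state
  expect_true(all(fs$x_c[!fs$engaged] == fs$x_s))
})

test_that("global failure returns the substrate to the origin", {
  sim <- run_clutch_simulation(stiff_params(n_c = 20), 5000, seed = 8)
  tr <- sim$trace
  fail_rows <- tr$engaged == 0 & tr$event != "init"
  expect_gt(sum(fail_rows), 0)
  expect_lt(max(abs(tr$x_s[fail_rows])), 1e-8)
  expect_lt(max(abs(tr$F_s[fail_rows])), 1e-8)
  expect_equal(tr$t[fail_rows], sim$failure_times)
})

test_that("unloaded clutches reach the two-state Markov occupancy", {
  p <- soft_params(n_c = 10)
  p$v_u <- 1e-9    # no motor transport: binding is force-free
  s <- run_clutch_simulation(p, n_events = 1e5, seed = 3, record = FALSE,
                             burn_in = "none")
  expect_equal(glance(s)$mean_engaged / 10, 0.75, tolerance = 0.01 / 0.75)
})

test_that("few clutches slip frictionally while many load and fail", {
  g50 <- glance(run_clutch_simulation(stiff_params(n_c = 50), 20000,
                                      seed = 1, record = FALSE))
  g400 <- glance(run_clutch_simulation(stiff_params(n_c = 400), 20000,
                                       seed = 1, record = FALSE))
  # slippage: sparse engagement, short cycles, fast flow
  expect_lt(g50$mean_engaged / 50, 0.5 * g400$mean_engaged / 400)
  expect_lt(g50$mean_cycle_time, 0.5 * g400$mean_cycle_time)
  expect_gt(g50$mean_v_f, g400$mean_v_f)
  # load-and-fail: larger substrate excursions
  expect_gt(g400$mean_x_s, g50$mean_x_s)
})

test_that("R-side trace summary agrees with the engine accumulators", {
  sim <- run_clutch_simulation(stiff_params(n_c = 40), 4000, seed = 6)
  expect_equal(summarize_trace(sim), sim$summary, tolerance = 1e-8)
  sim0 <- run_clutch_simulation(stiff_params(n_c = 40), 4000, seed = 6,
                                burn_in = "none")
  expect_equal(summarize_trace(sim0, "none"), sim0$summary, tolerance = 1e-8)
})

test_that("cycle time is the mean spacing of failures, missing when absent", {
  expect_equal(clutchsim:::cycle_time(c(10, 20, 35)), 12.5)
  expect_true(is.na(clutchsim:::cycle_time(c(7))))
  expect_true(is.na(clutchsim:::cycle_time(numeric(0))))
})

test_that("canonical and modified variants agree at zero residual strain", {
  for (nc in c(50, 200)) {
    vm <- mean(vapply(1:3, function(sd) {
      glance(run_clutch_simulation(stiff_params(n_c = nc), 20000, seed = sd,
                                   record = FALSE))$mean_v_f
    }, numeric(1)))
    vc <- mean(vapply(1:3, function(sd) {
      glance(run_clutch_simulation(
        stiff_params(n_c = nc, model_variant = "canonical"), 20000,
        seed = sd, record = FALSE))$mean_v_f
    }, numeric(1)))
    expect_equal(vm, vc, tolerance = 0.1)
  }
})

test_that("an empty event budget returns only the initial state", {
  sim <- run_clutch_simulation(clutch_params(n_c = 5), 0, seed = 1)
  expect_equal(nrow(sim$trace), 1L)
  expect_equal(sim$trace$event, "init")
  expect_equal(sim$final_state$t, 0)
})

test_that("transverse runs start from the pre-strained baseline", {
  p <- stiff_params(n_c = 20, eps0 = 1, strain_mode = "transverse")
  geom <- clutch_geometry(p)
  st <- initial_clutch_state(p)
  # residual force alone balances the anchorage beyond the offset
  expect_gt(st$x_s, geom$x0)
  expect_equal(geom$F0, substrate_force(st$x_s, p, geom), tolerance = 1e-6)
  # motors start unloaded: the residual force is not felt by the clutches
  expect_equal(st$v_f, 120)
  sim <- run_clutch_simulation(p, 500, seed = 2)
  expect_equal(sim$trace$x_s[1], st$x_s, tolerance = 1e-8)
})

test_that("individual-tension Bell kinetics are exposed and differ", {
  pi_ <- stiff_params(n_c = 100, bell_load = "individual")
  ps <- stiff_params(n_c = 100)
  gi <- glance(run_clutch_simulation(pi_, 10000, seed = 5, record = FALSE))
  gs <- glance(run_clutch_simulation(ps, 10000, seed = 5, record = FALSE))
  # per-bond loading culls stretched clutches: sparser engagement, faster flow
  expect_lt(gi$mean_engaged, gs$mean_engaged)
  expect_gt(gi$mean_v_f, gs$mean_v_f)
})
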