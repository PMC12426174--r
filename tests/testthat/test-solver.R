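test_that("zero bath concentration leaves the zero state fixed in every mode", {
  g <- foley_geometry("14Fr")
  gr <- radial_grid(g, 21)
  p <- transport_parameters(1.744e-5, 1.478, 0.7688, bath_concentration = 0)
  st <- wall_state(0, numeric(21))
  for (mode in c("load", "rest")) {
    out <- step_stage(st, NULL, mode, p, g, gr, dt = 0.5)
    expect_equal(out$state$concentration, numeric(21))
  }
  out <- step_stage(st, reservoir_state(0, 0), "delivery", p, g, gr, dt = 0.5)
  expect_equal(out$state$concentration, numeric(21))
  expect_equal(out$reservoir$CD, 0)
})

test_that("rest steps conserve wall mass exactly and delivery requires a reservoir", {
  g <- foley_geometry("14Fr")
  gr <- radial_grid(g, 41)
  p <- cfx_parameters("control")
  set.seed(7)
  C <- abs(rnorm(41, 500, 100))
  st <- wall_state(0, C)
  m0 <- wall_mass(C, gr)
  for (i in 1:20) st <- step_stage(st, NULL, "rest", p, g, gr, dt = 0.3)$state
  expect_lt(abs(wall_mass(st$concentration, gr) - m0) / m0, 1e-10)
  expect_error(step_stage(st, NULL, "delivery", p, g, gr, dt = 0.3),
               "reservoir")
  expect_error(step_stage(wall_state(0, numeric(10)), NULL, "rest", p, g, gr,
                          dt = 0.3), "grid")
})

test_that("well-mixed loading relaxes every node to gamma_L * C_L", {
  g <- foley_geometry("14Fr")
  p <- cfx_parameters("control")
  sim <- simulate_protocol(g, p, stage_protocol(4000, 4001, 4002),
                           numerics_config(n_nodes = 41, dt_load = 5,
                                           dt_rest = 0.5, dt_delivery = 1))
  eq <- p$gamma_load * p$bath_concentration
  Cend <- sim$stages$load$states[nrow(sim$stages$load$states), ]
  expect_lt(max(abs(Cend - eq)) / eq, 1e-6)
})

test_that("snapshots cover the stage boundaries and states stay nonnegative", {
  sim <- simulate_protocol(foley_geometry("14Fr"), cfx_parameters("control"),
                           stage_protocol(), mid_numerics())
  expect_equal(sim$stages$load$times[1], 0)
  expect_equal(sim$stages$load$times[length(sim$stages$load$times)], 12)
  expect_equal(sim$stages$rest$times[length(sim$stages$rest$times)], 36)
  d <- sim$stages$delivery$times
  expect_equal(d[1], 36)
  expect_equal(d[length(d)], 396)
  expect_true(all(sim$stages$load$states >= 0))
  expect_true(all(sim$stages$delivery$states >= -1e-12))
  # no interior value exceeds the loading boundary data
  eq <- 1.478 * 1330
  expect_lte(max(sim$stages$load$states), eq)
})

test_that("finite-bath delivery conserves wall + reservoir mass; CD and release are monotone", {
  for (cond in c("control", "LbL")) {
    sim <- simulate_protocol(foley_geometry("14Fr"), cfx_parameters(cond),
                             stage_protocol(), mid_numerics())
    audit <- mass_balance_audit(sim)
    expect_lt(audit$rest_defect, 1e-10)
    expect_lt(audit$delivery_defect, 1e-8)
    expect_true(all(diff(sim$stages$delivery$cd) >= 0))
    expect_true(all(diff(sim$stages$delivery$release) >= 0))
  }
})

test_that("pure-sink delivery matches its own boundary-flux integral and is monotone", {
  p <- cfx_parameters("control", reservoir_volume = Inf)
  sim <- simulate_protocol(foley_geometry("14Fr"), p, stage_protocol(),
                           mid_numerics())
  audit <- mass_balance_audit(sim)
  expect_lt(audit$delivery_defect, 1e-6)
  expect_true(all(diff(sim$stages$delivery$release) >= 0))
  # sink releases at least as much as the finite bath
  simf <- simulate_protocol(foley_geometry("14Fr"), cfx_parameters("control"),
                            stage_protocol(), mid_numerics())
  expect_gte(final_release(sim), final_release(simf) - 1e-6)
})

test_that("long-run finite-bath delivery reaches the closed-form equilibrium", {
  g <- foley_geometry("14Fr")
  p <- cfx_parameters("control", reservoir_volume = 10)
  sim <- simulate_protocol(g, p, stage_protocol(12, 36, 36 + 2500),
                           numerics_config(n_nodes = 101, dt_load = 0.05,
                                           dt_rest = 0.2, dt_delivery = 1))
  M1 <- wall_mass(sim$stages$delivery$states[1, ], sim$grid)
  cd_inf <- equilibrium_reservoir(M1, g, p)
  cd_end <- sim$stages$delivery$cd[length(sim$stages$delivery$cd)]
  expect_lt(abs(cd_end / cd_inf - 1), 0.005)
})

test_that("Robin conditions with large k reproduce the well-mixed reduction", {
  g <- foley_geometry("14Fr")
  pr <- cfx_parameters("control", k_load = 1e4, k_delivery = 1e4)
  pw <- cfx_parameters("control")
  num <- mid_numerics()
  sr <- simulate_protocol(g, pr, stage_protocol(), num)
  sw <- simulate_protocol(g, pw, stage_protocol(), num)
  expect_lt(abs(final_release(sr) / final_release(sw) - 1), 0.001)
  expect_lt(mass_balance_audit(sr)$delivery_defect, 1e-8)
})

test_that("crank-nicolson scheme is available and agrees with implicit Euler", {
  g <- foley_geometry("14Fr")
  p <- cfx_parameters("control")
  # CN needs dt small enough that the stage-boundary jumps excite no
  # sign-flipping modes (dt * 4D/h^2 < 2); larger steps raise the
  # numerical-instability error by design
  num_cn <- numerics_config(n_nodes = 61, dt_load = 0.02, dt_rest = 0.05,
                            dt_delivery = 0.05, scheme = "crank-nicolson")
  num_ie <- numerics_config(n_nodes = 61, dt_load = 0.02, dt_rest = 0.05,
                            dt_delivery = 0.05)
  sc <- simulate_protocol(g, p, stage_protocol(), num_cn)
  si <- simulate_protocol(g, p, stage_protocol(), num_ie)
  expect_lt(abs(final_release(sc) / final_release(si) - 1), 0.01)
  expect_lt(mass_balance_audit(sc)$delivery_defect, 1e-8)
  expect_error(
    simulate_protocol(g, p, stage_protocol(),
                      numerics_config(n_nodes = 101, dt_load = 0.05,
                                      dt_rest = 0.2, dt_delivery = 0.5,
                                      scheme = "crank-nicolson")),
    "smaller time step")
})

test_that("spatial convergence of loading uptake is near second order", {
  g <- foley_geometry("14Fr")
  p <- cfx_parameters("control")
  upt <- vapply(c(51, 101, 201), function(n) {
    sim <- simulate_protocol(g, p, stage_protocol(6, 6.5, 7.5),
                             numerics_config(n_nodes = n, dt_load = 0.002,
                                             dt_rest = 0.5, dt_delivery = 1))
    load_end_uptake(sim)
  }, numeric(1))
  order <- log2((upt[1] - upt[2]) / (upt[2] - upt[3]))
  expect_gte(order, 1.9)
})
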