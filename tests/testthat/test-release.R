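test_that("release conversion starts at zero and inverts exactly to CD", {
  sim <- simulate_protocol(foley_geometry("14Fr"), cfx_parameters("control"),
                           stage_protocol(), mid_numerics())
  prof <- cumulative_release(sim)
  expect_equal(prof$time_h[1], 0)
  expect_equal(prof$release_ug_cm2[1], 0)
  cd_back <- prof$release_ug_cm2 * external_area(sim$geometry) /
    sim$params$reservoir_volume
  expect_equal(cd_back, prof$cd_ug_cm3, tolerance = 1e-12)
})

test_that("short-time uptake oracle has the closed form's value and scaling", {
  p <- cfx_parameters("control")
  direct <- 2 * 1.478 * 1330 * sqrt(1.744e-5 * 12 / pi)
  expect_equal(short_time_uptake(p, 12), direct)
  expect_equal(short_time_uptake(p, 12), 32.088, tolerance = 1e-4)
  expect_equal(short_time_uptake(p, 48) / short_time_uptake(p, 12), 2)
  expect_lt(short_time_uptake(p, 1e-10), 1e-3)
  expect_error(short_time_uptake(p, 0), "positive")
  expect_error(short_time_uptake(p, -3), "positive")
})

test_that("loading-stage uptake matches the semi-infinite oracle within 1%", {
  g <- foley_geometry("14Fr")
  p <- cfx_parameters("control")
  # penetration sqrt(D t) ~ 0.003 cm << 0.03 cm (0.3 * wall thickness)
  sim <- simulate_protocol(g, p, stage_protocol(0.5, 0.6, 1.6),
                           numerics_config(n_nodes = 801, dt_load = 2e-5,
                                           dt_rest = 0.1, dt_delivery = 0.5))
  expect_lt(abs(load_end_uptake(sim) / short_time_uptake(p, 0.5) - 1), 0.01)
})

test_that("equilibrium reservoir concentration follows the mass balance", {
  g <- foley_geometry("14Fr")
  p <- cfx_parameters("control")
  expect_equal(equilibrium_reservoir(0, g, p), 0)
  p_inf <- cfx_parameters("control", reservoir_volume = Inf)
  expect_equal(equilibrium_reservoir(100, g, p_inf), 0)
  direct <- 100 / (0.7688 * pi * (0.235^2 - 0.135^2) * 2.5 + 250)
  expect_equal(equilibrium_reservoir(100, g, p), direct)
  expect_error(equilibrium_reservoir(-1, g, p), "nonnegative")
})

test_that("wall snapshots show surface accumulation then inward spreading", {
  sim <- simulate_protocol(foley_geometry("14Fr"), cfx_parameters("control"),
                           stage_protocol(), mid_numerics())
  sn <- wall_profile_snapshots(sim, c(0, 12, 36))
  at <- function(tt) sn$concentration_ug_cm3[sn$time_h == tt]
  expect_true(all(at(0) == 0))
  # end of loading: maximum at the outer wall
  expect_equal(which.max(at(12)), sim$grid$n)
  # rest stage spreads the profile inward at constant mass
  expect_lt(max(at(36)), max(at(12)))
  mid <- floor(sim$grid$n / 2)
  expect_gt(at(36)[mid], at(12)[mid])
  expect_equal(wall_mass(at(36), sim$grid), wall_mass(at(12), sim$grid),
               tolerance = 1e-10)
  expect_error(wall_profile_snapshots(sim, 1000), "range")
})

test_that("protocol sweeps obey the sqrt-time uptake law and conservation", {
  g <- foley_geometry("14Fr")
  p <- cfx_parameters("control")
  num <- numerics_config(n_nodes = 61, dt_load = 0.05, dt_rest = 0.2,
                         dt_delivery = 0.5)
  sw <- sweep_protocol(g, p, c(12, 48), c(24), 48, num)
  u <- sw$uptake
  ratio <- u$uptake_ug_cm2[u$load_h == 48] / u$uptake_ug_cm2[u$load_h == 12]
  expect_gt(ratio, 1)
  expect_lt(ratio, 2.1)  # saturating, below the pure sqrt(4) = 2 law + slack
  # uptake while penetration << wall tracks the closed form
  expect_equal(u$uptake_ug_cm2[u$load_h == 12][1], short_time_uptake(p, 12),
               tolerance = 0.05)
  # released mass never exceeds the wall mass at delivery start
  for (ld in c(12, 48)) {
    final <- max(sw$release$release_ug_cm2[sw$release$load_h == ld])
    expect_lte(final, u$uptake_ug_cm2[u$load_h == ld][1] * (1 + 1e-9))
  }
})

test_that("matched 14Fr and 20Fr release-per-area curves differ by < 5%", {
  p <- cfx_parameters("control")
  num <- mid_numerics()
  s14 <- simulate_protocol(foley_geometry("14Fr"), p, stage_protocol(), num)
  s20 <- simulate_protocol(foley_geometry("20Fr"), p, stage_protocol(), num)
  r14 <- cumulative_release(s14)
  r20 <- cumulative_release(s20)
  i <- r14$time_h > 0.5  # skip the near-zero start where ratios are ill-posed
  expect_lt(max(abs(r14$release_ug_cm2[i] - r20$release_ug_cm2[i]) /
                  r14$release_ug_cm2[i]), 0.05)
})
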