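test_that("residuals vanish at the generating parameters and grow when perturbed", {
  num <- coarse_numerics()
  ds <- synthetic_release_dataset(seed = 3, noise = noise_model(scale = 0),
                                  numerics = num)
  cfg <- fit_config(numerics = num)
  r0 <- release_residuals(truth_params, ds$datasets, cfg)
  expect_lt(max(abs(r0)), 1e-6)
  # local identifiability of D: +10% strictly increases the sum of squares
  pD <- truth_params
  pD["D"] <- pD["D"] * 1.1
  expect_gt(sum(release_residuals(pD, ds$datasets, cfg)^2), sum(r0^2))
  # all-zero data: residuals equal the model curve itself
  zero <- ds$datasets[[1]]
  zero$profile$release_ug_cm2 <- 0
  rz <- release_residuals(truth_params, list(zero), cfg)
  sim <- simulate_protocol(zero$geometry,
                           cfx_parameters("control"), zero$protocol, num)
  ref <- cumulative_release(sim)
  expect_equal(rz, approx(ref$time_h, ref$release_ug_cm2,
                          xout = zero$profile$time_h)$y, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(release_residuals(truth_params[-1], ds$datasets, cfg),
               "missing")
})

test_that("failing candidate simulations yield finite penalty residuals", {
  num <- coarse_numerics()
  ds <- synthetic_release_dataset(seed = 3, noise = noise_model(scale = 0),
                                  numerics = num)
  bad <- truth_params
  bad["D"] <- NA_real_  # candidate that cannot simulate
  r <- release_residuals(bad, ds$datasets, fit_config(numerics = num))
  expect_true(all(is.finite(r)))
  expect_equal(attr(r, "n_failures"), 4L)
  expect_true(all(r == fit_config()$penalty))
})

test_that("log-space and linear-space fits agree on noise-free data", {
  num <- coarse_numerics()
  ds <- synthetic_release_dataset(seed = 5, noise = noise_model(scale = 0),
                                  numerics = num)
  init <- truth_params * 1.5
  f_log <- fit_release_parameters(ds$datasets,
                                  fit_config(numerics = num), init = init)
  f_lin <- fit_release_parameters(ds$datasets,
                                  fit_config(numerics = num,
                                             log_scale = FALSE), init = init)
  expect_true(f_log$converged)
  expect_true(f_lin$converged)
  expect_equal(f_log$estimates, f_lin$estimates, tolerance = 1e-4)
})

test_that("estimator bias shrinks as the noise level shrinks", {
  num <- coarse_numerics()
  med_err <- sapply(c(0.03, 0.01, 0.003), function(scale) {
    errs <- sapply(1:3, function(s) {
      ds <- synthetic_release_dataset(seed = 100 + s,
                                      noise = noise_model(scale = scale),
                                      numerics = num)
      fit <- fit_release_parameters(ds$datasets, fit_config(numerics = num),
                                    init = truth_params * 2)
      abs(fit$estimates[["D"]] / truth_params[["D"]] - 1)
    })
    median(errs)
  })
  expect_true(all(diff(med_err) < 0))
  expect_lt(med_err[3], med_err[1] / 2)
})

test_that("a single profile leaves D and gamma_L nearly collinear; the joint fit restores conditioning", {
  num <- coarse_numerics()
  ds <- synthetic_release_dataset(seed = 1, noise = noise_model(scale = 0),
                                  numerics = num)
  cfg <- fit_config(numerics = num)
  J_joint <- fd_log_jacobian(ds$datasets, truth_params, cfg)
  single <- ds$datasets[1]  # one condition, one size
  J_single <- fd_log_jacobian(
    single, truth_params[c("D", "gammaL.control", "gammaD.control")], cfg)
  cond_of <- function(J, cols) kappa(crossprod(J[, cols]), exact = TRUE)
  cols <- c("D", "gammaL.control")
  expect_gt(cond_of(J_single, cols), 10 * cond_of(J_joint, cols))
  w <- capture_warnings(
    fit_release_parameters(single, fit_config(numerics = num, maxiter = 1),
                           init = truth_params))
  expect_true(any(grepl("weakly identified", w)))
})
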