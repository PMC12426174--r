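# Shared fixtures: the reference kinetic parameter set and reduced problem
# sizes used to keep closed-loop fits fast while generator and fitter share
# one numerics configuration.

truth_params <- c(D = 1.744e-5,
                  gammaL.control = 1.478, gammaL.LbL = 3.928,
                  gammaD.control = 0.7688, gammaD.LbL = 1.282)

coarse_numerics <- function() {
  numerics_config(n_nodes = 61, dt_load = 0.1, dt_rest = 0.25,
                  dt_delivery = 1)
}

mid_numerics <- function() {
  numerics_config(n_nodes = 101, dt_load = 0.05, dt_rest = 0.2,
                  dt_delivery = 0.5)
}

# Forward-difference Jacobian of the residual vector in log-parameter space.
fd_log_jacobian <- function(datasets, pv, config, eps = 1e-6) {
  r0 <- release_residuals(pv, datasets, config)
  sapply(names(pv), function(nm) {
    p2 <- pv
    p2[nm] <- p2[nm] * exp(eps)
    (release_residuals(p2, datasets, config) - r0) / eps
  })
}

final_release <- function(sim) {
  rel <- sim$stages$delivery$release
  rel[length(rel)]
}

load_end_uptake <- function(sim) {
  st <- sim$stages$load$states
  wall_mass(st[nrow(st), ], sim$grid) / external_area(sim$geometry)
}
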