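# Independent oracles used to check the analytical implementations.

# Slow relaxation rate of the exact 2x2 linear system
#   closed <-> open -> exchanged
# via a numerical eigendecomposition (not the closed forms under test).
oracle_slow_rate <- function(k_op, k_cl, k_ch) {
  A <- matrix(c(-k_op, k_cl,
                k_op, -(k_cl + k_ch)), nrow = 2, byrow = TRUE)
  ev <- eigen(A, only.values = TRUE)$values
  min(abs(Re(ev)))
}

# Protonated fraction by numerical ODE integration of df/dt = -k(t) f with
# piecewise-constant rates (integrated phase by phase).
oracle_protonated_fraction <- function(rates_h, durations_min) {
  f <- 1
  for (i in seq_along(rates_h)) {
    sol <- deSolve::ode(
      y = c(f = unname(f)), times = c(0, durations_min[i] / 60),
      func = function(t, y, p) list(-p * y), parms = rates_h[i],
      rtol = 1e-12, atol = 1e-14
    )
    f <- sol[nrow(sol), "f"]
  }
  unname(f)
}

# Monte-Carlo sd of the ratio of two Gaussian-noised signals with given
# true ratio and SNRs.
oracle_ratio_error_mc <- function(r, snr_pert, snr_gc, n = 1e5) {
  i_gc <- 1 + stats::rnorm(n, 0, 1 / snr_gc)
  i_p <- r * (1 + stats::rnorm(n, 0, 1 / snr_pert))
  stats::sd(i_p / i_gc)
}

# Ground-truth response direction of each fixture residue under a scenario.
expected_direction <- function(residues, scenario_type) {
  hydrophilic <- residues$hydropathy_class == "hydrophilic_surface"
  if (scenario_type == "thz") {
    ifelse(hydrophilic, "decelerated", "accelerated")
  } else {
    ifelse(hydrophilic, "accelerated", "decelerated")
  }
}

classify_fixture_run <- function(residues, scenario, condition, nominal_snr,
                                 seed) {
  peaks <- simulate_run(residues, scenario, condition,
                        nominal_snr = nominal_snr, seed = seed)
  suppressWarnings(classify_residues(compute_ratios(peaks)))
}
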