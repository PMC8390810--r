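test_that("general two-state rate matches the eigenvalue oracle and its limits", {
  # no chemistry, no exchange
  expect_equal(exchange_rate_general(1, 10, 0), 0)
  expect_equal(exchange_rate_general(0, 0, 0), 0)

  # EX2 regime example: agrees with the slow eigenvalue and with K_op*k_ch
  r <- exchange_rate_general(1, 1e4, 1)
  expect_equal(r, oracle_slow_rate(1, 1e4, 1), tolerance = 1e-3)
  expect_equal(r, 1e-4, tolerance = 1e-3)

  # EX1 regime example: rate is the opening rate
  expect_equal(exchange_rate_general(0.01, 1, 1e6), 0.01, tolerance = 1e-3)

  expect_error(exchange_rate_general(-1, 1, 1), "non-negative")
})

test_that("general rate tracks the slow eigenvalue in the pre-equilibrium regime", {
  set.seed(42)
  for (i in 1:200) {
    k_cl <- 10^runif(1, -2, 4)
    k_ch <- 10^runif(1, -2, 4)
    k_op <- runif(1, 0, 0.005) * (k_cl + k_ch)
    r <- exchange_rate_general(k_op, k_cl, k_ch)
    expect_equal(r, oracle_slow_rate(k_op, k_cl, k_ch), tolerance = 0.01)
  }
})

test_that("EX2 and EX1 limits hold to 1%", {
  set.seed(7)
  for (i in 1:200) {
    k_ch <- 10^runif(1, -3, 3)
    k_op <- 10^runif(1, -3, 3)
    # EX2: closing dominates both chemistry and opening
    k_cl <- max(k_op, k_ch) * 10^runif(1, 2, 5)
    ex2 <- ex2_rate(k_op / k_cl, k_ch)
    expect_equal(exchange_rate_general(k_op, k_cl, k_ch), ex2,
                 tolerance = 0.01)
    # EX1: chemistry dominates
    k_cl2 <- 10^runif(1, -3, 3)
    k_op2 <- 10^runif(1, -3, 3)
    k_ch2 <- (k_op2 + k_cl2) * 10^runif(1, 2, 5)
    expect_equal(exchange_rate_general(k_op2, k_cl2, k_ch2), k_op2,
                 tolerance = 0.01)
  }
})

test_that("EX2 product rate behaves", {
  expect_equal(ex2_rate(1e-4, 1e3), 0.1)
  expect_equal(ex2_rate(1, 0.37), 0.37) # fully open = intrinsic
  expect_equal(ex2_rate(0.5, 0), 0)
  expect_error(ex2_rate(0, 1), "positive")
  expect_error(ex2_rate(-1e-4, 1), "positive")
})

test_that("pH scaling is pure base catalysis: 10-fold per unit, multiplicative", {
  m <- intrinsic_rate_model(k_ref = 2, ph_ref = 5.6)
  expect_equal(scale_kch_ph(m, 5.6), 2)
  expect_equal(scale_kch_ph(m, 6.6), 20)
  expect_equal(scale_kch_ph(m, 7.2), 2 * 10^1.6)

  # exact multiplicativity: f(p1 + p2 - ref) = f(p1) f(p2) / k_ref
  set.seed(1)
  p1 <- runif(20, 3, 9); p2 <- runif(20, 3, 9)
  expect_equal(scale_kch_ph(m, p1 + p2 - m$ph_ref),
               scale_kch_ph(m, p1) * scale_kch_ph(m, p2) / m$k_ref)
  expect_error(scale_kch_ph(m, NaN), "finite")
})

test_that("temperature scaling is Arrhenius", {
  m <- intrinsic_rate_model(k_ref = 1, t_ref_c = 25, ea_kj_mol = 60)
  expect_equal(scale_kch_temperature(m, 25), 1)
  expect_equal(scale_kch_temperature(m, 30),
               exp(-(60 / 8.31446261815324e-3) * (1 / 303.15 - 1 / 298.15)))
  expect_equal(scale_kch_temperature(m, 30), 1.49, tolerance = 0.005)
  m0 <- intrinsic_rate_model(k_ref = 3, ea_kj_mol = 0)
  expect_equal(scale_kch_temperature(m0, c(-20, 4, 95)), rep(3, 3))
  expect_error(scale_kch_temperature(m, -300), "absolute zero")
})

test_that("protonated fraction: closed form, ODE oracle, subdivision, monotonicity", {
  res <- tibble::tibble(residue_number = 1L,
                        hydropathy_class = "hydrophobic_surface",
                        K_op = 1e-4, k_ch_ref = 1e3) # k_ex = 0.1 h^-1
  one <- phase_schedule(protocol_phase(14, 25, 5.6))
  f <- protonated_fraction(one, res)$fraction
  expect_equal(f, exp(-0.1 * 14 / 60), tolerance = 1e-9)
  expect_equal(f, oracle_protonated_fraction(0.1, 14), tolerance = 1e-6)

  # zero rate -> fraction 1
  res0 <- dplyr::mutate(res, k_ch_ref = 0)
  expect_equal(protonated_fraction(one, res0)$fraction, 1)

  # splitting a phase changes nothing
  two <- phase_schedule(protocol_phase(7, 25, 5.6), protocol_phase(7, 25, 5.6))
  expect_equal(protonated_fraction(two, res)$fraction, f)

  # appending phases never increases the fraction; multi-phase vs ODE oracle
  sched <- phase_schedule(
    protocol_phase(1, 25, 5.6),
    protocol_phase(6, 30, 5.6),
    protocol_phase(7, 25, 5.6),
    protocol_phase(480, 4, 5.6, kch_mult = c("*" = 0.05))
  )
  fracs <- purrr::map_dbl(seq_len(4), function(k) {
    protonated_fraction(
      do.call(phase_schedule, purrr::map(seq_len(k), ~ sched[.x, ])),
      res
    )$fraction
  })
  expect_true(all(diff(fracs) <= 0))
  rates <- phase_rates(sched, res)
  expect_equal(
    protonated_fraction(sched, res)$fraction,
    oracle_protonated_fraction(rates$k_ex, rates$duration_min),
    tolerance = 1e-6
  )

  expect_error(phase_schedule(), "positive duration")
})

test_that("phase multipliers act on the right classes", {
  res <- tibble::tibble(
    residue_number = 1:2,
    hydropathy_class = c("hydrophobic_surface", "hydrophilic_surface"),
    K_op = c(1e-5, 1e-4), k_ch_ref = c(1e3, 1e3)
  )
  sched <- phase_schedule(protocol_phase(
    60, 25, 5.6,
    kop_mult = c(hydrophobic_surface = 2),
    kch_mult = c(hydrophilic_surface = 0.5)
  ))
  k <- phase_rates(sched, res)
  expect_equal(k$k_ex, c(2 * 1e-5 * 1e3, 0.5 * 1e-4 * 1e3))
})

test_that("apparent pH order distinguishes ideal EX2 from opening-limited exchange", {
  expect_equal(ph_sensitivity(0.1, 0.1 * 10^1.6, 5.6, 7.2), 1)
  expect_equal(ph_sensitivity(0.05, 0.05, 5, 6), 0)
  expect_equal(ph_sensitivity(1, 4, 5.6, 7.2), log10(4) / 1.6)
  expect_error(ph_sensitivity(0, 1, 5, 6), "positive")
  expect_error(ph_sensitivity(1, 1, 6, 6), "differ")
})
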