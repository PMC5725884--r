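rv_rate <- function(rv, term) rv$rate[rv$term == term]

test_that("inhibition factor matches its linear form and clamps at zero", {
  expect_equal(inhib(0.6945, ha_params()), 0.699975)
  expect_equal(inhib(0, ha_params()), 2.4015)
  expect_equal(inhib(0.6945, ha_params(inhib_variant = "strong")), 0.7)
  # clamp: beyond intercept/slope the factor is zero, not negative
  expect_equal(inhib(1.5, ha_params()), 0)
  expect_equal(inhib(0.8, ha_params(inhib_variant = "strong")), 0)
  expect_error(inhib(-0.1, ha_params()), ">= 0")
})

test_that("saturable velocities reproduce hand-evaluated values", {
  rv <- reaction_velocities(ha_reference_state, ha_params())
  # frozen hand evaluations of the Michaelis-Menten forms
  expect_equal(rv_rate(rv, "v_htl"), 424.371294511, tolerance = 1e-9)
  expect_equal(rv_rate(rv, "v_hat"), 2670.52212389, tolerance = 1e-9)
  expect_equal(rv_rate(rv, "v_mat"), 2641.41078067, tolerance = 1e-9)
  expect_equal(rv_rate(rv, "release"), 2640.6556875, tolerance = 1e-9)
  # synthesis carries the inhibition factor
  expect_equal(attr(rv, "inhib"), 0.699975)
  expect_false(attr(rv, "inhib_clamped"))
})

test_that("saturable velocities vanish at zero substrate", {
  zero <- stats::setNames(rep(0, 10), STATE_VARS)
  rv <- reaction_velocities(zero, ha_params())
  sat <- c("v_htl", "v_htdc", "v_hnmt", "v_hnmt_g", "v_hat", "v_hat_g",
           "v_mat", "release")
  expect_equal(rv$rate[rv$term %in% sat], rep(0, length(sat)))
  # only the constant inflows survive: HT_in and the setpoint exchange
  expect_equal(rv_rate(rv, "ht_in"), 424)
  expect_equal(rv_rate(rv, "bht_stab"), 0.25 * (0 - 100))
})

test_that("rhs is assembled exactly from the flux decomposition", {
  p <- ha_params()
  states <- list(
    ha_reference_state,
    stats::setNames(c(1, 10, 0.5, 0.2, 80, 100, 200, 0.3, 5, 1),
                    STATE_VARS),
    stats::setNames(c(0.01, 400, 12, 3, 150, 50, 600, 0.9, 40, 8),
                    STATE_VARS)
  )
  for (s in states) {
    d <- varicosity_rhs(0, s, p)
    nets <- dplyr::summarise(dplyr::group_by(flux_balance(s, p), variable),
                             net = sum(flux))
    expect_equal(nets$net[match(STATE_VARS, nets$variable)],
                 unname(d), tolerance = 1e-12)
  }
})

test_that("rhs at the reference equilibrium balances to rounding error", {
  p <- ha_params()
  d <- varicosity_rhs(0, ha_reference_state, p)
  # the reference state is quoted to 3-4 significant figures, so each
  # equation's imbalance is bounded by the rounding of its gross
  # turnover; the receptor-binding equation turns over thousands of
  # uM/hr, hence the larger absolute allowance
  expect_lt(max(abs(d)), 6)
  gross <- dplyr::summarise(
    dplyr::group_by(flux_balance(ha_reference_state, p), variable),
    gross = sum(abs(flux)))
  rel <- abs(d[gross$variable]) / pmax(gross$gross, 1)
  # glial histamine is quoted to two significant figures only
  expect_lt(max(rel), 5e-3)
})

test_that("silencing firing removes the release term", {
  p <- ha_params()
  s <- ha_reference_state
  fp0 <- firing_protocol(default_rate = 0)
  d0 <- varicosity_rhs(0, s, p, firing = fp0)
  d5 <- varicosity_rhs(0, s, p)
  rv <- reaction_velocities(s, p, firing_rate = 0)
  expect_equal(d0[["vHA"]], rv_rate(rv, "v_mat"))
  expect_gte(d0[["vHA"]], d5[["vHA"]])
})

test_that("speed multipliers rescale derivatives but preserve zeros", {
  ss <- nominal_ss()
  p_fast <- ha_params(speed_gstar = 5, speed_tstar = 5, speed_bha = 0.3)
  d <- varicosity_rhs(0, ss, p_fast)
  expect_lt(max(abs(d)), 1e-5)
  # away from equilibrium the multipliers scale the transduction rates
  s <- ha_reference_state
  s[["eHA"]] <- 5
  d1 <- varicosity_rhs(0, s, ha_params())
  d2 <- varicosity_rhs(0, s, p_fast)
  expect_equal(d2[["bHA"]], 0.3 * d1[["bHA"]])
  expect_equal(d2[["Gstar"]], 5 * d1[["Gstar"]])
})
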