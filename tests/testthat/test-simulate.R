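test_that("the steady state is invariant under constant protocols", {
  ss <- nominal_ss()
  traj <- simulate_varicosity(ha_params(), initial = ss,
                              t_span = c(0, 24),
                              output_times = seq(0, 24, by = 1))
  for (v in STATE_VARS) {
    expect_equal(traj[[v]], rep(ss[[v]], nrow(traj)), tolerance = 1e-6)
  }
})

test_that("output grids are honoured exactly", {
  ss <- nominal_ss()
  out_s <- seq(0, 30, by = 0.1)
  st <- control_stim()
  expect_equal(nrow(st$trace), 301)
  expect_equal(st$trace$time_s, out_s)
  traj <- simulate_varicosity(ha_params(), initial = ss,
                              t_span = c(0, 1),
                              output_times = c(0, 0.25, 1))
  expect_equal(traj$time_hr, c(0, 0.25, 1))
  expect_error(
    simulate_varicosity(ha_params(), initial = ss, t_span = c(0, 1),
                        output_times = c(0, 2)),
    "within t_span")
})

test_that("trajectories stay non-negative and below conservation caps", {
  p <- ha_params()
  ss <- nominal_ss()
  runs <- list(
    control = control_stim()$trace,
    antagonist = antagonist_stim()$trace,
    halflife = halflife_result()$trajectory,
    load = load_result()$trajectory
  )
  for (nm in names(runs)) {
    tr <- runs[[nm]]
    caps_p <- if (nm == "antagonist") ha_params(b0 = 4) else p
    for (v in STATE_VARS) expect_true(all(tr[[v]] >= 0), label = paste(nm, v))
    expect_true(all(tr$Gstar <= caps_p$g0), label = nm)
    expect_true(all(tr$Tstar <= caps_p$t0), label = nm)
    expect_true(all(tr$bHA <= caps_p$b0), label = nm)
  }
})

test_that("piecewise forcing is applied without smoothing", {
  ss <- nominal_ss()
  # one-sided step in dietary input: bHT must be rising right after the
  # step and still at baseline just before it
  inp <- input_protocol(data.frame(start = 1, end = 2, rate = 6700))
  traj <- simulate_varicosity(ha_params(), initial = ss, input = inp,
                              t_span = c(0, 3),
                              output_times = seq(0, 3, by = 0.01))
  before <- traj$bHT[traj$time_hr <= 1]
  expect_equal(before, rep(ss[["bHT"]], length(before)), tolerance = 1e-6)
  expect_gt(traj$bHT[traj$time_hr == 1.01], ss[["bHT"]] + 1)
})

test_that("simulation is deterministic", {
  a <- run_stimulation(ha_params(), "control", horizon_s = 12)
  b <- run_stimulation(ha_params(), "control", horizon_s = 12)
  expect_identical(a$trace, b$trace)
})
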