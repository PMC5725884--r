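test_that("parameter constructor validates and rejects unknowns", {
  p <- ha_params()
  expect_s3_class(p, "ha_params")
  expect_error(ha_params(not_a_param = 1), "not_a_param")
  expect_error(ha_params(km_htdc = -1), "km_htdc")
  expect_error(ha_params(km_htdc = 0), "km_htdc")
  expect_error(ha_params(g0 = 0), "g0")
  expect_error(ha_params(speed_gstar = -1), "speed_gstar")
  # zero Vmax is allowed (synthesis blockade)
  expect_equal(ha_params(vmax_htdc = 0)$vmax_htdc, 0)
  # a single named list of overrides works too
  expect_equal(ha_params(list(b0 = 4))$b0, 4)
})

test_that("inhibition variants share the tonic operating point", {
  pd <- ha_params()
  ps <- ha_params(inhib_variant = "strong")
  expect_equal(ps$inhib_intercept, 7.645)
  expect_equal(ps$inhib_slope, 10)
  # both lines pass through 0.7 at the tonic G*
  g_tonic <- 0.6945
  expect_equal(pd$inhib_intercept - pd$inhib_slope * g_tonic, 0.7,
               tolerance = 1e-4)
  expect_equal(ps$inhib_intercept - ps$inhib_slope * g_tonic, 0.7,
               tolerance = 1e-12)
  # explicit overrides beat the variant switch
  expect_equal(ha_params(inhib_slope = 3,
                         inhib_variant = "strong")$inhib_slope, 3)
})

test_that("ha_update replaces fields and re-validates", {
  p <- ha_update(ha_params(), b0 = 4, vmax_htdc = 0)
  expect_equal(p$b0, 4)
  expect_equal(p$vmax_htdc, 0)
  expect_equal(p$a13, 432)
  expect_error(ha_update(ha_params(), km_hat = -2), "km_hat")
})

test_that("state constructor enforces names, sign and caps", {
  s <- ha_state(ha_reference_state)
  expect_named(s, STATE_VARS)
  expect_error(ha_state(ha_reference_state[-1]), "cHA")
  bad <- ha_reference_state
  bad[["eHA"]] <- -0.1
  expect_error(ha_state(bad), "non-negative")
  over <- ha_reference_state
  over[["Gstar"]] <- 1.5
  expect_error(ha_state(over, params = ha_params()), "cap")
  expect_silent(ha_state(over))  # cap only checked when params given
})
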