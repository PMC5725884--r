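test_that("half-life experiment is internally consistent", {
  hl <- halflife_result()
  expect_length(hl$censored, 0)
  expect_equal(hl$brain_half_life,
               weighted_half_life(hl$mass_fractions, hl$half_lives))
  expect_equal(sum(hl$mass_fractions), 1)
  # vesicular decay dominates the weighting and is the fastest
  expect_equal(which.max(hl$mass_fractions), c(vHA = 2))
  expect_equal(which.min(hl$half_lives), c(vHA = 2))
  td <- tidy(hl)
  expect_equal(td$half_life_hr, unname(hl$half_lives))
})

test_that("histidine loading: histamine lags histidine and returns slower", {
  ld <- load_result()
  tr <- ld$trace
  expect_equal(tr$histidine_fold[1], 1)
  expect_equal(tr$histamine_fold[1], 1)
  g <- glance(ld)
  expect_gt(g$histamine_peak_hr, g$histidine_peak_hr)
  # histamine stays elevated (>10% over baseline) longer than histidine
  expect_gt(max(tr$time_hr[tr$histamine_fold > 1.1]),
            max(tr$time_hr[tr$histidine_fold > 1.1]))
})

test_that("a load at the normal input rate changes nothing", {
  ld0 <- run_histidine_load(ha_params(), load_rate = 424, horizon_hr = 4)
  expect_equal(ld0$trace$histidine_fold,
               rep(1, nrow(ld0$trace)), tolerance = 1e-6)
  expect_equal(ld0$trace$histamine_fold,
               rep(1, nrow(ld0$trace)), tolerance = 1e-6)
  expect_error(run_histidine_load(ha_params(), window_hr = c(10, 14),
                                  horizon_hr = 12), "window")
})

test_that("dietary response is monotone and sub-proportional", {
  dt <- dietary_result()
  expect_equal(dt$histidine_fold[dt$factor == 1], 1, tolerance = 1e-6)
  expect_equal(dt$histamine_fold[dt$factor == 1], 1, tolerance = 1e-6)
  expect_true(all(diff(dt$histidine_fold) > 0))
  expect_true(all(diff(dt$histamine_fold) > 0))
  expect_lt(dt$histamine_fold[dt$factor > 2], 8 / 3)
  expect_true(all(dt$settled))
})

test_that("control stimulation overshoots then dips below baseline", {
  st <- control_stim()
  g <- glance(st)
  tr <- st$trace
  # positive relative eHA from stimulus onset until ~20 s
  expect_true(all(tr$eHA_rel[tr$time_s > 5 & tr$time_s < 15] > 0))
  expect_gt(g$rebaseline_s, 15)
  expect_lt(g$rebaseline_s, 25)
  expect_lt(tr$eHA_rel[tr$time_s == 30], 0)
})

test_that("autoreceptor blockade raises the peak through the HAT range", {
  st <- control_stim()
  ant <- antagonist_stim()
  expect_gt(glance(ant)$peak_eha, glance(st)$peak_eha)
  # descending limb passes through 8-15 uM, far above the HAT Km
  tr <- ant$trace
  peak_i <- which.max(tr$eHA)
  desc <- tr$eHA[seq(peak_i, nrow(tr))]
  expect_true(any(desc > 8 & desc < 15))
  expect_gt(glance(ant)$baseline_eha, glance(st)$baseline_eha)
})

test_that("transduction peaks are ordered and outlast the eHA transient", {
  st <- control_stim()
  g <- glance(st)
  expect_lte(g$peak_bha_s, g$peak_gstar_s)
  expect_lte(g$peak_gstar_s, g$peak_tstar_s)
  # when eHA first returns to baseline the transduction machinery is
  # still engaged above its resting levels
  tr <- st$trace
  i <- which(tr$time_s == g$rebaseline_s)
  expect_gte(tr$bHA[i], st$baseline[["bHA"]] - 1e-6)
  expect_gt(tr$Gstar[i], st$baseline[["Gstar"]])
  expect_gt(tr$Tstar[i], st$baseline[["Tstar"]])
})

test_that("lowering the receptor pool monotonically raises the peak", {
  # acute blockade: same firing protocol and starting physiology, only
  # the receptor pool reduced (bound receptors clipped to the new total);
  # at b0 = 1 the reduced model has no stable resting state, so acute
  # application is the only well-posed comparison
  ss <- nominal_ss()
  peaks <- vapply(c(10, 4, 1), function(b0) {
    init <- ss
    init[["bHA"]] <- min(init[["bHA"]], b0)
    st <- run_stimulation(ha_params(b0 = b0),
                          stimulation_protocol("control"),
                          initial = init)
    max(st$trace$eHA)
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("polymorphism runs report steady-state percent changes", {
  none <- run_polymorphism(ha_params())
  expect_equal(none$percent_change, 0, tolerance = 1e-8)
  htdc_default <- run_polymorphism(ha_params(), htdc_scale = 0.33)
  htdc_strong <- run_polymorphism(ha_params(inhib_variant = "strong"),
                                  htdc_scale = 0.33)
  expect_lt(htdc_default$percent_change, 0)
  # stronger feedback buffers the same enzyme deficit (homeostasis)
  expect_lt(abs(htdc_strong$percent_change),
            abs(htdc_default$percent_change))
  # catabolic deficit raises eHA; glial inclusion strengthens the effect
  hnmt_both <- run_polymorphism(ha_params(), hnmt_scale = 0.74)
  hnmt_neuronal <- run_polymorphism(ha_params(), hnmt_scale = 0.74,
                                    glial_hnmt = FALSE)
  expect_gt(hnmt_neuronal$percent_change, 0)
  expect_gt(hnmt_both$percent_change, hnmt_neuronal$percent_change)
})

test_that("the oscillation variant rings at ~25 s; nominal does not", {
  osc <- oscillation_result()
  expect_true(osc$oscillatory)
  expect_gte(osc$period_s, 10)
  expect_lte(osc$period_s, 30)
  expect_gte(osc$n_peaks, 3)
  # variant steady state coincides with the nominal one
  expect_equal(as.numeric(osc$stimulation$baseline),
               as.numeric(nominal_ss()), tolerance = 0.01)
  # nominal parameters: response decays without repeated cycling
  flat <- run_oscillation_variant(ha_params(),
                                  multipliers = c(gstar = 1, tstar = 1,
                                                  bha = 1),
                                  inhib_variant = "default")
  expect_false(flat$oscillatory)
})

test_that("the multiplier scan picks the assignment nearest 25 s", {
  sc <- suppressMessages(scan_oscillation_multipliers(ha_params()))
  expect_equal(attr(sc, "best"), c(5, 5, 0.3))
  expect_true(sc$oscillatory[1])
  expect_equal(sc$period_s[1], 25, tolerance = 0.1)
})
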