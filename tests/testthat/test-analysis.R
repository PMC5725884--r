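test_that("half-life readout recovers the closed-form exponential", {
  t <- seq(0, 5, by = 0.01)
  expect_equal(half_life_of_trace(t, exp(-t * log(2))), 1,
               tolerance = 1e-4)
  # invariant under uniform rescaling of the values
  expect_equal(half_life_of_trace(t, 37.5 * exp(-t * log(2))), 1,
               tolerance = 1e-4)
  expect_true(is.na(half_life_of_trace(t, rep(2, length(t)))))
  expect_error(half_life_of_trace(t, c(0, exp(-t[-1]))), "positive")
  expect_error(half_life_of_trace(rev(t), exp(-t)), "increasing")
})

test_that("mass fractions normalise concentration-volume products", {
  conc <- c(2.90, 150.9, 1.39, 0.61)
  vol <- c(0.30, 0.10, 0.20, 0.40)
  mf <- mass_fractions(conc, vol)
  expect_equal(sum(mf), 1)
  expect_equal(100 * mf, c(5.27, 91.5, 1.69, 1.48), tolerance = 2e-3)
  # scale invariance and the equal-concentration identity
  expect_equal(mass_fractions(1000 * conc, vol), mf)
  expect_equal(mass_fractions(rep(3, 4), vol), vol)
  expect_error(mass_fractions(conc, c(0.5, 0.5, 0.2, 0.2)), "sum to 1")
  expect_error(mass_fractions(rep(0, 4), vol), "zero")
})

test_that("weighted half-life is the mass-fraction dot product", {
  mf <- c(0.0527, 0.915, 0.0169, 0.0148)
  mf <- mf / sum(mf)
  hl <- c(1.62, 1.02, 1.31, 1.87)
  expect_equal(weighted_half_life(mf, hl), 1.0685, tolerance = 1e-3)
  expect_equal(weighted_half_life(c(0, 1, 0, 0), hl), 1.02)
  perm <- c(3, 1, 4, 2)
  expect_equal(weighted_half_life(mf[perm], hl[perm]),
               weighted_half_life(mf, hl))
  expect_error(weighted_half_life(mf, c(NA, 1, 1, 1)), "censored")
})

test_that("period detection recovers a sinusoid and rejects monotones", {
  t <- seq(0, 100, by = 0.1)
  p <- detect_period(t, sin(2 * pi * t / 25))
  expect_equal(as.numeric(p), 25, tolerance = 0.1 / 25)
  expect_equal(attr(p, "period_acf"), 25, tolerance = 0.2 / 25)
  expect_true(is.na(detect_period(t, exp(-t / 10))))
  # affine invariance of the detection
  p2 <- detect_period(t, 3 - 0.4 * sin(2 * pi * t / 25))
  expect_equal(as.numeric(p2), as.numeric(p), tolerance = 0.1 / 25)
  expect_error(detect_period(c(0, 1, 3, 4, 5), sin(1:5)), "uniform")
})

test_that("baseline subtraction is an exact involution partner", {
  x <- c(1.39, 2, 0.5)
  expect_equal(baseline_relative(x, 1.39) + 1.39, x)
  expect_equal(baseline_relative(rep(1.39, 5), 1.39), rep(0, 5))
  expect_error(baseline_relative(x, NA), "finite")
})
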