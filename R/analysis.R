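#' Half-life of a decaying trace
#'
#' First time at which the trace falls to half of its initial value,
#' linearly interpolated between grid points. The readout is invariant
#' under uniform rescaling of the values.
#'
#' @param time Time stamps (hours), increasing.
#' @param value Concentrations; `value[1]` must be positive.
#' @return Half-life in hours, or `NA` (censored) when the trace never
#'   reaches half its initial value.
#' @examples
#' t <- seq(0, 5, by = 0.01)
#' half_life_of_trace(t, exp(-t * log(2)))
#' @export
half_life_of_trace <- function(time, value) {
  if (length(time) != length(value) || length(time) < 2) {
    stop("time and value must be equal-length vectors (n >= 2)",
         call. = FALSE)
  }
  if (is.unsorted(time, strictly = TRUE)) {
    stop("time must be strictly increasing", call. = FALSE)
  }
  v0 <- value[1]
  if (!is.finite(v0) || v0 <= 0) {
    stop("initial value must be positive", call. = FALSE)
  }
  target <- v0 / 2
  i <- which(value <= target)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1) return(time[1])
  t0 <- time[i - 1]; t1 <- time[i]
  y0 <- value[i - 1]; y1 <- value[i]
  t0 + (t1 - t0) * (target - y0) / (y1 - y0)
}

#' Mass fractions from concentrations and volume fractions
#'
#' Converts per-compartment concentrations into fractions of total mass,
#' `f_i = c_i v_i / sum_j c_j v_j`. Scale-invariant in the
#' concentrations; the result sums to one.
#'
#' @param concentrations Per-compartment concentrations (uM).
#' @param volume_fractions Compartment volume fractions (must sum to 1).
#' @return Mass fractions (named like the inputs).
#' @examples
#' mass_fractions(ha_reference_state[c("cHA", "vHA", "eHA", "gHA")],
#'                c(0.30, 0.10, 0.20, 0.40))
#' @export
mass_fractions <- function(concentrations, volume_fractions) {
  if (length(concentrations) != length(volume_fractions)) {
    stop("concentrations and volume_fractions must have equal length",
         call. = FALSE)
  }
  if (abs(sum(volume_fractions) - 1) > 1e-8) {
    stop("volume fractions must sum to 1", call. = FALSE)
  }
  if (any(concentrations < 0) || any(volume_fractions < 0)) {
    stop("concentrations and volume fractions must be non-negative",
         call. = FALSE)
  }
  mass <- concentrations * volume_fractions
  if (sum(mass) == 0) stop("all compartment masses are zero", call. = FALSE)
  mass / sum(mass)
}

#' Mass-fraction-weighted half-life
#'
#' Whole-tissue half-life as the dot product of per-compartment mass
#' fractions and half-lives.
#'
#' @param mass_fractions Fractions summing to 1.
#' @param half_lives Per-compartment half-lives (hours); `NA` (censored)
#'   entries are an error.
#' @return Weighted half-life in hours.
#' @examples
#' weighted_half_life(c(.0527, .915, .0169, .0148),
#'                    c(1.62, 1.02, 1.31, 1.87))
#' @export
weighted_half_life <- function(mass_fractions, half_lives) {
  if (length(mass_fractions) != length(half_lives)) {
    stop("mass_fractions and half_lives must have equal length",
         call. = FALSE)
  }
  if (abs(sum(mass_fractions) - 1) > 1e-6) {
    stop("mass fractions must sum to 1", call. = FALSE)
  }
  if (any(is.na(half_lives))) {
    stop("cannot weight censored half-lives", call. = FALSE)
  }
  sum(mass_fractions * half_lives)
}

#' Dominant oscillation period of a uniformly sampled trace
#'
#' Detects strict local maxima whose prominence (height above the larger
#' of the two adjacent minima) exceeds a noise floor expressed as a
#' fraction of the trace range, and returns the median peak-to-peak
#' interval. Requires at least `min_cycles` qualifying peaks; otherwise
#' returns `NA` (no sustained oscillation). The prominence criterion is
#' relative to the trace range, so the result is invariant under affine
#' transforms of the values. An autocorrelation estimate of the period is
#' attached as a cross-check.
#'
#' @param time Uniformly spaced time stamps (seconds).
#' @param value Trace values.
#' @param min_cycles Minimum number of qualifying peaks.
#' @param noise_floor Prominence threshold as a fraction of the trace
#'   range.
#' @return Period in the units of `time`, or `NA`; attributes `n_peaks`,
#'   `peak_times`, `period_acf`.
#' @examples
#' t <- seq(0, 100, by = 0.1)
#' detect_period(t, sin(2 * pi * t / 25))
#' @export
detect_period <- function(time, value, min_cycles = 3,
                          noise_floor = 0.02) {
  n <- length(time)
  if (n != length(value) || n < 5) {
    stop("time and value must be equal-length vectors (n >= 5)",
         call. = FALSE)
  }
  dt <- diff(time)
  if (any(abs(dt - dt[1]) > 1e-6 * max(dt[1], 1e-12))) {
    stop("trace must be uniformly sampled", call. = FALSE)
  }
  rng <- diff(range(value))
  if (rng == 0) {
    return(structure(NA_real_, n_peaks = 0L, peak_times = numeric(),
                     period_acf = NA_real_))
  }
  # ">=" on the right side so a peak that samples as a two-point plateau
  # (period not a multiple of the grid step) is still caught, once
  is_max <- which(value[2:(n - 1)] > value[1:(n - 2)] &
                    value[2:(n - 1)] >= value[3:n]) + 1L
  is_min <- which(value[2:(n - 1)] < value[1:(n - 2)] &
                    value[2:(n - 1)] <= value[3:n]) + 1L
  # prominence relative to adjacent minima (trace ends count as minima)
  keep <- vapply(is_max, function(i) {
    left <- c(1L, is_min[is_min < i])
    right <- c(is_min[is_min > i], n)
    lo <- max(min(value[left[length(left)]:i]),
              min(value[i:right[1]]))
    (value[i] - lo) >= noise_floor * rng
  }, logical(1))
  peaks <- is_max[keep]
  if (length(peaks) < min_cycles) {
    return(structure(NA_real_, n_peaks = length(peaks),
                     peak_times = time[peaks], period_acf = NA_real_))
  }
  period <- stats::median(diff(time[peaks]))
  # autocorrelation cross-check: first local maximum beyond lag zero
  ac <- stats::acf(value - mean(value), lag.max = n - 2, plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  la <- length(ac)
  cand <- which(ac[2:(la - 1)] > ac[1:(la - 2)] &
                  ac[2:(la - 1)] >= ac[3:la]) + 1L
  period_acf <- if (length(cand) > 0) {
    (cand[which.max(ac[cand])] - 1) * dt[1]
  } else NA_real_
  structure(period, n_peaks = length(peaks), peak_times = time[peaks],
            period_acf = period_acf)
}

#' Baseline-relative trace
#'
#' Subtracts a baseline, the convention of voltammetry measurements which
#' report changes from baseline rather than absolute concentrations.
#' Exact inverse of adding the baseline back.
#'
#' @param value Trace values (uM).
#' @param baseline Baseline value (uM).
#' @return `value - baseline`.
#' @export
baseline_relative <- function(value, baseline) {
  if (!is.finite(baseline)) stop("baseline must be finite", call. = FALSE)
  value - baseline
}
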