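#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for model results
#'
#' Every experiment result has a `tidy()` method returning its main
#' table (one row per observation) and a `glance()` method returning a
#' one-row summary, in the style of broom.
#'
#' @param x A result object.
#' @param ... Unused.
#' @name histasim-tidiers
NULL

#' @rdname histasim-tidiers
#' @export
tidy.ha_steady_state <- function(x, ...) {
  tibble::tibble(variable = names(x), value = as.numeric(x))
}

#' @rdname histasim-tidiers
#' @export
glance.ha_steady_state <- function(x, ...) {
  tibble::tibble(residual = attr(x, "residual"),
                 polished = attr(x, "polished"),
                 firing_rate = attr(x, "firing_rate"),
                 ht_in = attr(x, "ht_in"))
}

#' @rdname histasim-tidiers
#' @export
tidy.ha_trajectory <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"time_hr",
                      names_to = "variable", values_to = "value")
}

#' @rdname histasim-tidiers
#' @export
tidy.ha_halflife <- function(x, ...) {
  tibble::tibble(compartment = names(x$half_lives),
                 concentration = as.numeric(
                   x$steady_state[names(x$half_lives)]),
                 volume_fraction = as.numeric(x$volume_fractions),
                 mass_fraction = as.numeric(x$mass_fractions),
                 half_life_hr = as.numeric(x$half_lives))
}

#' @rdname histasim-tidiers
#' @export
glance.ha_halflife <- function(x, ...) {
  tibble::tibble(brain_half_life_hr = x$brain_half_life,
                 n_censored = length(x$censored))
}

#' @rdname histasim-tidiers
#' @export
tidy.ha_load <- function(x, ...) x$trace

#' @rdname histasim-tidiers
#' @export
glance.ha_load <- function(x, ...) {
  tr <- x$trace
  tibble::tibble(
    histidine_peak_fold = max(tr$histidine_fold),
    histidine_peak_hr = tr$time_hr[which.max(tr$histidine_fold)],
    histamine_peak_fold = max(tr$histamine_fold),
    histamine_peak_hr = tr$time_hr[which.max(tr$histamine_fold)]
  )
}

#' @rdname histasim-tidiers
#' @export
tidy.ha_dietary <- function(x, ...) {
  tibble::as_tibble(x)[c("factor", "histidine_fold", "histamine_fold")]
}

#' @rdname histasim-tidiers
#' @export
tidy.ha_stim <- function(x, ...) {
  tidyr::pivot_longer(x$trace, -"time_s", names_to = "variable",
                      values_to = "value")
}

#' @rdname histasim-tidiers
#' @export
glance.ha_stim <- function(x, ...) {
  tr <- x$trace
  peak_at <- function(v) tr$time_s[which.max(tr[[v]])]
  after <- tr$time_s > 9  # stimulus over
  below <- which(tr$eHA_rel[after] < 0)
  tibble::tibble(
    protocol = x$protocol$name,
    baseline_eha = x$baseline[["eHA"]],
    peak_eha = max(tr$eHA),
    peak_eha_s = peak_at("eHA"),
    rebaseline_s = if (length(below) > 0) {
      tr$time_s[after][below[1]]
    } else NA_real_,
    eha_rel_end = tr$eHA_rel[nrow(tr)],
    peak_bha_s = peak_at("bHA"),
    peak_gstar_s = peak_at("Gstar"),
    peak_tstar_s = peak_at("Tstar")
  )
}

#' @rdname histasim-tidiers
#' @export
tidy.ha_oscillation <- function(x, ...) tidy(x$stimulation)

#' @rdname histasim-tidiers
#' @export
glance.ha_oscillation <- function(x, ...) {
  tibble::tibble(oscillatory = x$oscillatory, period_s = x$period_s,
                 period_acf_s = x$period_acf_s, n_peaks = x$n_peaks,
                 decay_ratio = x$decay_ratio,
                 inhib_variant = x$inhib_variant)
}

#' @rdname histasim-tidiers
#' @export
glance.ha_polymorphism <- function(x, ...) {
  tibble::tibble(htdc_scale = x$htdc_scale, hnmt_scale = x$hnmt_scale,
                 glial_hnmt = x$glial_hnmt,
                 eha_nominal = x$eha_nominal,
                 eha_perturbed = x$eha_perturbed,
                 percent_change = x$percent_change)
}
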