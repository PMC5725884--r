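#' Synthesis-blockade half-life experiment
#'
#' From the nominal steady state, the synthesis capacity (`vmax_htdc`) is
#' set to zero at `t = 0` — the in-silico analogue of a decarboxylase
#' inhibitor — and the decay of histamine in the four compartments
#' (cytosol, vesicles, extracellular space, glia) is followed. Each
#' compartment's half-life is the first, linearly interpolated, crossing
#' of half its initial concentration; the whole-brain half-life is the
#' mass-fraction-weighted average, with mass fractions computed from the
#' steady-state concentrations and the compartment volume fractions.
#'
#' @param params An [ha_params()] object.
#' @param horizon_hr Integration horizon (hours).
#' @param dt_hr Output grid step; half-lives are interpolated on this
#'   grid.
#' @param volume_fractions Volume fractions of (cHA, vHA, eHA, gHA);
#'   must sum to 1.
#' @return An object of class `ha_halflife` with elements `half_lives`,
#'   `mass_fractions`, `brain_half_life` (`NA` if any compartment is
#'   censored), `censored`, `steady_state` and `trajectory`.
#' @examples
#' \donttest{
#' hl <- run_half_life(ha_params())
#' glance(hl)
#' }
#' @export
run_half_life <- function(params = ha_params(), horizon_hr = 12,
                          dt_hr = 0.005,
                          volume_fractions = c(cHA = 0.30, vHA = 0.10,
                                               eHA = 0.20, gHA = 0.40)) {
  comps <- c("cHA", "vHA", "eHA", "gHA")
  stopifnot(setequal(names(volume_fractions), comps))
  volume_fractions <- volume_fractions[comps]
  ss <- find_steady_state(params)
  blocked <- ha_update(params, vmax_htdc = 0)
  traj <- simulate_varicosity(
    blocked, initial = ss, t_span = c(0, horizon_hr),
    output_times = seq(0, horizon_hr, by = dt_hr)
  )
  hl <- vapply(comps, function(v) {
    half_life_of_trace(traj$time_hr, traj[[v]])
  }, numeric(1))
  censored <- comps[is.na(hl)]
  mf <- mass_fractions(as.numeric(ss[comps]), volume_fractions)
  names(mf) <- comps
  brain <- if (length(censored) > 0) NA_real_ else
    weighted_half_life(mf, hl)
  structure(list(half_lives = hl, mass_fractions = mf,
                 brain_half_life = brain, censored = censored,
                 volume_fractions = volume_fractions,
                 steady_state = ss, trajectory = traj),
            class = "ha_halflife")
}

#' @export
print.ha_halflife <- function(x, ...) {
  cat("<ha_halflife> synthesis-blockade decay\n")
  print(tidy(x))
  cat(sprintf("brain half-life: %s h\n",
              if (is.na(x$brain_half_life)) "censored"
              else format(round(x$brain_half_life, 3))))
  invisible(x)
}

weighted_histidine <- function(traj, blood_fraction = 0.2) {
  blood_fraction * traj$bHT +
    (1 - blood_fraction) * (traj$cHT + traj$HTpool) / 2
}

weighted_histamine <- function(traj, fractions = c(cHA = 0.4, vHA = 0.1,
                                                   eHA = 0.2, gHA = 0.3)) {
  as.numeric(as.matrix(traj[names(fractions)]) %*% fractions)
}

#' Histidine loading experiment
#'
#' Emulates a histidine bolus: the dietary input is raised from its
#' normal 424 uM/hr to `load_rate` over `window_hr`, and the tissue
#' responses are summarised as fold changes over baseline of (i) a
#' weighted histidine index — blood plus extracellular space
#' (`blood_fraction`, default 20%) against cellular histidine (the mean
#' of cytosolic histidine and the histidine pool, 80%) — and (ii) the
#' volume-weighted average histamine across the four compartments
#' (fractions 0.4, 0.1, 0.2, 0.3 for cytosol, vesicles, extracellular
#' space, glia). Histamine responds later and relaxes more slowly than
#' histidine because it must first be synthesised.
#'
#' @param params An [ha_params()] object.
#' @param load_rate Input rate during the load (uM/hr).
#' @param window_hr Length-2 load window (hours).
#' @param horizon_hr Total simulated time (hours).
#' @param dt_hr Output grid step.
#' @param blood_fraction Weight of blood histidine in the histidine
#'   index.
#' @param ha_fractions Volume fractions for the histamine average.
#' @return An object of class `ha_load`: trace tibble (`time_hr`,
#'   `histidine_fold`, `histamine_fold`) plus the underlying trajectory.
#' @examples
#' \donttest{
#' ld <- run_histidine_load(ha_params())
#' glance(ld)
#' }
#' @export
run_histidine_load <- function(params = ha_params(), load_rate = 6700,
                               window_hr = c(1, 2), horizon_hr = 12,
                               dt_hr = 0.01, blood_fraction = 0.2,
                               ha_fractions = c(cHA = 0.4, vHA = 0.1,
                                                eHA = 0.2, gHA = 0.3)) {
  if (length(window_hr) != 2 || window_hr[2] <= window_hr[1] ||
      window_hr[1] < 0 || window_hr[2] > horizon_hr) {
    stop("load window must lie within [0, horizon_hr]", call. = FALSE)
  }
  ss <- find_steady_state(params)
  inp <- input_protocol(
    data.frame(start = window_hr[1], end = window_hr[2], rate = load_rate),
    default_rate = params$ht_in_base
  )
  traj <- simulate_varicosity(params, initial = ss, input = inp,
                              t_span = c(0, horizon_hr),
                              output_times = seq(0, horizon_hr, by = dt_hr))
  ht <- weighted_histidine(traj, blood_fraction)
  ha <- weighted_histamine(traj, ha_fractions)
  trace <- tibble::tibble(time_hr = traj$time_hr,
                          histidine_fold = ht / ht[1],
                          histamine_fold = ha / ha[1])
  structure(list(trace = trace, trajectory = traj, steady_state = ss,
                 load_rate = load_rate, window_hr = window_hr),
            class = "ha_load")
}

#' @export
print.ha_load <- function(x, ...) {
  cat(sprintf("<ha_load> HT_in %g uM/hr on [%g, %g] hr\n",
              x$load_rate, x$window_hr[1], x$window_hr[2]))
  print(glance(x))
  invisible(x)
}

#' Dietary histidine intervention
#'
#' Scales the dietary histidine input by each `factor` (1/3 and 8/3
#' emulate deficient and excess diets) and reports the fold change, after
#' two weeks, of the same weighted histidine and histamine indices used
#' in [run_histidine_load()]. The reported value is the root-polished
#' steady state under the scaled input; the two-week integration from the
#' nominal state is used to confirm settling, and both values are
#' retained when they differ by more than 0.5%.
#'
#' @param params An [ha_params()] object.
#' @param factors Multipliers on the normal dietary input.
#' @param duration_hr Integration horizon used for the settling check.
#' @param blood_fraction,ha_fractions As in [run_histidine_load()].
#' @return An object of class `ha_dietary`: a tibble with one row per
#'   factor (`factor`, `histidine_fold`, `histamine_fold`, trajectory
#'   end-point folds, `settled`, `drift`).
#' @examples
#' \donttest{
#' run_dietary(ha_params(), factors = c(1/3, 1, 8/3))
#' }
#' @export
run_dietary <- function(params = ha_params(), factors = c(1 / 3, 1, 8 / 3),
                        duration_hr = 336, blood_fraction = 0.2,
                        ha_fractions = c(cHA = 0.4, vHA = 0.1,
                                         eHA = 0.2, gHA = 0.3)) {
  stopifnot(all(factors > 0))
  ss0 <- find_steady_state(params)
  base <- tibble::as_tibble(as.data.frame(t(as.numeric(ss0))))
  names(base) <- STATE_VARS
  ht0 <- weighted_histidine(base, blood_fraction)
  ha0 <- weighted_histamine(base, ha_fractions)
  rows <- purrr::map_dfr(factors, function(f) {
    ht_in <- f * params$ht_in_base
    ss <- find_steady_state(params, ht_in = ht_in)
    p2 <- ha_update(params, ht_in_base = ht_in)
    traj <- simulate_varicosity(p2, initial = ss0,
                                t_span = c(0, duration_hr),
                                output_times = c(0, duration_hr / 2,
                                                 duration_hr))
    yend <- as.numeric(traj[nrow(traj), STATE_VARS])
    names(yend) <- STATE_VARS
    drift <- max(abs(varicosity_rhs(duration_hr, yend, p2)))
    endt <- traj[nrow(traj), ]
    folds <- c(weighted_histidine(endt, blood_fraction) / ht0,
               weighted_histamine(endt, ha_fractions) / ha0)
    sst <- tibble::as_tibble(as.data.frame(t(as.numeric(ss))))
    names(sst) <- STATE_VARS
    folds_ss <- c(weighted_histidine(sst, blood_fraction) / ht0,
                  weighted_histamine(sst, ha_fractions) / ha0)
    settled <- max(abs(folds - folds_ss) / folds_ss) <= 0.005
    if (!settled) {
      warning(sprintf(
        "dietary run (factor %.3g) not fully settled after %g h (drift %.2e)",
        f, duration_hr, drift), call. = FALSE)
    }
    tibble::tibble(factor = f,
                   histidine_fold = folds_ss[1],
                   histamine_fold = folds_ss[2],
                   histidine_fold_end = folds[1],
                   histamine_fold_end = folds[2],
                   settled = settled, drift = drift)
  })
  structure(rows, class = c("ha_dietary", class(rows)),
            baseline = ss0)
}

#' Stimulation firing protocols
#'
#' The two stimulation paradigms on a seconds timescale: `control` raises
#' firing from 5 to 25 sp/s on `[5, 8)` s and 14 sp/s on `[8, 9)` s;
#' `antagonist` models an H3 blocker by reducing the autoreceptor total
#' `b0` from 10 to 4 together with slightly lower drive (22 then
#' 11 sp/s over the same windows).
#'
#' @param protocol `"control"` or `"antagonist"`.
#' @param horizon_s Run length in seconds (must exceed the last
#'   breakpoint).
#' @return A list with the [firing_protocol()], the `b0` override (or
#'   `NA`), the protocol name and horizon.
#' @export
stimulation_protocol <- function(protocol = c("control", "antagonist"),
                                 horizon_s = 30) {
  protocol <- match.arg(protocol)
  segs <- switch(protocol,
    control = data.frame(start = c(5, 8), end = c(8, 9), rate = c(25, 14)),
    antagonist = data.frame(start = c(5, 8), end = c(8, 9),
                            rate = c(22, 11))
  )
  if (horizon_s <= max(segs$end)) {
    stop("horizon_s must exceed the last protocol breakpoint",
         call. = FALSE)
  }
  list(firing = firing_protocol(segs, default_rate = 5,
                                units = "seconds"),
       b0 = if (protocol == "antagonist") 4 else NA_real_,
       name = protocol, horizon_s = horizon_s)
}

#' Stimulation experiment
#'
#' Starts from the steady state of the (possibly antagonist-modified)
#' parameterisation, applies a stimulation firing protocol and returns
#' the extracellular histamine response, absolute and relative to its
#' baseline, together with the transduction variables, on a 10 Hz grid —
#' the sampling convention of fast-scan voltammetry.
#'
#' @param params An [ha_params()] object.
#' @param protocol `"control"`, `"antagonist"`, or a list from
#'   [stimulation_protocol()].
#' @param horizon_s Run length (seconds).
#' @param hz Output sampling rate.
#' @param initial Optional starting state, for acute perturbations whose
#'   new parameterisation has not (or cannot) re-equilibrate — e.g. a
#'   receptor pool reduced below its resting occupancy. Defaults to the
#'   steady state of the run's parameterisation; the baseline for the
#'   relative trace is the starting state's `eHA`.
#' @return An object of class `ha_stim`: trace tibble (`time_s`, the ten
#'   state variables, `eHA_rel`), the baseline state, and the protocol.
#' @examples
#' \donttest{
#' st <- run_stimulation(ha_params(), "control")
#' glance(st)
#' }
#' @export
run_stimulation <- function(params = ha_params(), protocol = "control",
                            horizon_s = 30, hz = 10, initial = NULL) {
  spec <- if (is.character(protocol)) {
    stimulation_protocol(protocol, horizon_s)
  } else protocol
  p <- if (!is.na(spec$b0)) ha_update(params, b0 = spec$b0) else params
  baseline <- if (is.null(initial)) {
    find_steady_state(p)
  } else ha_state(initial, params = p)
  out_s <- seq(0, spec$horizon_s, by = 1 / hz)
  traj <- simulate_varicosity(p, initial = baseline, firing = spec$firing,
                              t_span = c(0, spec$horizon_s / 3600),
                              output_times = out_s / 3600)
  trace <- dplyr::mutate(
    tibble::as_tibble(traj),
    time_s = .data$time_hr * 3600,
    eHA_rel = baseline_relative(.data$eHA, baseline[["eHA"]]),
    .before = 1
  )
  trace$time_hr <- NULL
  structure(list(trace = trace, baseline = baseline, protocol = spec,
                 params = p),
            class = "ha_stim")
}

#' @export
print.ha_stim <- function(x, ...) {
  cat(sprintf("<ha_stim> %s stimulation, %g s at %g points\n",
              x$protocol$name, x$protocol$horizon_s, nrow(x$trace)))
  print(glance(x))
  invisible(x)
}

#' Enzyme polymorphism experiment
#'
#' Rescales the maximal activity of the synthesis enzyme (HTDC) and/or
#' the catabolic enzyme (HNMT), recomputes the steady state, and reports
#' the percent change in extracellular histamine relative to the
#' unperturbed steady state of the same parameterisation. A 67% loss of
#' HTDC activity corresponds to `htdc_scale = 0.33`; a 26% loss of HNMT
#' activity to `hnmt_scale = 0.74`. By default the HNMT scaling applies
#' to both the neuronal and the glial enzyme (one gene product);
#' `glial_hnmt = FALSE` restricts it to the neuronal enzyme.
#'
#' @param params An [ha_params()] object (use
#'   `ha_params(inhib_variant = "strong")` for the strongly homeostatic
#'   feedback variant).
#' @param htdc_scale,hnmt_scale Multipliers on the nominal Vmax values.
#' @param glial_hnmt Apply `hnmt_scale` to the glial enzyme too?
#' @return An object of class `ha_polymorphism` with `eha_nominal`,
#'   `eha_perturbed` and `percent_change`
#'   (`100 * (new - nominal) / nominal`).
#' @examples
#' \donttest{
#' run_polymorphism(ha_params(), htdc_scale = 0.33)$percent_change
#' }
#' @export
run_polymorphism <- function(params = ha_params(), htdc_scale = 1,
                             hnmt_scale = 1, glial_hnmt = TRUE) {
  stopifnot(htdc_scale > 0, hnmt_scale > 0)
  ss0 <- find_steady_state(params)
  p2 <- ha_update(params,
                  vmax_htdc = params$vmax_htdc * htdc_scale,
                  vmax_hnmt = params$vmax_hnmt * hnmt_scale,
                  vmax_hnmt_g = if (glial_hnmt) {
                    params$vmax_hnmt_g * hnmt_scale
                  } else params$vmax_hnmt_g)
  ss1 <- find_steady_state(p2)
  structure(list(
    eha_nominal = ss0[["eHA"]], eha_perturbed = ss1[["eHA"]],
    percent_change = 100 * (ss1[["eHA"]] - ss0[["eHA"]]) / ss0[["eHA"]],
    htdc_scale = htdc_scale, hnmt_scale = hnmt_scale,
    glial_hnmt = glial_hnmt,
    steady_state_nominal = ss0, steady_state_perturbed = ss1
  ), class = "ha_polymorphism")
}

#' @export
print.ha_polymorphism <- function(x, ...) {
  cat(sprintf(
    "<ha_polymorphism> HTDC x%g, HNMT x%g (%s): eHA %.3f -> %.3f uM (%+.1f%%)\n",
    x$htdc_scale, x$hnmt_scale,
    if (x$glial_hnmt) "neuronal + glial" else "neuronal only",
    x$eha_nominal, x$eha_perturbed, x$percent_change))
  invisible(x)
}

#' Oscillatory autoreceptor variant
#'
#' Switches to the strong inhibition line (`7.645 - 10 G*`, applied to
#' both release and synthesis), multiplies the three transduction
#' right-hand sides by the given factors, and runs the control
#' stimulation over `horizon_s`. Because the multipliers rescale
#' equations whose right-hand sides vanish at equilibrium, the steady
#' state is unchanged; the feedback loop, however, rings: extracellular
#' histamine oscillates for several cycles after the stimulus. The
#' dominant period of the post-stimulation trace is estimated with
#' [detect_period()]; if fewer than `min_cycles` qualifying peaks are
#' found the result is flagged damped, with the amplitude decay ratio
#' per cycle reported when at least two peaks exist.
#'
#' The default assignment — G-protein and RGS equations x5, receptor
#' binding x0.3 — is the one selected by
#' [scan_oscillation_multipliers()] as producing sustained cycles with
#' period closest to 25 s.
#'
#' @param params An [ha_params()] object (its inhibition line is
#'   overridden per `inhib_variant`).
#' @param multipliers Named multipliers `c(gstar, tstar, bha)` for the
#'   three transduction equations.
#' @param inhib_variant Inhibition line to apply.
#' @param horizon_s Run length (seconds).
#' @param hz Output sampling rate.
#' @param min_cycles Peaks required to call the response oscillatory.
#' @param analysis_from_s Start of the period-analysis window (after the
#'   stimulus).
#' @return An object of class `ha_oscillation` with the stimulation
#'   result, `period_s`, `oscillatory`, `n_peaks`, `peak_times_s` and
#'   `decay_ratio`.
#' @examples
#' \donttest{
#' osc <- run_oscillation_variant(ha_params())
#' glance(osc)
#' }
#' @export
run_oscillation_variant <- function(params = ha_params(),
                                    multipliers = c(gstar = 5, tstar = 5,
                                                    bha = 0.3),
                                    inhib_variant = c("strong", "default"),
                                    horizon_s = 100, hz = 10,
                                    min_cycles = 3,
                                    analysis_from_s = 10) {
  inhib_variant <- match.arg(inhib_variant)
  stopifnot(setequal(names(multipliers), c("gstar", "tstar", "bha")),
            all(multipliers > 0))
  line <- if (inhib_variant == "strong") {
    c(intercept = 7.645, slope = 10)
  } else c(intercept = 2.4015, slope = 2.45)
  p <- ha_update(params,
                 inhib_intercept = unname(line["intercept"]),
                 inhib_slope = unname(line["slope"]),
                 speed_gstar = unname(multipliers[["gstar"]]),
                 speed_tstar = unname(multipliers[["tstar"]]),
                 speed_bha = unname(multipliers[["bha"]]))
  stim <- run_stimulation(p, "control", horizon_s = horizon_s, hz = hz)
  sel <- stim$trace$time_s >= analysis_from_s
  period <- detect_period(stim$trace$time_s[sel],
                          stim$trace$eHA[sel], min_cycles = min_cycles)
  pk <- attr(period, "peak_times")
  amp <- stim$trace$eHA[match(round(pk, 10),
                              round(stim$trace$time_s, 10))] -
    stim$baseline[["eHA"]]
  decay <- if (length(amp) >= 2 && all(amp > 0)) {
    stats::median(amp[-1] / amp[-length(amp)])
  } else NA_real_
  structure(list(stimulation = stim,
                 period_s = as.numeric(period),
                 oscillatory = !is.na(period),
                 n_peaks = attr(period, "n_peaks"),
                 peak_times_s = pk,
                 period_acf_s = attr(period, "period_acf"),
                 decay_ratio = decay,
                 multipliers = multipliers,
                 inhib_variant = inhib_variant),
            class = "ha_oscillation")
}

#' @export
print.ha_oscillation <- function(x, ...) {
  cat(sprintf(
    "<ha_oscillation> %s inhibition, multipliers (%g, %g, %g): %s\n",
    x$inhib_variant, x$multipliers[["gstar"]], x$multipliers[["tstar"]],
    x$multipliers[["bha"]],
    if (x$oscillatory) {
      sprintf("period %.2f s over %d peaks (amplitude ratio %.2f/cycle)",
              x$period_s, x$n_peaks, x$decay_ratio)
    } else sprintf("damped (%d peak(s))", x$n_peaks)))
  invisible(x)
}

#' Scan speed-multiplier assignments for oscillations
#'
#' Evaluates each candidate assignment of the speed multipliers to the
#' three transduction equations under the strong inhibition line and
#' ranks them by closeness of the detected period to `target_period_s`.
#' By default the three distinct assignments of `{5, 5, 0.3}` are tried.
#'
#' @param params An [ha_params()] object.
#' @param candidates List of named multiplier vectors.
#' @param target_period_s Period to rank against (seconds).
#' @param ... Passed to [run_oscillation_variant()].
#' @return A tibble with one row per assignment (`gstar`, `tstar`,
#'   `bha`, `oscillatory`, `period_s`, `n_peaks`), sorted by distance to
#'   the target; attribute `best` holds the winning assignment.
#' @examples
#' \donttest{
#' scan_oscillation_multipliers(ha_params())
#' }
#' @export
scan_oscillation_multipliers <- function(params = ha_params(),
                                         candidates = list(
                                           c(gstar = 5, tstar = 5, bha = 0.3),
                                           c(gstar = 5, tstar = 0.3, bha = 5),
                                           c(gstar = 0.3, tstar = 5, bha = 5)
                                         ),
                                         target_period_s = 25, ...) {
  rows <- purrr::map_dfr(candidates, function(m) {
    r <- run_oscillation_variant(params, multipliers = m, ...)
    tibble::tibble(gstar = m[["gstar"]], tstar = m[["tstar"]],
                   bha = m[["bha"]], oscillatory = r$oscillatory,
                   period_s = r$period_s, n_peaks = r$n_peaks,
                   decay_ratio = r$decay_ratio)
  })
  rows <- dplyr::arrange(
    rows,
    dplyr::desc(.data$oscillatory),
    dplyr::coalesce(abs(.data$period_s - target_period_s), Inf)
  )
  attr(rows, "best") <- as.numeric(rows[1, c("gstar", "tstar", "bha")])
  rows
}
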