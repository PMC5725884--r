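#' Autoreceptor inhibition factor
#'
#' The active G-protein subunit suppresses both vesicular release and
#' synthesis through the linear factor
#' `inhib(G*) = intercept - slope * G*`, clamped at zero so neither flux
#' can become negative when `G*` exceeds `intercept/slope`. Tonically
#' (at `G* = 0.6945`) the factor equals 0.7 for both the default
#' (2.4015, 2.45) and the strong (7.645, 10) parameterisation: the two
#' lines intersect at the operating point, so switching variants leaves
#' the steady state unchanged while altering feedback strength.
#'
#' @param Gstar Active G-protein level(s), `>= 0` (arbitrary units).
#' @param params An [ha_params()] object.
#' @return The dimensionless inhibition factor, `>= 0`.
#' @examples
#' inhib(0.6945, ha_params())
#' inhib(0.6945, ha_params(inhib_variant = "strong"))
#' @export
inhib <- function(Gstar, params = ha_params()) {
  if (any(!is.finite(Gstar)) || any(Gstar < 0)) {
    stop("Gstar must be finite and >= 0", call. = FALSE)
  }
  pmax(0, params$inhib_intercept - params$inhib_slope * Gstar)
}

mm <- function(vmax, km, s) vmax * s / (km + s)

# All flux terms at one state, as a named numeric vector (uM/hr).
# `fire` is the firing rate (sp/s), `ht_in` the dietary input (uM/hr).
# The ODE right-hand side is assembled *only* from this vector, so the
# mass-balance audit in flux_balance() is exact by construction.
flux_terms <- function(y, p, fire, ht_in) {
  inh <- p$inhib_intercept - p$inhib_slope * y[["Gstar"]]
  clamped <- inh < 0
  if (clamped) inh <- 0
  fl <- c(
    v_htl       = mm(p$vmax_htl, p$km_htl, y[["bHT"]]),
    v_htdc      = mm(p$vmax_htdc, p$km_htdc, y[["cHT"]]) * inh,
    v_hnmt      = mm(p$vmax_hnmt, p$km_hnmt, y[["cHA"]]),
    v_hnmt_g    = mm(p$vmax_hnmt_g, p$km_hnmt_g, y[["gHA"]]),
    v_mat       = mm(p$vmax_mat, p$km_mat, y[["cHA"]]) -
                  p$mat_backleak * y[["vHA"]],
    v_hat       = mm(p$vmax_hat, p$km_hat, y[["eHA"]]),
    v_hat_g     = mm(p$vmax_hat_g, p$km_hat_g, y[["eHA"]]),
    release     = p$a2 * inh * fire * y[["vHA"]],
    leak_cyt    = p$a1 * y[["cHA"]],
    leak_glia   = p$a3 * y[["gHA"]],
    removal     = p$a4 * y[["eHA"]],
    ht_in       = ht_in,
    bht_stab    = p$a5 * (y[["bHT"]] - p$bht_setpoint),
    cht_to_pool = p$a6 * y[["cHT"]],
    pool_to_cht = p$a7 * y[["HTpool"]],
    pool_other  = p$a8 * y[["HTpool"]],
    gstar_gain  = p$a9 * y[["bHA"]]^2 * (p$g0 - y[["Gstar"]]),
    gstar_loss  = p$a10 * y[["Tstar"]] * y[["Gstar"]],
    tstar_gain  = p$a11 * y[["Gstar"]]^2 * (p$t0 - y[["Tstar"]]),
    tstar_loss  = p$a12 * y[["Tstar"]],
    bha_gain    = p$a13 * y[["eHA"]] * (p$b0 - y[["bHA"]]),
    bha_loss    = p$a14 * y[["bHA"]]
  )
  attr(fl, "inhib") <- inh
  attr(fl, "inhib_clamped") <- clamped
  fl
}

# Assemble d(state)/dt from the flux vector. Signs follow mass balance;
# the transduction derivatives carry the speed multipliers.
rhs_from_fluxes <- function(fl, p) {
  c(
    cHA    = fl[["v_htdc"]] - fl[["v_mat"]] - fl[["v_hnmt"]] -
             fl[["leak_cyt"]] + fl[["v_hat"]],
    vHA    = fl[["v_mat"]] - fl[["release"]],
    eHA    = fl[["release"]] - fl[["v_hat"]] - fl[["v_hat_g"]] +
             fl[["leak_cyt"]] + fl[["leak_glia"]] - fl[["removal"]],
    gHA    = fl[["v_hat_g"]] - fl[["leak_glia"]] - fl[["v_hnmt_g"]],
    bHT    = fl[["ht_in"]] - fl[["v_htl"]] - fl[["bht_stab"]],
    cHT    = fl[["v_htl"]] - fl[["v_htdc"]] - fl[["cht_to_pool"]] +
             fl[["pool_to_cht"]],
    HTpool = fl[["cht_to_pool"]] - fl[["pool_to_cht"]] - fl[["pool_other"]],
    Gstar  = p$speed_gstar * (fl[["gstar_gain"]] - fl[["gstar_loss"]]),
    Tstar  = p$speed_tstar * (fl[["tstar_gain"]] - fl[["tstar_loss"]]),
    bHA    = p$speed_bha * (fl[["bha_gain"]] - fl[["bha_loss"]])
  )
}

#' Reaction velocities at a state
#'
#' Evaluates every flux of the model at one state: the Michaelis--Menten
#' velocities (histidine transport `v_htl`, synthesis `v_htdc` including
#' the autoreceptor inhibition factor, neuronal and glial catabolism
#' `v_hnmt`/`v_hnmt_g`, net vesicular packaging `v_mat` which may be
#' negative when the backleak dominates, reuptake `v_hat`/`v_hat_g`),
#' the firing-driven release, and all linear leak, removal, exchange and
#' transduction terms.
#'
#' @param state Named state vector (see [ha_state()]).
#' @param params An [ha_params()] object.
#' @param firing_rate Firing rate in sp/s.
#' @param ht_in Dietary histidine input in uM/hr.
#' @return A tibble with columns `term` and `rate` (uM/hr), plus
#'   attributes `inhib` (the inhibition factor used) and `inhib_clamped`.
#' @examples
#' reaction_velocities(ha_reference_state, ha_params())
#' @export
reaction_velocities <- function(state, params = ha_params(),
                                firing_rate = params$fire_base,
                                ht_in = params$ht_in_base) {
  state <- ha_state(state)
  fl <- flux_terms(state, params, firing_rate, ht_in)
  out <- tibble::tibble(term = names(fl), rate = as.numeric(fl))
  attr(out, "inhib") <- attr(fl, "inhib")
  attr(out, "inhib_clamped") <- attr(fl, "inhib_clamped")
  out
}

#' Right-hand side of the varicosity ODE system
#'
#' Mass-balance derivatives of the ten state variables, with the firing
#' and dietary-input protocols evaluated at `t_hr`. The three
#' transduction derivatives are multiplied by their speed multipliers,
#' which rescale kinetics without moving the equilibrium.
#'
#' @param t_hr Time in hours.
#' @param state Named state vector.
#' @param params An [ha_params()] object.
#' @param firing,input Protocols (see [firing_protocol()],
#'   [input_protocol()]); `NULL` means constant at the baseline rates in
#'   `params`.
#' @return Named derivative vector (per hour).
#' @examples
#' varicosity_rhs(0, ha_reference_state, ha_params())
#' @export
varicosity_rhs <- function(t_hr, state, params = ha_params(),
                           firing = NULL, input = NULL) {
  state <- ha_state(state)
  fire <- if (is.null(firing)) params$fire_base else
    protocol_rate(firing, t_hr)
  htin <- if (is.null(input)) params$ht_in_base else
    protocol_rate(input, t_hr)
  fl <- flux_terms(state, params, fire, htin)
  if (any(!is.finite(fl))) {
    stop("non-finite flux at t = ", t_hr, " hr", call. = FALSE)
  }
  rhs_from_fluxes(fl, params)
}

#' Simulate the varicosity model
#'
#' Stiff initial-value integration (via \pkg{deSolve}'s `lsoda`) of the
#' ten-variable system under piecewise-constant firing and dietary-input
#' protocols. The integration is restarted at every protocol breakpoint,
#' so the step forcing is handled exactly rather than smoothed. Output
#' states are checked against the model invariants (non-negativity and
#' the transduction conservation caps), with sub-tolerance solver noise
#' clamped.
#'
#' @param params An [ha_params()] object.
#' @param initial Initial state; defaults to the nominal steady state of
#'   `params`.
#' @param firing,input Protocols; `NULL` means constant at the baseline
#'   rates in `params`.
#' @param t_span Length-2 numeric, integration span in hours.
#' @param output_times Output grid in hours (within `t_span`); defaults
#'   to 201 equally spaced points.
#' @param rtol,atol Relative / absolute solver tolerances. The defaults
#'   (1e-8, 1e-10) resolve the fast receptor-binding kinetics that make
#'   the system stiff during stimulation.
#' @return An `ha_trajectory`: a tibble with column `time_hr` and one
#'   column per state variable, carrying the parameters and protocols as
#'   attributes. If the inhibition clamp activated anywhere on the output
#'   grid, attribute `inhib_clamped_points` records how often and a
#'   message is emitted.
#' @examples
#' traj <- simulate_varicosity(ha_params(), initial = ha_reference_state,
#'                             t_span = c(0, 1))
#' tail(traj)
#' @export
simulate_varicosity <- function(params = ha_params(), initial = NULL,
                                firing = NULL, input = NULL,
                                t_span = c(0, 24), output_times = NULL,
                                rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "ha_params"))
  if (length(t_span) != 2 || t_span[2] <= t_span[1]) {
    stop("t_span must be an increasing length-2 vector (hours)",
         call. = FALSE)
  }
  if (is.null(firing)) firing <- firing_protocol(NULL, params$fire_base)
  if (is.null(input)) input <- input_protocol(NULL, params$ht_in_base)
  if (is.null(initial)) {
    initial <- find_steady_state(params)
  }
  y <- ha_state(initial, params = params)
  if (is.null(output_times)) {
    output_times <- seq(t_span[1], t_span[2], length.out = 201)
  }
  output_times <- sort(unique(output_times))
  if (output_times[1] < t_span[1] - 1e-12 ||
      output_times[length(output_times)] > t_span[2] + 1e-12) {
    stop("output_times must lie within t_span", call. = FALSE)
  }

  bks <- c(protocol_breakpoints(firing), protocol_breakpoints(input))
  bks <- bks[bks > t_span[1] & bks < t_span[2]]
  edges <- sort(unique(c(t_span[1], bks, t_span[2])))

  rows <- vector("list", length(edges) - 1)
  for (i in seq_len(length(edges) - 1)) {
    lo <- edges[i]; hi <- edges[i + 1]
    fire <- protocol_rate(firing, lo)
    htin <- protocol_rate(input, lo)
    fn <- function(t, y, parms) {
      fl <- flux_terms(y, params, fire, htin)
      if (any(!is.finite(fl))) {
        stop("non-finite flux at t = ", t, " hr", call. = FALSE)
      }
      list(rhs_from_fluxes(fl, params))
    }
    tt <- output_times[output_times > lo + 1e-12 & output_times < hi - 1e-12]
    tt <- sort(unique(c(lo, tt, hi)))
    sol <- deSolve::ode(y = y, times = tt, func = fn, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol,
                        maxsteps = 100000)
    if (attr(sol, "istate")[1] < 0) {
      stop("solver failed near t = ", sol[nrow(sol), 1], " hr",
           call. = FALSE)
    }
    y <- sol[nrow(sol), STATE_VARS]
    # clamp solver noise, then enforce invariants
    y <- clamp_state(y, params)
    m <- sol[, c("time", STATE_VARS), drop = FALSE]
    rows[[i]] <- m
  }
  m <- do.call(rbind, rows)
  m <- m[!duplicated(round(m[, "time"], 12)), , drop = FALSE]
  keep <- vapply(output_times, function(t) {
    which.min(abs(m[, "time"] - t))
  }, integer(1))
  m <- m[keep, , drop = FALSE]
  m[, "time"] <- output_times

  states <- m[, STATE_VARS, drop = FALSE]
  states <- t(apply(states, 1, clamp_state, params = params))
  n_clamped <- sum(params$inhib_intercept -
                     params$inhib_slope * states[, "Gstar"] < 0)
  traj <- tibble::as_tibble(as.data.frame(states))
  traj <- dplyr::bind_cols(tibble::tibble(time_hr = output_times), traj)
  if (n_clamped > 0) {
    message("inhib() clamp active at ", n_clamped, " output point(s)")
  }
  new_trajectory(traj, params, firing, input,
                 inhib_clamped_points = n_clamped)
}

# Tolerate integrator noise just below zero / just above the caps;
# anything larger is a genuine invariant violation.
clamp_state <- function(y, params, slack = 1e-7) {
  y <- y[STATE_VARS]
  scale <- pmax(abs(y), 1)
  bad <- y < -slack * scale
  if (any(bad)) {
    stop("trajectory violated non-negativity for: ",
         paste(STATE_VARS[bad], collapse = ", "), call. = FALSE)
  }
  y[y < 0] <- 0
  caps <- c(Gstar = params$g0, Tstar = params$t0, bHA = params$b0)
  for (v in names(caps)) {
    if (y[[v]] > caps[[v]] * (1 + slack)) {
      stop("trajectory exceeded conservation cap for ", v, call. = FALSE)
    }
    if (y[[v]] > caps[[v]]) y[[v]] <- caps[[v]]
  }
  y
}

new_trajectory <- function(tbl, params, firing, input, ...) {
  structure(tbl,
            class = c("ha_trajectory", class(tibble::tibble())),
            params = params, firing = firing, input = input, ...)
}

#' @export
print.ha_trajectory <- function(x, ...) {
  cat(sprintf("<ha_trajectory> %d time points over [%g, %g] hr\n",
              nrow(x), x$time_hr[1], x$time_hr[nrow(x)]))
  NextMethod()
}
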