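#' Model parameters for the histamine varicosity model
#'
#' Builds the full parameter set of the varicosity model: the fourteen
#' first-order coefficients `a1`--`a14`, Michaelis--Menten `Vmax`/`Km` pairs
#' for every enzyme and transporter, pool totals for the transduction
#' variables, baseline firing and dietary input rates, and the linear
#' autoreceptor inhibition function. All rate constants are per hour;
#' concentrations are micromolar except the transduction variables
#' (`Gstar`, `Tstar`, `bHA`), whose units are arbitrary.
#'
#' The default inhibition function is `inhib(G*) = 2.4015 - 2.45 G*`;
#' `inhib_variant = "strong"` switches to the more homeostatic
#' `7.645 - 10 G*`. Both lines pass through 0.7 at the tonic operating
#' point `G* = 0.6945`, so the steady state is unchanged by the switch.
#'
#' The totals `g0 = 1` and `t0 = 60` are pinned by requiring the
#' transduction equations to balance at the nominal equilibrium
#' (see [verify_derived_totals()]).
#'
#' @param ... Named overrides of any parameter, or a single named list of
#'   overrides. Unknown names are rejected.
#' @param inhib_variant `"default"` or `"strong"` autoreceptor inhibition
#'   line. Explicit `inhib_intercept`/`inhib_slope` overrides take
#'   precedence.
#'
#' @return An object of class `ha_params`: a validated named list.
#'
#' @section Parameters:
#' \describe{
#'   \item{a1, a3}{HA leakage from cytosol / glia to the extracellular
#'     space (per hr).}
#'   \item{a2}{HA release per action potential (the firing rate enters as
#'     its numeric sp/s value; `a2` absorbs the unit conversion).}
#'   \item{a4}{HA removal from the extracellular space (per hr).}
#'   \item{a5}{Stabilisation of blood histidine toward `bht_setpoint`.}
#'   \item{a6, a7, a8}{Exchange between cytosolic histidine and the
#'     histidine pool, and consumption of the pool by other pathways.}
#'   \item{a9--a14}{Transduction kinetics: bound receptors activate the
#'     G-protein subunit, `G*` activates the RGS protein, active RGS
#'     deactivates `G*`, and extracellular HA binds/unbinds receptors.}
#'   \item{vmax_*, km_*}{Michaelis--Menten constants (uM/hr, uM) for the
#'     histidine transporter (HTL), histidine decarboxylase (HTDC),
#'     neuronal and glial histamine N-methyltransferase (HNMT), the
#'     vesicular monoamine transporter (MAT, with linear `mat_backleak`),
#'     and the neuronal and glial reuptake transporters (HAT).}
#'   \item{g0, t0, b0}{Totals of G-protein, RGS protein and autoreceptors
#'     (arbitrary units). Lowering `b0` models an H3 antagonist.}
#'   \item{speed_gstar, speed_tstar, speed_bha}{Multipliers on the three
#'     transduction right-hand sides; they rescale kinetics without moving
#'     the steady state.}
#' }
#'
#' @examples
#' p <- ha_params()
#' p$vmax_htl
#' ha_params(b0 = 4)$b0                     # autoreceptor antagonist
#' ha_params(inhib_variant = "strong")$inhib_slope
#' @export
ha_params <- function(..., inhib_variant = c("default", "strong")) {
  inhib_variant <- match.arg(inhib_variant)
  defaults <- list(
    a1 = 12, a2 = 5, a3 = 12, a4 = 0.001, a5 = 0.25, a6 = 2.5, a7 = 1,
    a8 = 1, a9 = 4.32, a10 = 1.296, a11 = 14.4, a12 = 25.92, a13 = 432,
    a14 = 1440,
    vmax_htl = 4680, km_htl = 1000,
    vmax_htdc = 234, km_htdc = 270,
    vmax_hnmt = 185.5, km_hnmt = 4.2,
    vmax_hnmt_g = 53, km_hnmt_g = 4.2,
    vmax_mat = 31500, km_mat = 24, mat_backleak = 5,
    vmax_hat = 6513, km_hat = 2,
    vmax_hat_g = 24, km_hat_g = 1,
    ht_in_base = 424, bht_setpoint = 100,
    inhib_intercept = 2.4015, inhib_slope = 2.45,
    g0 = 1, t0 = 60, b0 = 10,
    fire_base = 5,
    speed_gstar = 1, speed_tstar = 1, speed_bha = 1
  )
  if (inhib_variant == "strong") {
    defaults$inhib_intercept <- 7.645
    defaults$inhib_slope <- 10
  }
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]])) {
    over <- over[[1]]
  }
  if (length(over) > 0 && (is.null(names(over)) || any(names(over) == ""))) {
    stop("all parameter overrides must be named", call. = FALSE)
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p <- utils::modifyList(defaults, over)
  validate_ha_params(p)
  structure(p, class = "ha_params")
}

validate_ha_params <- function(p) {
  num1 <- function(keys, check, what) {
    for (k in keys) {
      v <- p[[k]]
      if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || !check(v)) {
        stop("parameter '", k, "' must be a finite ", what, call. = FALSE)
      }
    }
  }
  # Vmax values may be zeroed (synthesis blockade); Km and totals must be
  # strictly positive or rate laws degenerate.
  num1(grep("^vmax_", names(p), value = TRUE), function(v) v >= 0,
       "number >= 0")
  num1(grep("^km_", names(p), value = TRUE), function(v) v > 0,
       "number > 0")
  num1(c("g0", "t0", "b0", "bht_setpoint",
         "speed_gstar", "speed_tstar", "speed_bha"),
       function(v) v > 0, "number > 0")
  num1(c(paste0("a", 1:14), "mat_backleak", "ht_in_base", "fire_base",
         "inhib_intercept", "inhib_slope"),
       function(v) v >= 0, "number >= 0")
  invisible(p)
}

#' Modify a parameter set
#'
#' Returns a new validated [ha_params()] object with the given fields
#' replaced.
#'
#' @param params An `ha_params` object.
#' @param ... Named replacements.
#' @return A new `ha_params` object.
#' @examples
#' ha_update(ha_params(), vmax_htdc = 0)$vmax_htdc
#' @export
ha_update <- function(params, ...) {
  stopifnot(inherits(params, "ha_params"))
  ha_params(utils::modifyList(unclass(params), list(...)))
}

#' @export
print.ha_params <- function(x, ...) {
  cat("<ha_params> histamine varicosity model parameters\n")
  cat(sprintf("  inhib(G*) = %g - %g G*   (tonic value %.3f at G* = 0.6945)\n",
              x$inhib_intercept, x$inhib_slope,
              x$inhib_intercept - x$inhib_slope * 0.6945))
  cat(sprintf("  totals: g0 = %g, t0 = %g, b0 = %g; fire_base = %g sp/s; HT_in = %g uM/hr\n",
              x$g0, x$t0, x$b0, x$fire_base, x$ht_in_base))
  cat(sprintf("  transduction speed multipliers: %g, %g, %g\n",
              x$speed_gstar, x$speed_tstar, x$speed_bha))
  invisible(x)
}

#' State variable names of the varicosity model
#'
#' Order used throughout: cytosolic, vesicular, extracellular and glial
#' histamine; blood and cytosolic histidine and the histidine pool; then
#' the transduction variables (active G-protein, active RGS protein,
#' bound autoreceptors).
#' @export
STATE_VARS <- c("cHA", "vHA", "eHA", "gHA", "bHT", "cHT", "HTpool",
                "Gstar", "Tstar", "bHA")

#' Reference nominal steady state
#'
#' The model's nominal operating point (firing 5 sp/s, dietary input
#' 424 uM/hr), rounded to the precision at which it is usually quoted.
#' Used to pin the derived transduction totals and as a regression
#' reference; the exact equilibrium from [find_steady_state()] agrees
#' with these values to better than 1%.
#' @export
ha_reference_state <- c(
  cHA = 2.90, vHA = 150.9, eHA = 1.39, gHA = 0.61, bHT = 99.72,
  cHT = 273.5, HTpool = 341.9, Gstar = 0.6945, Tstar = 12.69, bHA = 2.94
)

#' Construct and validate a model state
#'
#' @param ... Either ten named values (names in [STATE_VARS]) or a single
#'   named numeric vector.
#' @param params Optional `ha_params` used to check the conservation caps
#'   `Gstar <= g0`, `Tstar <= t0`, `bHA <= b0`.
#' @return A named numeric state vector in canonical order.
#' @examples
#' ha_state(ha_reference_state)
#' @export
ha_state <- function(..., params = NULL) {
  v <- c(...)
  if (is.list(v)) v <- unlist(v)
  if (!is.numeric(v) || is.null(names(v))) {
    stop("state must be a named numeric vector", call. = FALSE)
  }
  missing <- setdiff(STATE_VARS, names(v))
  extra <- setdiff(names(v), STATE_VARS)
  if (length(missing) > 0) {
    stop("missing state variable(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(extra) > 0) {
    stop("unknown state variable(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  v <- v[STATE_VARS]
  if (any(!is.finite(v))) stop("state contains non-finite values", call. = FALSE)
  if (any(v < 0)) {
    stop("state variables must be non-negative: ",
         paste(STATE_VARS[v < 0], collapse = ", "), call. = FALSE)
  }
  if (!is.null(params)) {
    caps <- c(Gstar = params$g0, Tstar = params$t0, bHA = params$b0)
    over <- v[names(caps)] > caps
    if (any(over)) {
      stop("conservation cap exceeded for: ",
           paste(names(caps)[over], collapse = ", "), call. = FALSE)
    }
  }
  v
}
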