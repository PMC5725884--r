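#' Piecewise-constant protocols
#'
#' A protocol is a step function of time built from non-overlapping,
#' ordered segments; outside all segments the default rate applies.
#' Segments are half-open `[start, end)`: at an exact breakpoint the new
#' rate applies. [simulate_varicosity()] restarts the integrator at every
#' breakpoint so the steps are resolved without smoothing.
#'
#' `firing_protocol()` describes neuronal firing in spikes per second and
#' takes segment times in seconds by default (stimulation experiments run
#' on a seconds timescale); `input_protocol()` describes dietary histidine
#' input in uM/hr with segment times in hours. Internally all times are
#' hours.
#'
#' @param segments A data frame with columns `start`, `end`, `rate`
#'   (or `NULL` for a constant protocol).
#' @param default_rate Rate outside all segments (sp/s for firing,
#'   uM/hr for input).
#' @param units Units of `start`/`end` in `segments`.
#' @return An object of class `ha_protocol`.
#' @examples
#' fp <- firing_protocol(data.frame(start = c(5, 8), end = c(8, 9),
#'                                  rate = c(25, 14)))
#' protocol_rate(fp, c(0, 5, 8.5, 9) / 3600)
#' @name protocols
NULL

new_protocol <- function(segments, default_rate, units, kind) {
  if (!is.numeric(default_rate) || length(default_rate) != 1 ||
      !is.finite(default_rate) || default_rate < 0) {
    stop("default_rate must be a single non-negative number", call. = FALSE)
  }
  to_hr <- if (units == "seconds") 1 / 3600 else 1
  if (is.null(segments) || nrow(as.data.frame(segments)) == 0) {
    segments <- tibble::tibble(start_hr = numeric(), end_hr = numeric(),
                               rate = numeric())
  } else {
    segments <- as.data.frame(segments)
    need <- c("start", "end", "rate")
    if (!all(need %in% names(segments))) {
      stop("segments must have columns start, end, rate", call. = FALSE)
    }
    if (any(!is.finite(as.matrix(segments[need])))) {
      stop("segments contain non-finite values", call. = FALSE)
    }
    if (any(segments$rate < 0)) stop("rates must be >= 0", call. = FALSE)
    if (any(segments$end <= segments$start)) {
      stop("each segment must have end > start", call. = FALSE)
    }
    segments <- segments[order(segments$start), , drop = FALSE]
    if (nrow(segments) > 1 &&
        any(segments$start[-1] < segments$end[-nrow(segments)])) {
      stop("segments must be non-overlapping", call. = FALSE)
    }
    segments <- tibble::tibble(start_hr = segments$start * to_hr,
                               end_hr = segments$end * to_hr,
                               rate = segments$rate)
  }
  structure(list(segments = segments, default_rate = default_rate,
                 kind = kind),
            class = "ha_protocol")
}

#' @rdname protocols
#' @export
firing_protocol <- function(segments = NULL, default_rate = 5,
                            units = c("seconds", "hours")) {
  new_protocol(segments, default_rate, match.arg(units), "firing")
}

#' @rdname protocols
#' @export
input_protocol <- function(segments = NULL, default_rate = 424,
                           units = c("hours", "seconds")) {
  new_protocol(segments, default_rate, match.arg(units), "input")
}

#' Evaluate a protocol
#'
#' @param protocol An `ha_protocol`.
#' @param t_hr Time(s) in hours.
#' @return Rate(s) at `t_hr`, honouring the half-open `[start, end)`
#'   segment convention.
#' @export
protocol_rate <- function(protocol, t_hr) {
  stopifnot(inherits(protocol, "ha_protocol"))
  if (any(!is.finite(t_hr))) stop("protocol lookup at non-finite time",
                                  call. = FALSE)
  out <- rep(protocol$default_rate, length(t_hr))
  seg <- protocol$segments
  if (nrow(seg) > 0) {
    for (i in seq_len(nrow(seg))) {
      hit <- t_hr >= seg$start_hr[i] & t_hr < seg$end_hr[i]
      out[hit] <- seg$rate[i]
    }
  }
  out
}

#' Breakpoints of a protocol
#'
#' @param protocol An `ha_protocol`.
#' @return Sorted unique segment boundaries in hours (integrator restart
#'   points).
#' @export
protocol_breakpoints <- function(protocol) {
  stopifnot(inherits(protocol, "ha_protocol"))
  sort(unique(c(protocol$segments$start_hr, protocol$segments$end_hr)))
}

#' @export
print.ha_protocol <- function(x, ...) {
  cat(sprintf("<ha_protocol> %s, default rate %g, %d segment(s)\n",
              x$kind, x$default_rate, nrow(x$segments)))
  if (nrow(x$segments) > 0) print(x$segments)
  invisible(x)
}
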