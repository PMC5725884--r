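#' Plot methods for model results
#'
#' `autoplot()` methods returning ggplot objects: faceted state
#' trajectories, the four-compartment decay of the half-life experiment,
#' fold-change traces of a histidine load, the baseline-relative
#' stimulation response with its transduction variables, dietary
#' dose-response points, and the oscillation trace with detected peaks.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name histasim-plots
NULL

#' @rdname histasim-plots
#' @export
autoplot.ha_trajectory <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$time_hr, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (hr)", y = "concentration (uM / a.u.)")
}

#' @rdname histasim-plots
#' @export
autoplot.ha_halflife <- function(object, ...) {
  tr <- tidy(object$trajectory)
  tr <- dplyr::filter(tr, .data$variable %in% c("cHA", "vHA", "eHA", "gHA"))
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time_hr, y = .data$value,
                                   colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time after synthesis blockade (hr)",
                  y = "histamine (uM, log scale)", colour = NULL)
}

#' @rdname histasim-plots
#' @export
autoplot.ha_load <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trace, -"time_hr",
                            names_to = "index", values_to = "fold")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time_hr, y = .data$fold,
                                   colour = .data$index)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "time (hr)", y = "fold change over baseline",
                  colour = NULL)
}

#' @rdname histasim-plots
#' @export
autoplot.ha_dietary <- function(object, ...) {
  tr <- tidyr::pivot_longer(tidy(object), -"factor",
                            names_to = "index", values_to = "fold")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$factor, y = .data$fold,
                                   colour = .data$index)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "dietary histidine (fold of normal)",
                  y = "fold change after two weeks", colour = NULL)
}

#' @rdname histasim-plots
#' @export
autoplot.ha_stim <- function(object, ...) {
  tr <- tidy(object)
  tr <- dplyr::filter(tr, .data$variable %in%
                        c("eHA_rel", "bHA", "Gstar", "Tstar"))
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = paste(object$protocol$name, "stimulation"))
}

#' @rdname histasim-plots
#' @export
autoplot.ha_oscillation <- function(object, ...) {
  tr <- object$stimulation$trace
  p <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$time_s, y = .data$eHA)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$stimulation$baseline[["eHA"]],
                        linetype = 2) +
    ggplot2::labs(x = "time (s)", y = "extracellular histamine (uM)")
  if (length(object$peak_times_s) > 0) {
    pk <- tr[tr$time_s %in% object$peak_times_s, ]
    p <- p + ggplot2::geom_point(data = pk, colour = "red")
  }
  p
}
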