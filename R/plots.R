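#' Plot a Kaplan-Meier curve
#'
#' @param object A `ctpirp_km` curve.
#' @param ... Unused.
#' @return A ggplot: survival step function with its confidence band.
#' @method autoplot ctpirp_km
#' @export
autoplot.ctpirp_km <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::geom_step(ggplot2::aes(y = .data$lower), linetype = "dashed",
                       na.rm = TRUE) +
    ggplot2::geom_step(ggplot2::aes(y = .data$upper), linetype = "dashed",
                       na.rm = TRUE) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years since enrolment", y = "Survival",
                  title = paste0("Kaplan-Meier (", attr(object, "event"),
                                 ")")) +
    ggplot2::theme_minimal()
}

#' Plot cumulative incidence functions
#'
#' Stacked cumulative-incidence areas per cause, the standard competing-risks
#' display.
#'
#' @param object A `ctpirp_cif` object.
#' @param stacked Stack the cause-specific incidences (default) or overlay
#'   them as step curves.
#' @param ... Unused.
#' @method autoplot ctpirp_cif
#' @export
autoplot.ctpirp_cif <- function(object, stacked = TRUE, ...) {
  d <- filter(as_tibble(object), .data$cause != "event_free")
  if (stacked) {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$cif,
                                    fill = .data$cause)) +
      ggplot2::geom_area(position = "stack") +
      ggplot2::labs(x = "Years since enrolment",
                    y = "Cumulative incidence", fill = "Cause") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$cif,
                                    colour = .data$cause)) +
      ggplot2::geom_step() +
      ggplot2::labs(x = "Years since enrolment",
                    y = "Cumulative incidence", colour = "Cause") +
      ggplot2::theme_minimal()
  }
}

#' Plot discrimination curves (per-node Kaplan-Meier)
#'
#' @param object A `ctpirp_discrimination` result.
#' @param ... Unused.
#' @method autoplot ctpirp_discrimination
#' @export
autoplot.ctpirp_discrimination <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$time, y = .data$surv,
                               colour = factor(.data$node))) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years since enrolment", y = "Survival",
                  colour = "Node",
                  title = paste0("Discrimination (", object$event, ")")) +
    ggplot2::theme_minimal()
}

#' Calibration plot: expected vs observed survival per node
#'
#' Expected curves from the derivation baseline-survival transfer as lines;
#' observed validation Kaplan-Meier estimates as points with confidence
#' intervals.
#'
#' @param object A `ctpirp_calibration` result.
#' @param ... Unused.
#' @method autoplot ctpirp_calibration
#' @export
autoplot.ctpirp_calibration <- function(object, ...) {
  d <- object$curves
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected)) +
    ggplot2::geom_pointrange(ggplot2::aes(y = .data$observed,
                                          ymin = .data$obs_lower,
                                          ymax = .data$obs_upper),
                             size = 0.2, na.rm = TRUE) +
    ggplot2::facet_wrap(~node, labeller = ggplot2::label_both) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years since enrolment", y = "Survival",
                  title = paste0("Calibration (", object$event,
                                 "): expected line vs observed points")) +
    ggplot2::theme_minimal()
}
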