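#' Plot a time-activity curve with an optional fitted model
#'
#' @param tac TAC tibble.
#' @param fit Optional `petrel_kfit` with fitted frame values.
#' @param schedule Frame schedule (default: TAC attribute).
#' @return A ggplot object: frame-midpoint activity versus minutes
#'   post-injection.
#' @export
plot_tac <- function(tac, fit = NULL, schedule = attr(tac, "schedule")) {
  stopifnot(!is.null(schedule))
  d <- tibble::tibble(t_min = schedule$mid_inj_s / 60,
                      value = tac$value_kBq_ml)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$t_min, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Time post-injection (min)",
                  y = "Activity concentration (kBq/ml)",
                  title = tac$region_id[1])
  if (!is.null(fit) && !is.null(fit$fitted)) {
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(t_min = d$t_min, value = fit$fitted),
      colour = "firebrick")
  }
  p
}

#' @export
autoplot.petrel_ba <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$bias, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of methods", y = "Difference (method 1 - 2)",
                  title = "Bland-Altman comparison")
}

#' @export
autoplot.petrel_rs <- function(object, ...) {
  d <- tibble::tibble(R = object$R_grid, vt = object$vt_curve)
  win <- d[object$plateau_window, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$R, y = .data$vt)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = win, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = object$vt, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Expected signal-to-noise ratio R", y = "V_T(R)",
                  title = "Rank-shaping V_T(R) plateau")
}

#' @export
autoplot.petrel_sa <- function(object, ...) {
  sp <- object$spectrum[object$spectrum$alpha > 0, ]
  ggplot2::ggplot(sp, ggplot2::aes(x = .data$beta_acq, y = .data$alpha)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$beta_acq, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Component rate (1/s, acquisition domain)",
                  y = "Amplitude", title = "Spectral analysis components")
}

#' Plot per-region ICCs of one or more reliability tables
#'
#' @param ... One or more [build_reliability_table()] results.
#' @return A ggplot object; the dashed line marks the conventional 0.75
#'   good-reliability threshold.
#' @export
plot_reliability <- function(...) {
  d <- dplyr::bind_rows(...)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$region_id, y = .data$icc,
                                  colour = .data$method,
                                  group = .data$method)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.75, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "ICC (one-way random, single measures)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
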