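#' Plot a simulated trajectory
#'
#' Tumor volume (left axis, solid) and functional PD-L1 expression
#' (dashed, rescaled) over time, with dose days marked by vertical lines.
#'
#' @param object A [simulate_arm()] trajectory.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pdl1_trajectory
#' @export
autoplot.pdl1_trajectory <- function(object, ...) {
  arm <- attr(object, "arm")
  eps_scale <- max(object$V_mm3) / max(max(object$eps), 1e-12)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_day)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$V_mm3, linetype = "tumor volume")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$eps * eps_scale, linetype = "expression (scaled)")) +
    ggplot2::scale_linetype_manual(NULL, values = c("tumor volume" = "solid",
                                                    "expression (scaled)" = "dashed")) +
    ggplot2::labs(x = "time (days)", y = "tumor volume (mm³)",
                  title = sprintf("arm %s (%s epsilon)", arm$name, attr(object, "mode"))) +
    ggplot2::theme_minimal()
  if (nrow(arm$events) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = unique(arm$events$day),
                                 linetype = "dotted", colour = "grey50")
  }
  p
}

#' Plot a time-course sensitivity comparison
#'
#' Overlays the nominal, plus, and minus trajectories of the expression
#' state produced by [timecourse_sensitivity()].
#'
#' @param object A `pdl1_sens_tc` object.
#' @param state `"eps"` (default) or `"V_mm3"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pdl1_sens_tc
#' @export
autoplot.pdl1_sens_tc <- function(object, state = c("eps", "V_mm3"), ...) {
  state <- match.arg(state)
  frac <- attr(object, "frac")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_day, y = .data[[state]],
                                       colour = .data$variant, linetype = .data$variant)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(nominal = "black", plus = "firebrick", minus = "steelblue")) +
    ggplot2::scale_linetype_manual(values = c(nominal = "solid", plus = "dashed", minus = "dashed")) +
    ggplot2::labs(x = "time (days)",
                  y = if (state == "eps") "functional PD-L1 expression" else "tumor volume (mm³)",
                  title = sprintf("%s perturbed by ±%.0f%% (arm %s)",
                                  attr(object, "parameter"), 100 * frac,
                                  attr(object, "arm")$name)) +
    ggplot2::theme_minimal()
}

#' Plot a fitted model against its data
#'
#' Overlays the fitted simulation on the observed tumor volumes for every
#' arm covered by the fit.
#'
#' @param object A `pdl1_fit` object.
#' @param data The arm dataset the model was fitted to.
#' @param base,v0,step Passed to [simulate_arm()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pdl1_fit
#' @export
autoplot.pdl1_fit <- function(object, data, base = base_params(),
                              v0 = 100, step = 0.1, ...) {
  data <- as_arm_data(data)
  eps_arg <- if (object$mode == "dynamic") fitted_epsilon_params(object) else object$estimates[["epsilon"]]
  sims <- dplyr::bind_rows(lapply(object$arms, function(arm) {
    traj <- simulate_arm(arm, base = base, epsilon = eps_arg, mode = object$mode,
                         t_end = max(data$day), v0 = v0, step = step)
    tibble::tibble(arm = arm$name, time_day = traj$time_day, V_mm3 = traj$V_mm3)
  }))
  ggplot2::ggplot() +
    ggplot2::geom_line(data = sims, ggplot2::aes(x = .data$time_day, y = .data$V_mm3),
                       colour = "steelblue") +
    ggplot2::geom_point(data = data, ggplot2::aes(x = .data$day, y = .data$volume_mm3),
                        colour = "firebrick") +
    ggplot2::facet_wrap(~arm) +
    ggplot2::labs(x = "time (days)", y = "tumor volume (mm³)",
                  title = sprintf("%s-epsilon fit (RSS %.4g, AIC %.2f)",
                                  object$mode, object$rss, object$aic)) +
    ggplot2::theme_minimal()
}
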