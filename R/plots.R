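# ggplot2 views of the main result types. These are working plots, not
# figure-styling helpers.

#' @describeIn reward_landscape heat map of the reward-rate landscape with
#'   the argmax marked.
#' @param object A `waitgo_landscape`.
#' @export
autoplot.waitgo_landscape <- function(object, ...) {
  am <- attr(object, "argmax")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$slope_deg, y = .data$intercept,
                               fill = .data$reward_rate)) +
    ggplot2::geom_tile() +
    ggplot2::annotate("point", x = am$slope_deg, y = am$intercept,
                      shape = 4, size = 3) +
    ggplot2::scale_fill_viridis_c(name = "reward rate") +
    ggplot2::labs(x = "boundary slope (degrees)",
                  y = "boundary intercept (evidence units)")
}

#' @describeIn extract_boundary step plot of the boundary trace (and its
#'   mirror image).
#' @param object A `waitgo_boundary`.
#' @param ... Unused.
#' @export
autoplot.waitgo_boundary <- function(object, ...) {
  df <- filter(as_tibble(object), !is.na(.data$theta))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$theta)) +
    ggplot2::geom_step(ggplot2::aes(y = -.data$theta), linetype = "dashed") +
    ggplot2::labs(x = "time (ISI units)", y = "evidence x")
}

#' @describeIn solve_optimal_policy tile plot of the wait/go action map.
#' @export
autoplot.waitgo_policy <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$t, y = .data$x,
                               fill = .data$action)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(go = "grey20", wait = "grey75")) +
    ggplot2::labs(x = "time (ISI units)", y = "evidence x")
}

#' Heat map of a fitted wait/go model
#'
#' Plots the fitted go probability over the `(t, X)` plane together with the
#' line of indifference, mirroring the standard per-participant diagnostic
#' view of a wait/go fit.
#'
#' @param fit A `waitgo_fit`.
#' @param t_max,x_max Plot ranges.
#' @return A ggplot object.
#' @export
plot_waitgo_fit <- function(fit, t_max = 20, x_max = 10) {
  stopifnot(inherits(fit, "waitgo_fit"))
  grid <- tidyr::expand_grid(t = 0:t_max, x = 0:x_max)
  b <- fit$coef
  bT <- if (fit$include_time) b[["betaT"]] else 0
  grid$p_go <- plogis(b[["beta0"]] + bT * grid$t + b[["betaX"]] * grid$x)
  li <- line_of_indifference(fit)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$t, y = .data$x,
                                     fill = .data$p_go)) +
    ggplot2::geom_tile() +
    ggplot2::geom_abline(intercept = li$intercept, slope = li$gradient,
                         colour = "white") +
    ggplot2::scale_fill_viridis_c(name = "P(go)", limits = c(0, 1)) +
    ggplot2::labs(x = "time (ISI units)", y = "evidence magnitude X")
}
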