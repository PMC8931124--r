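#' Plot per-row framing effects
#'
#' Dumbbell-style plot of the share choosing the later option in each
#' condition for every stimulus row of a trial table — the visual
#' analogue of the published stimulus tables.
#'
#' @param trials A trial tibble from [simulate_binary_experiment()].
#' @return A ggplot object.
#' @export
plot_frame_effect <- function(trials) {
  rows <- summarise_frame_effect(trials) |>
    tidyr::pivot_longer(c("pct_baseline", "pct_cancellation"),
                        names_to = "condition", names_prefix = "pct_",
                        values_to = "pct")
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$pct,
                                     y = factor(.data$trial_id),
                                     colour = .data$condition)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$trial_id),
                       colour = "grey60") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = "% choosing the later option", y = "stimulus row",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot indifference thresholds against curvature
#'
#' Shows the integrated and cancelled threshold discount factors of one
#' choice pair as functions of the utility curvature, illustrating both
#' the level shift (cancellation lowers the threshold) and the steeper
#' slope under cancellation.
#'
#' @inheritParams delta_star_cancelled
#' @param alpha_grid Curvature values to evaluate.
#' @return A ggplot object.
#' @export
plot_threshold_curves <- function(x0, xk, common, k,
                                  alpha_grid = seq(0.2, 1, by = 0.01),
                                  beta = 1) {
  dat <- tibble::tibble(
    alpha = rep(alpha_grid, 2),
    frame = rep(c("integrated", "cancelled"), each = length(alpha_grid)),
    threshold = c(delta_star(x0, xk, k, alpha_grid, beta),
                  delta_star_cancelled(x0, xk, common, k, alpha_grid, beta))
  )
  ggplot2::ggplot(dat, ggplot2::aes(.data$alpha, .data$threshold,
                                    colour = .data$frame)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = expression(alpha), y = expression(delta * "*"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Autoplot a replication report
#'
#' Binary-choice reports are drawn as per-row framing-effect dumbbells;
#' the retirement-menu report as the chosen-age distribution by
#' condition.
#'
#' @param object A `cancel_report` from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cancel_report <- function(object, ...) {
  if (!is.null(object$trials)) {
    return(plot_frame_effect(object$trials))
  }
  ggplot2::ggplot(object$distribution,
                  ggplot2::aes(x = factor(.data$start_age), y = .data$pct,
                               fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "benefit start age", y = "% choosing", fill = NULL) +
    ggplot2::theme_minimal()
}
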