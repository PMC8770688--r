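#' Mean-fitness trajectory plot
#'
#' Mean true fitness against trial with standard-error ribbons, one
#' panel per season and one colour per condition — the standard way the
#' task's cohort results are displayed.
#'
#' @param summary Trajectory summary from [summarize_trajectories()]
#'   (conditions may be row-bound).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(
    x = .data$trial, y = .data$mean_fitness,
    colour = .data$condition, fill = .data$condition)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_fitness - .data$se_fitness,
                   ymax = .data$mean_fitness + .data$se_fitness),
      alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~season, ncol = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Trial", y = "Mean true fitness (calories)",
                  colour = "Condition", fill = "Condition") +
    ggplot2::theme_minimal()
}

#' Fitness-SD trajectory plot
#'
#' Standard deviation of true fitness against trial, per season and
#' condition.
#'
#' @inheritParams plot_trajectories
#' @return A ggplot object.
#' @export
plot_sd_trajectories <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(
    x = .data$trial, y = .data$sd_fitness, colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~season, ncol = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Trial", y = "SD of true fitness (calories)",
                  colour = "Condition") +
    ggplot2::theme_minimal()
}
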