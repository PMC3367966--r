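# ggplot2 display methods for the package's result types

#' @export
autoplot.coral_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), dplyr::all_of(CLASS_COLS),
                              names_to = "class", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$count,
                                     colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "year", y = "colonies per transect",
                  colour = "size class",
                  title = "Projected size-class trajectory") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.scenario_result <- function(object, ...) {
  long <- tidy.scenario_result(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$cover_cm2,
                                     linetype = .data$run)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(disturbed = "solid",
                                              reference = "dotted")) +
    ggplot2::labs(x = "year", y = expression(cover ~ (cm^2)),
                  linetype = NULL,
                  title = "Coral cover: disturbed vs undisturbed") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.synergy_grid <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$loss_rate),
                               y = factor(.data$mortality),
                               fill = .data$relative_final_cover)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.0f%%", .data$relative_final_cover)), size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100)) +
    ggplot2::labs(x = "recruitment loss (%/yr)", y = "mortality per event",
                  fill = "% of\nundisturbed",
                  title = "Synergy of recruitment loss and episodic mortality") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.elasticity_result <- function(object, ...) {
  long <- tidy.elasticity_result(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$from, y = .data$to,
                                     fill = .data$mean_elasticity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse(breaks = 1:5) +
    ggplot2::scale_x_continuous(breaks = 1:5) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "stage (from)", y = "stage (to)",
                  fill = "mean\nelasticity",
                  title = "Mean eigenvalue elasticity over the fertility grid") +
    ggplot2::theme_minimal()
}
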