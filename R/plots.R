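#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a task schedule
#'
#' Offer-cost map of a block: one point per trial, coloured by cost regime
#' surrogate (the cost itself), with the passive option's stake on the x
#' axis. Mirrors the usual way these schedules are displayed to show how
#' close the two options' values sit for most trials.
#'
#' @param object An `avoid_design`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot avoid_design
#' @export
autoplot.avoid_design <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offer, y = .data$cost)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$stimulus)),
                        alpha = 0.8) +
    ggplot2::labs(x = "offer (points)", y = "action cost (points)",
                  colour = "stimulus",
                  title = paste(unique(object$task), "block schedule")) +
    ggplot2::theme_minimal()
}

#' Go-rate learning curves from choice data
#'
#' Mean probability of choosing the active option across successive
#' encounters with a stimulus, split by the stimulus's true success
#' probability. The signature of learning is a fan: curves for high success
#' probabilities rise with encounters, low ones fall.
#'
#' @param data Choice data (simulated or observed).
#' @return A ggplot object.
#' @export
plot_choice_curves <- function(data) {
  curves <- data |>
    dplyr::group_by(.data$subject, .data$task, .data$block,
                    .data$stimulus) |>
    dplyr::mutate(encounter = dplyr::row_number()) |>
    dplyr::group_by(.data$success_prob, .data$encounter) |>
    dplyr::summarise(go_rate = mean(.data$choice), n = dplyr::n(),
                     .groups = "drop")
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$encounter, y = .data$go_rate,
                               colour = factor(round(.data$success_prob, 3)),
                               group = .data$success_prob)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "encounter with stimulus", y = "P(active choice)",
                  colour = "success prob.") +
    ggplot2::theme_minimal()
}

#' Plot model-selection results
#'
#' Bar chart of model frequency and protected exceedance probability per
#' model.
#'
#' @param object A `bms_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bms_result
#' @export
autoplot.bms_result <- function(object, ...) {
  long <- tidyr::pivot_longer(tidy(object), c("m_freq", "pxp"),
                              names_to = "measure")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model, y = .data$value,
                                     fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 1 / length(object$models),
                        linetype = "dashed") +
    ggplot2::labs(y = NULL, x = NULL) +
    ggplot2::theme_minimal()
}

#' Plot parameter recovery
#'
#' True versus recovered constrained parameter values, one facet per
#' parameter, with the identity line.
#'
#' @param object A `parameter_recovery`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot parameter_recovery
#' @export
autoplot.parameter_recovery <- function(object, ...) {
  ggplot2::ggplot(object$values,
                  ggplot2::aes(x = .data$true, y = .data$recovered)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(title = paste("Parameter recovery:", object$model)) +
    ggplot2::theme_minimal()
}
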