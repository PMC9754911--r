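#' Plot a wet/dry bout record with extracted trips
#'
#' Timeline of one bird's immersion record: wet and dry bouts as coloured
#' segments, extracted foraging trips overlaid as a ribbon.
#'
#' @param bouts Bout tibble from [parse_binned()] or [parse_state_change()].
#' @param trips Optional trip tibble from [extract_trips_and_shifts()].
#' @return A ggplot object.
#' @export
plot_bouts <- function(bouts, trips = NULL) {
  p <- ggplot2::ggplot(bouts) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$bird_id, yend = .data$bird_id,
                   colour = .data$state),
      linewidth = 4
    ) +
    ggplot2::scale_colour_manual(values = c(dry = "tan3", wet = "steelblue3")) +
    ggplot2::labs(x = NULL, y = NULL, colour = "state")
  if (!is.null(trips) && nrow(trips) > 0) {
    p <- p + ggplot2::geom_segment(
      data = trips,
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$bird_id, yend = .data$bird_id),
      linewidth = 1, colour = "black"
    )
  }
  p
}

#' Plot coordination: focal trip duration against partner deviation
#'
#' Scatter of the square-root focal trip duration against the partner
#' previous-trip deviation with the fitted population slope; the slope is the
#' coordination strength, and a positive slope means focal birds lengthen
#' their trips after an unusually long partner trip.
#'
#' @param model_table One stage's tibble from [build_model_table()].
#' @param slope,intercept Optional fitted line; when omitted a least-squares
#'   line is drawn.
#' @return A ggplot object.
#' @export
plot_coordination <- function(model_table, slope = NULL, intercept = NULL) {
  p <- ggplot2::ggplot(model_table,
                       ggplot2::aes(x = .data$partner_prev_dev,
                                    y = .data$response)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::labs(x = "partner previous-trip deviation",
                  y = expression(sqrt("trip duration (h)")))
  if (is.null(slope)) {
    p + ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                             colour = "black")
  } else {
    p + ggplot2::geom_abline(slope = slope,
                             intercept = intercept %||% mean(model_table$response),
                             colour = "black")
  }
}

#' Plot the AICc model ranking
#'
#' Candidate models ordered by AICc, with the delta < 2 window and the final
#' (post nested-exclusion) set highlighted.
#'
#' @param object A [select_models()] result.
#' @param ... Unused.
#' @param n_show Number of top models to display.
#' @return A ggplot object.
#' @export
autoplot.model_selection <- function(object, ..., n_show = 20) {
  df <- head(object$ranking, n_show)
  df$terms <- factor(df$terms, levels = rev(df$terms))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta, y = .data$terms,
                                   fill = .data$in_final_set)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = object$delta, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue4",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = expression(Delta * AICc), y = NULL,
                  fill = "final set")
}
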