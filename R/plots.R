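#' Plot a cyclic tensometer trace
#'
#' Load and displacement channels against time; apex samples are marked when
#' the trace carries generator ground truth.
#'
#' @param object A `tensile_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tensile_trace <- function(object, ...) {
  df <- tibble(time_s = object$time_s,
               load_N = object$load_N,
               displacement_mm = object$displacement_mm) |>
    tidyr::pivot_longer(c("load_N", "displacement_mm"),
                        names_to = "channel", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~ .data$channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = attr(object, "sample_id") %||% "tensile trace") +
    ggplot2::theme_minimal()
}

#' Plot stress-strain hysteresis loops of the central cycles
#'
#' @param result A `tendon_result` (see [process_tensile_trace()]).
#' @param trace The `tensile_trace` the result came from.
#' @return A ggplot object with one loop per central cycle.
#' @export
plot_hysteresis <- function(result, trace) {
  stopifnot(inherits(result, "tendon_result"))
  z <- result$summary$zero_offset_N
  central <- result$cycles |> filter(.data$cycle_index %in% 2:4)
  loops <- map(seq_len(nrow(central)), function(i) {
    cyc <- central[i, ]
    curves <- rising_falling_split(cyc, trace, zero_offset = z)
    dplyr::bind_rows(
      curves$rising |> mutate(limb = "rising"),
      curves$falling |> mutate(limb = "falling")) |>
      mutate(cycle = paste("cycle", cyc$cycle_index))
  }) |> list_rbind()
  ggplot2::ggplot(loops, ggplot2::aes(x = .data$strain, y = .data$stress_MPa,
                                      colour = .data$limb)) +
    ggplot2::geom_path(linewidth = 0.4) +
    ggplot2::facet_wrap(~ .data$cycle) +
    ggplot2::labs(x = "strain", y = "stress (MPa)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a lever table
#'
#' Mechanical advantage per species, faceted by prey scenario, coloured by
#' family group when available.
#'
#' @param object A `lever_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.lever_table <- function(object, ...) {
  df <- as_tibble(object)
  aes_args <- ggplot2::aes(
    x = stats::reorder(.data$species, .data$MA), y = .data$MA)
  p <- ggplot2::ggplot(df, aes_args)
  p <- if ("group" %in% names(df)) {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data$group))
  } else {
    p + ggplot2::geom_col()
  }
  p + ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mechanical advantage (FA/RA)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a Pagel's lambda profile likelihood
#'
#' @param object A `lambda_fit`.
#' @param ... Unused.
#' @return A ggplot object of the profile log-likelihood with the ML
#'   estimate marked.
#' @exportS3Method ggplot2::autoplot
autoplot.lambda_fit <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$lambda, y = .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$lambda, linetype = 2) +
    ggplot2::labs(x = expression(lambda), y = "profile log-likelihood") +
    ggplot2::theme_minimal()
}
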