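# ggplot2 visualisations for the main result types.

#' Insert-size distribution with concordance bounds
#'
#' @param pairs Aligned-pair tibble.
#' @param model An `insert_size_model`.
#' @return A ggplot.
#' @export
plot_insert_sizes <- function(pairs, model) {
  fr <- dplyr::filter(pairs, .data$strand1 != .data$strand2)
  ggplot2::ggplot(fr, ggplot2::aes(x = abs(.data$template_len_bp))) +
    ggplot2::geom_histogram(bins = 60, fill = "grey40") +
    ggplot2::geom_vline(xintercept = c(model$lower_bp, model$upper_bp),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "|template length| (bp)", y = "pairs",
                  title = sprintf("Insert sizes (median %.0f bp, concordant [%.0f, %.0f])",
                                  model$median_bp, model$lower_bp, model$upper_bp))
}

#' @rdname run_filter_cascade
#' @param object A `filter_report`.
#' @exportS3Method ggplot2::autoplot
autoplot.filter_report <- function(object, ...) {
  df <- mutate(object$stages, stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n_out)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_out), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "surviving variants",
                  title = "Variant prioritization cascade") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Inversion calls along the reference, with optional truth
#'
#' Draws each call's proximal and distal breakpoint intervals as segments,
#' coloured by evidence class; planted true breakpoints are dotted lines.
#'
#' @param calls Inversion-call tibble.
#' @param truth Optional inversion truth tibble (`start`, `end`).
#' @return A ggplot.
#' @export
plot_inversion_calls <- function(calls, truth = NULL) {
  if (!nrow(calls)) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "No inversion calls") +
             ggplot2::theme_void())
  }
  calls <- mutate(calls, call = factor(row_number()))
  long <- tidyr::pivot_longer(
    calls,
    cols = c("prox_start", "prox_end", "dist_start", "dist_end"),
    names_to = c("side", ".value"), names_pattern = "(prox|dist)_(start|end)"
  )
  p <- ggplot2::ggplot(long) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$call, yend = .data$call,
                   colour = .data$evidence),
      linewidth = 3
    ) +
    ggplot2::labs(x = "reference position (bp)", y = "call",
                  title = "Inversion breakpoint intervals")
  if (!is.null(truth) && nrow(truth)) {
    p <- p + ggplot2::geom_vline(xintercept = c(truth$start, truth$end),
                                 linetype = "dotted")
  }
  p
}

#' Inverted-repeat hits as a mirrored dot plot
#'
#' @param hits Repeat-hit tibble from [find_inverted_repeats()].
#' @return A ggplot.
#' @export
plot_repeat_hits <- function(hits) {
  ggplot2::ggplot(hits) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$a_start, xend = .data$a_end,
                   y = .data$b_end, yend = .data$b_start,
                   colour = .data$identity_pct),
      linewidth = 1.2
    ) +
    ggplot2::scale_colour_viridis_c(name = "identity %") +
    ggplot2::labs(x = "copy A position (bp)", y = "copy B position (bp)",
                  title = "Inverted repeat pairs (anti-diagonal = inverted match)")
}
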