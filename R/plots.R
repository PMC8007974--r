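#' Plot group d-prime means with confidence intervals
#'
#' Point-and-errorbar display of mean d-prime per condition; the dashed line
#' at 0 marks chance discrimination.
#'
#' @param summary A `seg_dprime_summary` from [dprime_summary()].
#' @return A ggplot object.
#' @export
plot_dprime <- function(summary) {
  ggplot2::ggplot(
    summary,
    ggplot2::aes(x = .data$condition, y = .data$mean_d_prime)
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "red") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      width = 0.2
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = NULL, y = "d'", title = "Discrimination of words from part-words") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.seg_dprime_summary <- function(object, ...) plot_dprime(object)

#' Plot proportion correct by condition and stimulus type
#'
#' Dodged points with bootstrap confidence intervals; the dashed line at 0.5
#' marks guessing.
#'
#' @param prop A `seg_prop_correct` from [proportion_correct()].
#' @return A ggplot object.
#' @export
plot_proportion_correct <- function(prop) {
  pd <- ggplot2::position_dodge(width = 0.5)
  ggplot2::ggplot(
    prop,
    ggplot2::aes(
      x = .data$condition, y = .data$prop_correct,
      colour = .data$stimulus_type, group = .data$stimulus_type
    )
  ) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      width = 0.2, position = pd
    ) +
    ggplot2::geom_point(size = 2, position = pd) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = "proportion correct", colour = "stimulus type",
      title = "Correct answers by condition and stimulus type"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.seg_prop_correct <- function(object, ...) plot_proportion_correct(object)

#' Plot the prosodic profile of a stream excerpt
#'
#' Duration-proportional syllable bars at their f0, mirroring the usual
#' schematic of speech-stream conditions; useful for eyeballing that a
#' condition modified only word-final syllables.
#'
#' @param stream A `seg_stream`.
#' @param n_tokens Number of leading tokens to show.
#' @return A ggplot object.
#' @export
plot_stream <- function(stream, n_tokens = 9L) {
  x <- utils::head(stream, n_tokens)
  t_on <- cumsum(c(0, utils::head(x$duration + x$pause_after, -1))) / 1000
  x <- dplyr::mutate(x, t_on = t_on, t_off = t_on + .data$duration / 1000)
  ggplot2::ggplot(x) +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = .data$t_on, xend = .data$t_off, y = .data$f0, yend = .data$f0,
        colour = .data$word
      ),
      linewidth = 3
    ) +
    ggplot2::geom_text(
      ggplot2::aes(x = (.data$t_on + .data$t_off) / 2, y = .data$f0 + 8,
        label = .data$syllable),
      size = 3
    ) +
    ggplot2::labs(
      x = "time (s)", y = "f0 (Hz)", colour = "word",
      title = paste0("Condition: ", stream$condition[1])
    ) +
    ggplot2::theme_minimal()
}
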