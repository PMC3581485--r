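#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the bit-score distributions of a decoy control
#'
#' Reproduces the classic calibration figure: the true-model score
#' distribution as unfilled bars, the reversed-alignment decoy as filled
#' bars, and a vertical line at the sequence inclusion threshold.
#'
#' @param object A `decoy_report`.
#' @param bin_width Histogram bin width in bits (default 2).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot decoy_report
#' @export
autoplot.decoy_report <- function(object, bin_width = 2, ...) {
  h <- tidy(object, bin_width = bin_width)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_start + bin_width / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(
      data = h[h$series == "forward", ],
      fill = NA, colour = "grey20", width = bin_width) +
    ggplot2::geom_col(
      data = h[h$series == "decoy", ],
      fill = "seagreen", alpha = 0.6, width = bin_width) +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 2) +
    ggplot2::scale_y_continuous(trans = "log1p") +
    ggplot2::labs(x = "bit score", y = "sequences",
                  title = "Forward (open) vs reversed-alignment decoy (filled)") +
    ggplot2::theme_minimal()
}

#' Plot per-state information content of a profile HMM
#'
#' @param object A `profile_hmm`.
#' @param ... Unused.
#' @return A ggplot object (relative entropy per match state in bits).
#' @method autoplot profile_hmm
#' @export
autoplot.profile_hmm <- function(object, ...) {
  info <- rowSums(object$match_emissions *
                    log2(sweep(object$match_emissions, 2,
                               object$null_freqs, "/")))
  ggplot2::ggplot(tibble(state = seq_len(object$m), bits = info),
                  ggplot2::aes(.data$state, .data$bits)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "match state", y = "information (bits)") +
    ggplot2::theme_minimal()
}

#' Plot the growth of an iterative search
#'
#' @param object An `iter_search`.
#' @param ... Unused.
#' @return A ggplot object (included sequences per round).
#' @method autoplot iter_search
#' @export
autoplot.iter_search <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(.data$round, .data$n_included)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "round", y = "sequences included") +
    ggplot2::theme_minimal()
}
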