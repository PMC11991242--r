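# ggplot2 views of descriptor sequences and training runs.

#' Plot descriptor windows
#'
#' Descriptor value against time, one line per channel, faceted by source
#' window. Useful for eyeballing how breathing-induced energy modulation
#' differs from fan, arm or curtain motion.
#'
#' @param object A `descriptor_windows` tibble.
#' @param max_windows Plot at most this many windows (first rows).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot descriptor_windows
#' @export
autoplot.descriptor_windows <- function(object, max_windows = 6, ...) {
  shown <- object[seq_len(min(nrow(object), max_windows)), ]
  shown <- new_descriptor_windows(shown, attr(object, "delta_t"),
                                  attr(object, "window_s"),
                                  attr(object, "ts"),
                                  attr(object, "channels"))
  long <- descriptor_long(shown)
  long$panel <- paste0(long$source_id, " w", long$window,
                       " (label ", long$label, ")")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_s, y = .data$value,
                                     colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = "time [s]", y = "differential-chirp mean energy",
                  colour = "channel") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Plot a training run
#'
#' Loss components (cross-entropy, weighted quantization loss) and training
#' accuracy per epoch; the vertical line marks the quantization-loss
#' activation epoch for quantization-aware runs.
#'
#' @param object A `gru_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gru_fit
#' @export
autoplot.gru_fit <- function(object, ...) {
  h <- object$history
  long <- tidyr::pivot_longer(
    h[c("epoch", "cce", "total", "train_accuracy")],
    -"epoch", names_to = "series", values_to = "value"
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                          colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = paste0(format_arch(object$config), " (",
                                 object$route, ")")) +
    ggplot2::theme_minimal(base_size = 9)
  if (!is.null(object$qc)) {
    p <- p + ggplot2::geom_vline(xintercept = object$qc$activation_epoch,
                                 linetype = "dashed", colour = "grey50")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
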