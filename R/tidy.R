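# broom-style accessors for fitted detectors.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted detector
#'
#' @param x A `gru_fit`.
#' @param ... Unused.
#' @return The per-epoch training history as a tibble (`epoch`, `cce`,
#'   `lq`, `lq_weight`, `total`, `train_accuracy`).
#' @method tidy gru_fit
#' @export
tidy.gru_fit <- function(x, ...) {
  x$history
}

#' One-row summary of a fitted detector
#'
#' @param x A `gru_fit`.
#' @param ... Unused.
#' @return One-row tibble: architecture, parameter count, route, epochs,
#'   final losses and training accuracy, quantization bit depth (NA for
#'   float models).
#' @method glance gru_fit
#' @export
glance.gru_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(
    arch = format_arch(x$config),
    n_params = count_params(x$config),
    route = x$route,
    epochs = nrow(x$history),
    final_cce = last$cce,
    final_lq = last$lq,
    train_accuracy = last$train_accuracy,
    bit_depth = if (!is.null(x$quant)) x$quant$qc$bit_depth else NA_integer_
  )
}
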