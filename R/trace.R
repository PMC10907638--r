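#' Voltage/calcium trace container
#'
#' A trace is a tibble with a strictly increasing `time_ms` column, a
#' `V_mV` voltage column and an optional `c_mM` cytosolic-calcium column,
#' carrying a free-form `metadata` attribute (units, provenance, solver
#' settings). Optical recordings use the same container with
#' arbitrary-unit voltage.
#'
#' @param x A data frame with columns `time_ms`, `V_mV` and optionally
#'   `c_mM`.
#' @param metadata Named list stored as the `metadata` attribute.
#' @return A tibble of class `chanreg_trace`.
#' @export
as_trace <- function(x, metadata = list()) {
  x <- tibble::as_tibble(x)
  if (!all(c("time_ms", "V_mV") %in% names(x))) {
    stop("a trace needs `time_ms` and `V_mV` columns", call. = FALSE)
  }
  if (nrow(x) >= 2 && any(diff(x$time_ms) <= 0)) {
    stop("`time_ms` must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(x$time_ms)) || any(!is.finite(x$V_mV))) {
    stop("trace columns must be finite", call. = FALSE)
  }
  class(x) <- unique(c("chanreg_trace", class(x)))
  attr(x, "metadata") <- metadata
  x
}

#' @rdname as_trace
#' @export
is_trace <- function(x) inherits(x, "chanreg_trace")

#' Trace metadata
#' @param x A trace.
#' @return The `metadata` attribute (a list).
#' @export
trace_metadata <- function(x) attr(x, "metadata") %||% list()

#' @importFrom rlang %||%
NULL

#' Plot a voltage (and calcium) trace
#'
#' @param object A trace created by [as_trace()], [run_fixed_n()] or
#'   [synth_optical_trace()].
#' @param ... Unused.
#' @return A ggplot object: voltage over time, with a calcium panel when
#'   the trace carries one.
#' @export
autoplot.chanreg_trace <- function(object, ...) {
  df <- tibble::as_tibble(object)
  long <- tidyr::pivot_longer(
    df, cols = dplyr::any_of(c("V_mV", "c_mM")),
    names_to = "channel", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_ms / 1000,
                                     y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}
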