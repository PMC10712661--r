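#' Uniformly sampled multichannel signal
#'
#' The basic container used by every processing chain: a numeric matrix of
#' samples (rows = time, columns = channels) with a sampling rate in Hz,
#' a unit string and channel labels. Missing samples are `NA`.
#'
#' @param samples numeric vector (single channel) or matrix (time x channel).
#' @param rate sampling rate in Hz, positive scalar.
#' @param units unit string, e.g. `"uS"`, `"mV"`, `"mm"`.
#' @param channels optional character vector of channel labels.
#' @return an object of class `signal_trace`.
#' @export
signal_trace <- function(samples, rate, units = "", channels = NULL) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a positive finite scalar (Hz)")
  if (is.null(dim(samples))) samples <- matrix(as.numeric(samples), ncol = 1L)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (is.null(channels)) {
    channels <- colnames(samples)
    if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(samples)))
  }
  if (length(channels) != ncol(samples))
    stop("`channels` must have one label per column")
  colnames(samples) <- channels
  structure(
    list(samples = samples, rate = rate, units = units, channels = channels),
    class = "signal_trace"
  )
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf(
    "<signal_trace> %d channel(s) x %d samples @ %g Hz (%.6g s)%s\n",
    ncol(x$samples), nrow(x$samples), x$rate, st_duration(x),
    if (nzchar(x$units)) paste0(" [", x$units, "]") else ""
  ))
  invisible(x)
}

#' Sample times of a trace
#'
#' Times in seconds of each row, starting at 0.
#' @param trace a [signal_trace()].
#' @return numeric vector of length `nrow(trace$samples)`.
#' @export
st_times <- function(trace) {
  (seq_len(nrow(trace$samples)) - 1L) / trace$rate
}

#' Duration of a trace in seconds
#' @param trace a [signal_trace()].
#' @return span covered by the samples, `n / rate` seconds.
#' @export
st_duration <- function(trace) nrow(trace$samples) / trace$rate

#' Extract one channel as a numeric vector
#' @param trace a [signal_trace()].
#' @param channel label or column index (default first channel).
#' @export
st_channel <- function(trace, channel = 1L) {
  as.numeric(trace$samples[, channel])
}

#' Cut a trace to a half-open time window
#'
#' Keeps samples with `t_start <= t < t_end` (times relative to the start of
#' the trace). The window convention matches the protocol timeline.
#' @param trace a [signal_trace()].
#' @param t_start,t_end window bounds in seconds.
#' @export
st_window <- function(trace, t_start, t_end) {
  t <- st_times(trace)
  keep <- t >= t_start & t < t_end
  signal_trace(trace$samples[keep, , drop = FALSE], trace$rate,
               units = trace$units, channels = trace$channels)
}

is_signal_trace <- function(x) inherits(x, "signal_trace")

assert_trace <- function(x, what = "trace") {
  if (!is_signal_trace(x)) stop(sprintf("`%s` must be a signal_trace", what))
  invisible(x)
}
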