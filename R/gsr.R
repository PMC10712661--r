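## Electrodermal chain: 2 Hz zero-phase low-pass + decimation to 5 Hz,
## phasic/tonic split by a +/-4 s running median, SCR peak detection by
## threshold crossings on the phasic trace, and the 11 time-domain features.

#' Preprocess a raw GSR trace
#'
#' Order-4 zero-phase Butterworth low-pass at 2 Hz followed by decimation
#' to 5 Hz.
#'
#' @param raw a [signal_trace()] (native 256 Hz in the reference setup; any
#'   rate > 5 Hz works).
#' @param cutoff low-pass cutoff (Hz).
#' @param target_rate output rate (Hz).
#' @return a [signal_trace()] at `target_rate`.
#' @export
preprocess_gsr <- function(raw, cutoff = 2, target_rate = 5) {
  assert_trace(raw, "raw")
  if (raw$rate < target_rate) stop("input rate must be >= the target rate")
  if (nrow(raw$samples) < 4 * raw$rate / cutoff)
    stop("trace too short for the filter padding")
  downsample(zero_phase_lowpass(raw, 4, cutoff), target_rate)
}

#' Split a filtered GSR trace into tonic and phasic components
#'
#' The tonic level at each sample is the median of the samples within
#' +/-4 s (window truncated at the edges, not reflected); the phasic
#' component is the filtered signal minus the tonic, so
#' `filtered = tonic + phasic` holds exactly, samplewise.
#'
#' @param filtered a [signal_trace()] (the 5 Hz preprocessed trace).
#' @param half_window_s median half-window (s).
#' @return a `phasic_decomposition`: list of `filtered`, `tonic`, `phasic`
#'   traces.
#' @export
extract_phasic <- function(filtered, half_window_s = 4) {
  assert_trace(filtered, "filtered")
  if (st_duration(filtered) < 2 * half_window_s)
    stop("trace must cover at least the full median window")
  x <- st_channel(filtered)
  h <- round(half_window_s * filtered$rate)
  tonic <- runmed_truncated_cpp(x, as.integer(h))
  structure(list(
    filtered = filtered,
    tonic = signal_trace(tonic, filtered$rate, units = filtered$units,
                         channels = "tonic"),
    phasic = signal_trace(x - tonic, filtered$rate, units = filtered$units,
                          channels = "phasic")
  ), class = "phasic_decomposition")
}

#' Detect skin conductance response peaks
#'
#' Onsets are upward crossings of the phasic trace above
#' `onset_threshold` (0.01 microsiemens); the offset is the subsequent
#' return of the phasic trace to <= 0 (clamped to the window end if it
#' never returns); the peak is the maximum of the *filtered* signal between
#' onset and offset, and its amplitude is the *phasic* value at that
#' location.
#'
#' @param decomp a `phasic_decomposition` from [extract_phasic()].
#' @param onset_threshold onset crossing level (microsiemens).
#' @return data.frame with one row per SCR: `onset_t`, `peak_t`,
#'   `offset_t`, `amplitude`, `rise_time`, `recovery_time`.
#' @export
detect_scr_peaks <- function(decomp, onset_threshold = 0.01) {
  stopifnot(inherits(decomp, "phasic_decomposition"))
  ph <- st_channel(decomp$phasic)
  fl <- st_channel(decomp$filtered)
  t <- st_times(decomp$filtered)
  n <- length(ph)
  empty <- data.frame(onset_t = numeric(), peak_t = numeric(),
                      offset_t = numeric(), amplitude = numeric(),
                      rise_time = numeric(), recovery_time = numeric())
  if (n < 3) return(empty)
  up <- which(ph[-1] > onset_threshold & ph[-n] <= onset_threshold) + 1L
  if (!length(up)) return(empty)
  rows <- list()
  last_offset <- 0L
  for (i in up) {
    if (i <= last_offset) next  # inside the previous SCR's span
    after <- which(ph[i:n] <= 0)
    offset <- if (length(after)) i + after[1] - 1L else n  # clamp at window end
    if (offset - i < 2L) { last_offset <- offset; next }
    seg <- i:offset
    pk <- seg[which.max(fl[seg])]
    if (pk <= i || pk >= offset && length(after)) pk <- seg[which.max(ph[seg])]
    if (pk <= i) { last_offset <- offset; next }
    rows[[length(rows) + 1L]] <- data.frame(
      onset_t = t[i], peak_t = t[pk], offset_t = t[offset],
      amplitude = ph[pk],
      rise_time = t[pk] - t[i], recovery_time = t[offset] - t[pk])
    last_offset <- offset
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Time-domain GSR features over a window
#'
#' The 11 electrodermal features: SCR count, mean peak amplitude, mean rise
#' and recovery times, mean and s.d. of the filtered signal, maximum signed
#' amplitude between consecutive maxima of the 0.5-1 Hz band-passed signal,
#' mean/s.d./max of the first derivative, and the time-average of the
#' running integral of the phasic component (AVenv). Peak-dependent
#' features are `NA` (not zero) when the window contains no SCR.
#'
#' @param decomp a `phasic_decomposition`.
#' @param peaks SCR table from [detect_scr_peaks()].
#' @param window `c(t_start, t_end)` in trace time (s); default the whole
#'   trace.
#' @return one-row data.frame with the 11 features.
#' @export
gsr_features <- function(decomp, peaks = detect_scr_peaks(decomp),
                         window = NULL) {
  stopifnot(inherits(decomp, "phasic_decomposition"))
  rate <- decomp$filtered$rate
  t <- st_times(decomp$filtered)
  if (is.null(window)) window <- c(0, st_duration(decomp$filtered))
  if (window[1] < -1e-9 || window[2] > st_duration(decomp$filtered) + 1e-9)
    stop("window must lie within the trace span")
  keep <- t >= window[1] & t < window[2]
  f <- st_channel(decomp$filtered)[keep]
  ph <- st_channel(decomp$phasic)[keep]
  if (length(f) < 3) stop("window contains too few samples")
  pk <- peaks[peaks$peak_t >= window[1] & peaks$peak_t < window[2], , drop = FALSE]
  n_peaks <- nrow(pk)
  # 0.5-1 Hz band-passed signal for the signed-amplitude feature
  msa <- NA_real_
  if (length(f) >= 12 && rate > 2) {
    bp <- st_channel(bandpass(signal_trace(f, rate), 2, 0.5, min(1, rate / 2 - 1e-6)))
    mx <- which(diff(sign(diff(bp))) < 0) + 1L  # local maxima
    if (length(mx) >= 2) {
      drops <- vapply(seq_len(length(mx) - 1L), function(k) {
        bp[mx[k]] - min(bp[mx[k]:mx[k + 1L]])
      }, numeric(1))
      msa <- max(drops)
    }
  }
  d <- diff(f) * rate
  cumint <- cumsum((utils::head(ph, -1) + utils::tail(ph, -1)) / 2) / rate
  data.frame(
    n_peaks = n_peaks,
    amp_peaks_mean = if (n_peaks) mean(pk$amplitude) else NA_real_,
    rise_time_mean = if (n_peaks) mean(pk$rise_time) else NA_real_,
    recovery_time_mean = if (n_peaks) mean(pk$recovery_time) else NA_real_,
    avg = mean(f), sd = stats::sd(f),
    max_signed_amp = msa,
    deriv_avg = mean(d), deriv_sd = stats::sd(d), deriv_max = max(d),
    env_avg = mean(c(0, cumint))
  )
}
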