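## Pupillometry chain: two-eye blink handling (out-of-range samples are
## blinks: substitute the other eye, then interpolate joint gaps), 5 Hz
## anti-aliased decimation to 10 Hz of the two-eye average diameter, and
## time/frequency features from the Welch periodogram of the detrended
## diameter (300-sample Hamming segments).

#' Clean and merge two-eye pupil traces into one diameter trace
#'
#' Samples outside the physiological 2-8 mm range are treated as blinks:
#' where exactly one eye is missing its sample is replaced by the other
#' eye's, where both are missing the gap is linearly interpolated (nearest
#' valid value at the trace edges, with a warning). The cleaned eyes are
#' averaged, low-pass filtered at 5 Hz (order-4 zero-phase) and decimated
#' to 10 Hz.
#'
#' @param left,right [signal_trace()]s in mm at the same rate and length.
#' @param range physiological diameter range `c(lo, hi)` in mm.
#' @param cutoff anti-aliasing cutoff (Hz).
#' @param target_rate output rate (Hz).
#' @return a single-channel [signal_trace()] `diameter` at `target_rate`.
#' @export
clean_pupil <- function(left, right, range = c(2, 8), cutoff = 5,
                        target_rate = 10) {
  assert_trace(left, "left"); assert_trace(right, "right")
  if (left$rate != right$rate || nrow(left$samples) != nrow(right$samples))
    stop("left and right traces must share rate and length")
  l <- st_channel(left); r <- st_channel(right)
  l[l < range[1] | l > range[2]] <- NA
  r[r < range[1] | r > range[2]] <- NA
  if (all(is.na(l)) && all(is.na(r)))
    stop("no valid samples in either eye")
  # one-eye blinks: copy the other eye
  only_l <- is.na(l) & !is.na(r)
  only_r <- is.na(r) & !is.na(l)
  l[only_l] <- r[only_l]
  r[only_r] <- l[only_r]
  # joint blinks: linear interpolation per eye
  n <- length(l)
  if (is.na(l[1]) || is.na(l[n]) || is.na(r[1]) || is.na(r[n]))
    warning("blink at trace edge; nearest-valid extrapolation used")
  fill <- function(x) {
    if (!anyNA(x)) return(x)
    idx <- which(!is.na(x))
    stats::approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
  }
  l <- fill(l); r <- fill(r)
  d <- (l + r) / 2
  tr <- signal_trace(d, left$rate, units = "mm", channels = "diameter")
  downsample(zero_phase_lowpass(tr, 4, cutoff), target_rate)
}

#' Pupil diameter features over a window
#'
#' Time features: mean (AVD) and standard deviation (SDD) of the diameter.
#' Frequency features, when the window holds at least one full Welch
#' segment (300 samples = 30 s at 10 Hz): band powers of the linearly
#' detrended diameter in DLF [0.05, 0.15) Hz, DHF [0.15, 0.45) Hz and DVHF
#' [0.45, 1.5) Hz, the DLF/DHF balance, and the normalized DLFn/DHFn (DVHF
#' is reported unnormalized only). Spectral features are `NA` on shorter
#' windows.
#'
#' @param diameter a [signal_trace()] from [clean_pupil()].
#' @param window optional `c(t_start, t_end)` seconds; default whole trace.
#' @param segment_samples Welch segment length in samples.
#' @param overlap_fraction Welch overlap.
#' @return one-row data.frame: `avd`, `sdd`, `dlf`, `dhf`, `dvhf`,
#'   `dlf_dhf`, `dlfn`, `dhfn`.
#' @export
pupil_features <- function(diameter, window = NULL, segment_samples = 300,
                           overlap_fraction = 0.5) {
  assert_trace(diameter, "diameter")
  if (!is.null(window)) diameter <- st_window(diameter, window[1], window[2])
  x <- st_channel(diameter)
  out <- data.frame(avd = mean(x), sdd = stats::sd(x),
                    dlf = NA_real_, dhf = NA_real_, dvhf = NA_real_,
                    dlf_dhf = NA_real_, dlfn = NA_real_, dhfn = NA_real_)
  if (length(x) < segment_samples) return(out)
  # linear detrend, then Welch with Hamming segments
  tt <- seq_along(x)
  x <- x - stats::fitted(stats::lm(x ~ tt))
  ps <- welch_psd(signal_trace(x, diameter$rate), segment_samples,
                  overlap_fraction, "hamming", detrend = TRUE)
  out$dlf <- band_power(ps, 0.05, 0.15)
  out$dhf <- band_power(ps, 0.15, 0.45)
  out$dvhf <- band_power(ps, 0.45, min(1.5, diameter$rate / 2 - 1e-9))
  out$dlf_dhf <- if (out$dhf > 0) out$dlf / out$dhf else NA_real_
  s <- out$dlf + out$dhf
  if (s > 0) { out$dlfn <- out$dlf / s; out$dhfn <- out$dhf / s }
  out
}
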