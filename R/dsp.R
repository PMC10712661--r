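## Shared signal-processing primitives: Butterworth design (second-order
## sections via bilinear transform), zero-phase filtering, decimation,
## Welch spectra and band-power integrals. No external DSP dependency:
## contracts here must be bit-stable across platforms.

# ---- Butterworth design -----------------------------------------------------

# Analog Butterworth prototype poles (unit cutoff, all-pole, DC gain 1).
butter_prototype_poles <- function(order) {
  k <- seq_len(order)
  exp(1i * pi * (2 * k + order - 1) / (2 * order))
}

# Second-order-section Butterworth design.
# type "low": `cutoff` is a scalar Hz; type "band": `cutoff` is c(low, high).
# Returns nsec x 6 matrix with rows (b0, b1, b2, 1, a1, a2).
butter_sos <- function(order, cutoff, rate, type = c("low", "band")) {
  type <- match.arg(type)
  if (order < 1L) stop("filter order must be >= 1")
  if (any(cutoff <= 0) || any(cutoff >= rate / 2))
    stop("cutoff frequencies must lie in (0, rate/2)")
  fs2 <- 2 * rate
  warp <- function(f) fs2 * tan(pi * f / rate)
  proto <- butter_prototype_poles(order)

  if (type == "low") {
    wc <- warp(cutoff)
    poles_a <- wc * proto
    # H(s) = wc^n / prod(s - p); bilinear s = fs2 (z-1)/(z+1)
    poles_z <- (fs2 + poles_a) / (fs2 - poles_a)
    gain <- Re(wc^order / prod(fs2 - poles_a))
    zeros_z <- rep(-1, order)
  } else {
    if (length(cutoff) != 2L || cutoff[1] >= cutoff[2])
      stop("band cutoff must be c(low, high) with low < high")
    w1 <- warp(cutoff[1]); w2 <- warp(cutoff[2])
    w0 <- sqrt(w1 * w2); bw <- w2 - w1
    # LP->BP: each prototype pole yields the roots of s^2 - bw*p*s + w0^2
    poles_a <- complex(0)
    for (p in proto) {
      d <- sqrt((bw * p)^2 / 4 - w0^2 + 0i)
      poles_a <- c(poles_a, bw * p / 2 + d, bw * p / 2 - d)
    }
    poles_z <- (fs2 + poles_a) / (fs2 - poles_a)
    # H(s) = (bw s)^n / prod(s - p_i); digital zeros: n at +1, n at -1
    gain <- Re((bw * fs2)^order / prod(fs2 - poles_a))
    zeros_z <- c(rep(1, order), rep(-1, order))
  }

  sos_from_zpk(zeros_z, poles_z, gain)
}

# Pair conjugate poles/zeros into biquads. Poles arrive as conjugate pairs
# (plus one real pole for odd-order lowpass); zeros are real (+1/-1).
sos_from_zpk <- function(zeros, poles, gain) {
  ord_p <- order(abs(Im(poles)) < 1e-12, -abs(poles))  # complex pairs first
  poles <- poles[ord_p]
  np <- length(poles)
  used <- rep(FALSE, np)
  pairs <- list()
  for (i in seq_len(np)) {
    if (used[i]) next
    used[i] <- TRUE
    if (abs(Im(poles[i])) > 1e-12) {
      j <- which(!used & abs(poles - Conj(poles[i])) < 1e-8)[1]
      if (is.na(j)) stop("unpaired complex pole; design error")
      used[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- c(poles[i], poles[j])
    } else {
      pairs[[length(pairs) + 1L]] <- poles[i]
    }
  }
  # distribute zeros two per section (one per section for a real pole)
  zq <- zeros
  # alternate +1/-1 zeros so each bandpass section is (z-1)(z+1)
  zq <- zq[order(seq_along(zq) %% 2)]
  if (length(zeros) > 0 && all(sort(unique(round(Re(zeros)))) %in% c(-1, 1)) &&
      any(Re(zeros) > 0) && any(Re(zeros) < 0)) {
    zq <- as.numeric(rbind(zeros[Re(zeros) > 0], zeros[Re(zeros) < 0]))
  }
  sos <- matrix(0, nrow = length(pairs), ncol = 6)
  zi <- 1L
  for (s in seq_along(pairs)) {
    pp <- pairs[[s]]
    if (length(pp) == 2L) {
      a <- c(1, -Re(pp[1] + pp[2]), Re(pp[1] * pp[2]))
      take <- min(2L, max(0L, length(zq) - zi + 1L))
      zz <- if (take > 0) zq[zi:(zi + take - 1L)] else complex(0)
      zi <- zi + take
      b <- switch(as.character(length(zz)),
                  "0" = c(1, 0, 0),
                  "1" = c(1, -Re(zz), 0),
                  "2" = c(1, -Re(zz[1] + zz[2]), Re(zz[1] * zz[2])))
    } else {
      a <- c(1, -Re(pp), 0)
      take <- min(1L, max(0L, length(zq) - zi + 1L))
      zz <- if (take > 0) zq[zi:(zi + take - 1L)] else complex(0)
      zi <- zi + take
      b <- if (length(zz)) c(1, -Re(zz), 0) else c(1, 0, 0)
    }
    sos[s, ] <- c(b, a)
  }
  sos[1, 1:3] <- sos[1, 1:3] * gain
  sos
}

# Frequency response of an SOS cascade at frequencies f (Hz).
sos_freqz <- function(sos, f, rate) {
  z <- exp(-1i * 2 * pi * f / rate)
  h <- rep(1 + 0i, length(f))
  for (s in seq_len(nrow(sos))) {
    num <- sos[s, 1] + sos[s, 2] * z + sos[s, 3] * z^2
    den <- sos[s, 4] + sos[s, 5] * z + sos[s, 6] * z^2
    h <- h * num / den
  }
  h
}

# Steady-state (step-response) internal state of the cascade for unit input;
# used to suppress start-up transients in the zero-phase wrapper.
sos_step_zi <- function(sos) {
  ns <- nrow(sos)
  zi <- matrix(0, ns, 2)
  xin <- 1
  for (s in seq_len(ns)) {
    b <- sos[s, 1:3]; a <- sos[s, 4:6]
    h <- sum(b) / sum(a)
    zi[s, 1] <- (h - b[1]) * xin
    zi[s, 2] <- (b[3] - a[3] * h) * xin
    xin <- xin * h
  }
  zi
}

# Zero-phase (forward-backward) filtering of one channel with odd-reflection
# padding; pad length ~three time constants of the slowest band edge.
filtfilt_sos <- function(sos, x, padlen) {
  n <- length(x)
  padlen <- max(6L, min(n - 1L, as.integer(padlen)))
  if (n <= 3L) return(x)
  pre <- 2 * x[1] - x[(padlen + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - padlen)]
  xe <- c(pre, x, post)
  zi <- sos_step_zi(sos)
  y <- sosfilt_cpp(sos, xe, zi * xe[1])
  y <- rev(y)
  y <- sosfilt_cpp(sos, y, zi * y[1])
  y <- rev(y)
  y[(padlen + 1L):(padlen + n)]
}

apply_filter_trace <- function(trace, sos, padlen) {
  out <- trace$samples
  for (j in seq_len(ncol(out))) out[, j] <- filtfilt_sos(sos, out[, j], padlen)
  signal_trace(out, trace$rate, units = trace$units, channels = trace$channels)
}

# ---- User-facing dsp operations --------------------------------------------

#' Zero-phase Butterworth low-pass filter
#'
#' Applies an order-`order` Butterworth low-pass forward and backward
#' (two passes, so the magnitude at the cutoff is ~0.5 rather than -3 dB),
#' with odd-reflection padding to suppress edge transients. Length, rate and
#' units are preserved.
#'
#' @param trace a [signal_trace()].
#' @param order filter order of a single pass.
#' @param cutoff -3 dB cutoff frequency (Hz) of a single pass; must be below
#'   the Nyquist frequency.
#' @return the filtered [signal_trace()].
#' @export
zero_phase_lowpass <- function(trace, order, cutoff) {
  assert_trace(trace)
  if (cutoff >= trace$rate / 2) stop("cutoff must be below the Nyquist frequency")
  sos <- butter_sos(order, cutoff, trace$rate, "low")
  apply_filter_trace(trace, sos, padlen = ceiling(9 * trace$rate / cutoff))
}

#' Zero-phase Butterworth band-pass filter
#'
#' @param trace a [signal_trace()].
#' @param order order of the low-pass prototype (the band-pass has `2*order`
#'   poles per pass).
#' @param low,high band edges in Hz, `0 < low < high < rate/2`.
#' @return the filtered [signal_trace()].
#' @export
bandpass <- function(trace, order, low, high) {
  assert_trace(trace)
  if (!(low > 0 && low < high && high < trace$rate / 2))
    stop("band edges must satisfy 0 < low < high < rate/2")
  sos <- butter_sos(order, c(low, high), trace$rate, "band")
  apply_filter_trace(trace, sos, padlen = ceiling(9 * trace$rate / low))
}

#' Decimate a trace to a lower rate
#'
#' Nearest-index selection onto the target grid. Anti-aliasing is the
#' caller's responsibility (the per-signal chains low-pass first, matching
#' the two-step convention of the acquisition pipeline).
#'
#' @param trace a [signal_trace()].
#' @param target_rate new rate in Hz, `<= rate`.
#' @return a [signal_trace()] at `target_rate`.
#' @export
downsample <- function(trace, target_rate) {
  assert_trace(trace)
  if (target_rate > trace$rate) stop("target rate exceeds the trace rate")
  if (target_rate == trace$rate) return(trace)
  n <- nrow(trace$samples)
  t_out <- seq(0, (n - 1) / trace$rate, by = 1 / target_rate)
  idx <- pmin(n, round(t_out * trace$rate) + 1L)
  signal_trace(trace$samples[idx, , drop = FALSE], target_rate,
               units = trace$units, channels = trace$channels)
}

#' Welch power spectral density
#'
#' One-sided PSD averaged over Hamming-windowed, overlapping segments with
#' density scaling (integrating the PSD over frequency recovers the signal
#' variance up to windowing tolerance).
#'
#' @param trace a [signal_trace()] (all channels are processed).
#' @param segment_len segment length in samples.
#' @param overlap_fraction fractional overlap between consecutive segments
#'   (default 0.5).
#' @param window taper; only `"hamming"` and `"hann"` are provided.
#' @param detrend remove each segment's mean before transforming.
#' @return a `spectrum_psd` object: list with `frequencies` (Hz) and
#'   `density` (matrix, one column per channel, units^2 per Hz).
#' @export
welch_psd <- function(trace, segment_len, overlap_fraction = 0.5,
                      window = c("hamming", "hann"), detrend = TRUE) {
  assert_trace(trace)
  window <- match.arg(window)
  n <- nrow(trace$samples)
  segment_len <- as.integer(segment_len)
  if (segment_len < 8L) stop("segment_len must be >= 8 samples")
  if (segment_len > n) stop("segment_len exceeds the trace length")
  step <- max(1L, as.integer(round(segment_len * (1 - overlap_fraction))))
  starts <- seq(1L, n - segment_len + 1L, by = step)
  k <- seq_len(segment_len) - 1L
  w <- switch(window,
              hamming = 0.54 - 0.46 * cos(2 * pi * k / (segment_len - 1)),
              hann = 0.5 - 0.5 * cos(2 * pi * k / (segment_len - 1)))
  u <- sum(w^2)
  nf <- segment_len %/% 2L + 1L
  freqs <- (seq_len(nf) - 1L) * trace$rate / segment_len
  dens <- matrix(0, nf, ncol(trace$samples))
  for (j in seq_len(ncol(trace$samples))) {
    acc <- numeric(nf)
    for (s in starts) {
      seg <- trace$samples[s:(s + segment_len - 1L), j]
      if (detrend) seg <- seg - mean(seg)
      X <- stats::fft(seg * w)[seq_len(nf)]
      p <- (Mod(X)^2) / (trace$rate * u)
      # one-sided: double everything except DC and (for even lengths) Nyquist
      dbl <- rep(2, nf); dbl[1] <- 1
      if (segment_len %% 2L == 0L) dbl[nf] <- 1
      acc <- acc + p * dbl
    }
    dens[, j] <- acc / length(starts)
  }
  colnames(dens) <- trace$channels
  structure(list(frequencies = freqs, density = dens,
                 channels = trace$channels),
            class = "spectrum_psd")
}

#' Integrate a PSD over a frequency band
#'
#' Trapezoidal integral of the density over `[low, high)`, with linear
#' interpolation of the density at the exact band edges so that adjacent
#' half-open bands partition the total power.
#'
#' @param spectrum a `spectrum_psd` from [welch_psd()] (or any list with
#'   `frequencies` and `density`).
#' @param low,high band edges in Hz.
#' @param channel column index or label (default 1).
#' @return band power (units^2).
#' @export
band_power <- function(spectrum, low, high, channel = 1L) {
  f <- spectrum$frequencies
  d <- if (is.matrix(spectrum$density)) spectrum$density[, channel] else spectrum$density
  if (low >= high) stop("band requires low < high")
  lo <- max(low, f[1]); hi <- min(high, f[length(f)])
  if (lo >= hi) return(0)
  inside <- f > lo & f < hi
  fi <- c(lo, f[inside], hi)
  di <- c(stats::approx(f, d, xout = lo)$y, d[inside],
          stats::approx(f, d, xout = hi)$y)
  sum(diff(fi) * (utils::head(di, -1) + utils::tail(di, -1)) / 2)
}
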