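## Synthetic multimodal recordings with known ground truth. Each generator
## emulates exactly the statistical structure its analysis chain assumes
## (and no more): RR intervals from a history-dependent inverse-Gaussian
## process with AR-modulated mean, SCRs as bi-exponential kernels on a tonic
## level, a stylized pulse waveform delayed from the R-peaks by a
## controllable arrival time, EEG as band-limited noise with set per-band /
## per-region powers, and pupil diameter with blinks and slow oscillations.

# ---- ground-truth records ---------------------------------------------------

#' Ground truth for the heartbeat point process
#'
#' @param theta0 baseline mean interval contribution (s).
#' @param ar_coeffs AR coefficients on the previous intervals (the implied
#'   stationary mean is `theta0 / (1 - sum(ar_coeffs))`).
#' @param lambda inverse-Gaussian shape (s); interval variance is
#'   `mu^3 / lambda`.
#' @param mean_modulation list of `c(frequency_hz, relative_amplitude)`
#'   sinusoids applied multiplicatively to `theta0` over time.
#' @export
rr_ground_truth <- function(theta0 = 0.8, ar_coeffs = numeric(0),
                            lambda = 200, mean_modulation = list()) {
  if (lambda <= 0) stop("lambda must be positive")
  if (theta0 <= 0) stop("theta0 must be positive")
  if (length(ar_coeffs) && !ar_stable(ar_coeffs))
    stop("AR coefficients are unstable (characteristic root inside the unit circle)")
  structure(list(theta0 = theta0, ar_coeffs = ar_coeffs, lambda = lambda,
                 mean_modulation = mean_modulation),
            class = "rr_ground_truth")
}

# Stability of 1 - sum(theta_i z^-i): all roots of the characteristic
# polynomial must lie outside the unit circle.
ar_stable <- function(ar_coeffs) {
  r <- polyroot(c(1, -ar_coeffs))
  all(Mod(r) > 1 + 1e-10)
}

#' Ground truth for electrodermal activity
#'
#' SCR events superposed on a tonic level. The default bi-exponential kernel
#' (`rise_tau` 0.3 s, `decay_tau` 1.2 s) is a fast-recovery SCR shape chosen
#' so the +/-4 s median-filter tonic estimate used downstream is unbiased at
#' the peak (see the methods vignette).
#'
#' @param event_times SCR onset times (s).
#' @param amplitudes peak amplitudes (microsiemens), one per event.
#' @param rise_tau,decay_tau kernel time constants (s), `decay_tau > rise_tau`.
#' @param tonic_level baseline conductance (microsiemens).
#' @export
scr_ground_truth <- function(event_times = numeric(0), amplitudes = numeric(0),
                             rise_tau = 0.3, decay_tau = 1.2,
                             tonic_level = 2) {
  if (length(event_times) != length(amplitudes))
    stop("one amplitude per event is required")
  if (any(amplitudes <= 0)) stop("amplitudes must be positive")
  if (!(decay_tau > rise_tau && rise_tau > 0))
    stop("decay_tau > rise_tau > 0 is required")
  o <- order(event_times)
  structure(list(event_times = event_times[o], amplitudes = amplitudes[o],
                 rise_tau = rise_tau, decay_tau = decay_tau,
                 tonic_level = tonic_level),
            class = "scr_ground_truth")
}

#' Ground truth for the pulse waveform
#'
#' @param pat pulse arrival time: delay from each R-peak to the pulse onset
#'   (steepest point of the upstroke), seconds.
#' @param vp_amplitude systolic-minus-diastolic amplitude (arbitrary units).
#' @param rise_s,decay_s upstroke and decay durations of the stylized pulse.
#' @export
bvp_ground_truth <- function(pat = 0.25, vp_amplitude = 1.0,
                             rise_s = 0.12, decay_s = 0.35) {
  if (pat <= 0) stop("pat must be positive")
  if (vp_amplitude < 0) stop("vp_amplitude must be non-negative")
  structure(list(pat = pat, vp_amplitude = vp_amplitude,
                 rise_s = rise_s, decay_s = decay_s),
            class = "bvp_ground_truth")
}

EEG_BANDS <- list(delta = c(1, 3), theta = c(4, 7),
                  alpha = c(8, 12), beta = c(16, 38))

#' Ground truth for EEG band powers
#'
#' Target integrated power per region and band. Rows `frontal`, `parietal`
#' and `other` (all remaining scalp channels); columns delta, theta, alpha,
#' beta. Defaults follow the usual 1/f-like ordering.
#'
#' @param powers numeric matrix (regions x bands, uV^2).
#' @export
eeg_ground_truth <- function(powers = NULL) {
  if (is.null(powers)) {
    powers <- rbind(frontal = c(delta = 40, theta = 20, alpha = 15, beta = 10),
                    parietal = c(delta = 35, theta = 18, alpha = 25, beta = 8),
                    other = c(delta = 35, theta = 18, alpha = 18, beta = 8))
  }
  if (any(powers < 0)) stop("band powers must be non-negative")
  if (!all(c("frontal", "parietal") %in% rownames(powers)))
    stop("powers must have 'frontal' and 'parietal' rows")
  if (!all(names(EEG_BANDS) %in% colnames(powers)))
    stop("powers must have delta/theta/alpha/beta columns")
  structure(list(powers = powers), class = "eeg_ground_truth")
}

#' Ground truth for the pupillary signal
#'
#' @param baseline mean diameter, mm (must lie in the physiological 2-8 mm
#'   range).
#' @param oscillations list of `c(frequency_hz, amplitude_mm)` components
#'   common to both eyes.
#' @param blink_left,blink_right lists of `c(start, end)` blink intervals in
#'   seconds, per eye.
#' @param noise_sd per-eye independent measurement noise (mm).
#' @export
pupil_ground_truth <- function(baseline = 5, oscillations = list(),
                               blink_left = list(), blink_right = list(),
                               noise_sd = 0.02) {
  if (baseline < 2 || baseline > 8)
    stop("baseline must lie in the physiological range [2, 8] mm")
  structure(list(baseline = baseline, oscillations = oscillations,
                 blink_left = blink_left, blink_right = blink_right,
                 noise_sd = noise_sd),
            class = "pupil_ground_truth")
}

# ---- RR interval generator --------------------------------------------------

# Exact inverse-Gaussian sampler (transform with rejection,
# Michael-Schucany-Haas). Vector of n draws with mean mu, shape lambda.
rinvgauss_ms <- function(n, mu, lambda) {
  v <- stats::rnorm(n)^2
  x <- mu + mu^2 * v / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * v + mu^2 * v^2)
  u <- stats::runif(n)
  ifelse(u <= mu / (mu + x), x, mu^2 / x)
}

#' Simulate RR intervals from the history-dependent inverse-Gaussian model
#'
#' Each interval is drawn from an inverse-Gaussian with shape `lambda` and
#' mean `theta0(t) + sum_i ar_coeffs[i] * RR_(k-i)` where `theta0(t)` is
#' `theta0` times the sinusoidal modulation evaluated at the current time
#' (and times `mod_fun(t)` if supplied). History is initialized at the
#' stationary mean.
#'
#' @param duration length of the generated series (s).
#' @param truth an [rr_ground_truth()].
#' @param seed integer seed (NULL = use current RNG state).
#' @param t0 time of the first R event (s).
#' @param mod_fun optional function of time returning an extra multiplicative
#'   factor on `theta0` (used for per-phase effects).
#' @return an `rr_series`: list with `r_times`, `intervals`, and the
#'   realized per-event `mu_trajectory`.
#' @export
simulate_rr_ig <- function(duration, truth = rr_ground_truth(), seed = NULL,
                           t0 = 0, mod_fun = NULL) {
  stopifnot(inherits(truth, "rr_ground_truth"))
  with_seed(seed, {
    p <- length(truth$ar_coeffs)
    s_ar <- sum(truth$ar_coeffs)
    mu_stat <- truth$theta0 / (1 - s_ar)
    hist_rr <- rep(mu_stat, max(p, 1))
    t <- t0
    r_times <- t0
    intervals <- numeric(0)
    mu_traj <- numeric(0)
    modulate <- function(tt) {
      m <- 1
      for (cmp in truth$mean_modulation)
        m <- m + cmp[2] * sin(2 * pi * cmp[1] * tt)
      if (!is.null(mod_fun)) m <- m * mod_fun(tt)
      m
    }
    repeat {
      th0 <- truth$theta0 * modulate(t)
      mu <- th0 + if (p > 0) sum(truth$ar_coeffs * hist_rr[seq_len(p)]) else 0
      mu <- max(mu, 0.05)
      rr <- rinvgauss_ms(1, mu, truth$lambda)
      rr <- min(max(rr, 1e-3), 5)
      t <- t + rr
      if (t > t0 + duration) break
      r_times <- c(r_times, t)
      intervals <- c(intervals, rr)
      mu_traj <- c(mu_traj, mu)
      if (p > 0) hist_rr <- c(rr, hist_rr)[seq_len(max(p, 1))]
    }
    rr_series(r_times, mu_trajectory = mu_traj, truth = truth)
  })
}

#' RR event series
#'
#' @param r_times strictly increasing R-event times (s).
#' @param mu_trajectory optional realized per-interval model means.
#' @param truth optional generator ground truth, kept for recovery tests.
#' @return an `rr_series` with `r_times` and `intervals = diff(r_times)`.
#' @export
rr_series <- function(r_times, mu_trajectory = NULL, truth = NULL) {
  r_times <- as.numeric(r_times)
  if (is.unsorted(r_times, strictly = TRUE))
    stop("r_times must be strictly increasing")
  structure(list(r_times = r_times, intervals = diff(r_times),
                 mu_trajectory = mu_trajectory, truth = truth),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d beats over %.1f s (mean RR %.3f s)\n",
              length(x$r_times),
              if (length(x$r_times)) diff(range(x$r_times)) else 0,
              mean(x$intervals)))
  invisible(x)
}

# ---- GSR generator ----------------------------------------------------------

scr_kernel <- function(t, rise_tau, decay_tau) {
  t_peak <- log(decay_tau / rise_tau) * rise_tau * decay_tau / (decay_tau - rise_tau)
  peak <- exp(-t_peak / decay_tau) - exp(-t_peak / rise_tau)
  k <- ifelse(t < 0, 0, exp(-t / decay_tau) - exp(-t / rise_tau))
  k / peak
}

#' Simulate a galvanic skin response trace
#'
#' Tonic level plus one normalized bi-exponential kernel per SCR event
#' (unit peak scaled to the event amplitude) plus white measurement noise.
#'
#' @param truth an [scr_ground_truth()].
#' @param duration trace length (s).
#' @param rate sampling rate (Hz, >= 10).
#' @param seed integer seed for the noise.
#' @param noise_sd measurement noise s.d. (microsiemens).
#' @return a [signal_trace()] in microsiemens.
#' @export
simulate_gsr <- function(truth = scr_ground_truth(), duration, rate = 256,
                         seed = NULL, noise_sd = 0.003) {
  stopifnot(inherits(truth, "scr_ground_truth"))
  if (rate < 10) stop("rate must be >= 10 Hz")
  if (length(truth$event_times) &&
      (any(truth$event_times < 0) || any(truth$event_times >= duration)))
    stop("SCR events must lie inside [0, duration)")
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  x <- rep(truth$tonic_level, n)
  for (i in seq_along(truth$event_times)) {
    x <- x + truth$amplitudes[i] *
      scr_kernel(t - truth$event_times[i], truth$rise_tau, truth$decay_tau)
  }
  if (noise_sd > 0) x <- x + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  signal_trace(x, rate, units = "uS", channels = "GSR")
}

# ---- ECG + BVP generator ----------------------------------------------------

gauss_bump <- function(t, center, width, amp) {
  amp * exp(-0.5 * ((t - center) / width)^2)
}

#' Simulate coupled ECG and blood volume pulse traces
#'
#' The ECG is a stylized spike train with one dominant R wave per event
#' (optionally with textbook P and T waves). The BVP places, per beat, a
#' sinusoidal upstroke whose steepest point (the detected pulse onset) falls
#' exactly `pat` seconds after the R-peak, a systolic maximum
#' `vp_amplitude` above the diastolic level, and a smooth decay back to the
#' diastolic level.
#'
#' @param rr an `rr_series` (may be empty).
#' @param truth a [bvp_ground_truth()]; `pat` must be below the minimum RR
#'   interval.
#' @param rate output rate (Hz) for both traces.
#' @param duration trace length (s); default covers the last beat + 1 s.
#' @param ecg_template `"spike"` (default) or `"textbook"` (adds P/T waves).
#' @return list with `ecg` and `bvp` [signal_trace()]s.
#' @export
simulate_ecg_bvp <- function(rr, truth = bvp_ground_truth(), rate = 2048,
                             duration = NULL, ecg_template = c("spike", "textbook")) {
  stopifnot(inherits(rr, "rr_series"), inherits(truth, "bvp_ground_truth"))
  ecg_template <- match.arg(ecg_template)
  if (length(rr$intervals) && truth$pat >= min(rr$intervals))
    stop("pat must be below the minimum RR interval")
  if (is.null(duration)) {
    duration <- if (length(rr$r_times)) max(rr$r_times) + 1 else 1
  }
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  ecg <- numeric(n); bvp <- numeric(n)
  for (rt in rr$r_times) {
    lo <- max(1L, floor((rt - 0.4) * rate)); hi <- min(n, ceiling((rt + 0.6) * rate))
    if (lo > n || hi < 1) next
    idx <- lo:hi; ti <- t[idx]
    ecg[idx] <- ecg[idx] + gauss_bump(ti, rt, 0.01, 1.0)
    if (ecg_template == "textbook") {
      ecg[idx] <- ecg[idx] + gauss_bump(ti, rt - 0.16, 0.025, 0.15) +
        gauss_bump(ti, rt + 0.30, 0.05, 0.25)
    }
    # pulse: upstroke centered (steepest) at rt + pat, then cosine decay
    tc <- rt + truth$pat
    rise <- truth$rise_s; dec <- truth$decay_s
    up <- ti >= tc - rise / 2 & ti < tc + rise / 2
    bvp[idx[up]] <- bvp[idx[up]] +
      truth$vp_amplitude * (1 + sin(pi * (ti[up] - tc) / rise)) / 2
    ts <- tc + rise / 2
    dn <- ti >= ts & ti < ts + dec
    bvp[idx[dn]] <- bvp[idx[dn]] +
      truth$vp_amplitude * (1 + cos(pi * (ti[dn] - ts) / dec)) / 2
  }
  list(ecg = signal_trace(ecg, rate, units = "mV", channels = "ECG"),
       bvp = signal_trace(bvp, rate, units = "au", channels = "BVP"))
}

# ---- EEG generator ----------------------------------------------------------

#' Simulate a 21-channel EEG recording with set band powers
#'
#' Each channel is a sum over the delta/theta/alpha/beta bands of band-pass
#' filtered white noise rescaled so its integrated power matches the target
#' for the channel's region (frontal, parietal, or other).
#'
#' @param truth an [eeg_ground_truth()].
#' @param duration trace length (s).
#' @param rate sampling rate (Hz).
#' @param montage a [montage_1020()].
#' @param seed integer seed.
#' @param gain_envelope optional function(band, region, t) returning a
#'   multiplicative amplitude envelope (used for per-session effects).
#' @return a 21-channel [signal_trace()].
#' @export
simulate_eeg <- function(truth = eeg_ground_truth(), duration, rate = 300,
                         montage = montage_1020(), seed = NULL,
                         gain_envelope = NULL) {
  stopifnot(inherits(truth, "eeg_ground_truth"))
  n <- round(duration * rate)
  labels <- montage$labels
  with_seed(seed, {
    out <- matrix(0, n, length(labels))
    t <- (seq_len(n) - 1) / rate
    for (j in seq_along(labels)) {
      region <- channel_region(labels[j], montage)
      if (!region %in% rownames(truth$powers)) region <- "other"
      x <- numeric(n)
      for (b in names(EEG_BANDS)) {
        target <- truth$powers[region, b]
        if (target <= 0) next
        w <- stats::rnorm(n)
        bp <- bandpass(signal_trace(w, rate), 4,
                       EEG_BANDS[[b]][1], EEG_BANDS[[b]][2])
        y <- st_channel(bp)
        y <- y * sqrt(target / stats::var(y))
        if (!is.null(gain_envelope)) y <- y * gain_envelope(b, region, t)
        x <- x + y
      }
      out[, j] <- x
    }
    signal_trace(out, rate, units = "uV", channels = labels)
  })
}

# ---- pupil generator --------------------------------------------------------

mark_blinks <- function(x, t, intervals, blink_value = 0) {
  for (iv in intervals) x[t >= iv[1] & t < iv[2]] <- blink_value
  x
}

#' Simulate two-eye pupil diameter traces
#'
#' Both eyes share the baseline and the slow oscillations and carry
#' independent measurement noise; samples inside blink intervals are set to
#' 0 mm (outside the physiological 2-8 mm range, as an eye tracker reports
#' during lid closure).
#'
#' @param truth a [pupil_ground_truth()].
#' @param duration trace length (s).
#' @param rate sampling rate (Hz).
#' @param seed integer seed.
#' @return list with `left` and `right` [signal_trace()]s in mm.
#' @export
simulate_pupil <- function(truth = pupil_ground_truth(), duration, rate = 60,
                           seed = NULL) {
  stopifnot(inherits(truth, "pupil_ground_truth"))
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  base <- rep(truth$baseline, n)
  for (cmp in truth$oscillations)
    base <- base + cmp[2] * sin(2 * pi * cmp[1] * t)
  with_seed(seed, {
    left <- base + if (truth$noise_sd > 0) stats::rnorm(n, 0, truth$noise_sd) else 0
    right <- base + if (truth$noise_sd > 0) stats::rnorm(n, 0, truth$noise_sd) else 0
    left <- mark_blinks(left, t, truth$blink_left)
    right <- mark_blinks(right, t, truth$blink_right)
    list(left = signal_trace(left, rate, units = "mm", channels = "pupil_L"),
         right = signal_trace(right, rate, units = "mm", channels = "pupil_R"))
  })
}
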