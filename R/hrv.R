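## Heartbeat analysis: Pan-Tompkins R-peak detection and the
## history-dependent inverse-Gaussian point-process model of the RR series.
## Each inter-beat interval is inverse-Gaussian with shape theta_{p+1} and a
## mean that is an affine (AR) function of the previous p intervals; the
## parameters are tracked by forgetting-factor-weighted local maximum
## likelihood, and the AR coefficients yield a time-varying parametric
## spectrum integrated into the VLF/LF/HF indices.

# ---- preprocessing & R-peak detection --------------------------------------

#' Preprocess a raw ECG trace
#'
#' Order-4 zero-phase low-pass anti-aliasing filter at 125 Hz, then
#' decimation to 250 Hz.
#'
#' @param raw a [signal_trace()] (native 2048 Hz in the reference setup).
#' @param cutoff anti-aliasing cutoff (Hz).
#' @param target_rate output rate (Hz).
#' @export
preprocess_ecg <- function(raw, cutoff = 125, target_rate = 250) {
  assert_trace(raw, "raw")
  downsample(zero_phase_lowpass(raw, 4, cutoff), target_rate)
}

#' Pan-Tompkins R-peak detection
#'
#' Classic chain: 5-15 Hz band-pass, five-point derivative, squaring,
#' 150 ms moving-window integration, adaptive signal/noise thresholds with
#' a 200 ms refractory period. R locations are refined to the raw-signal
#' maximum within +/-100 ms of each integrated-energy peak. Intervals
#' outside the physiologic guard (0.25-3 s) are flagged, and long gaps
#' trigger a local re-search at a lowered threshold.
#'
#' @param ecg a [signal_trace()] at ~250 Hz.
#' @param refractory_s minimum separation between beats (s).
#' @param guard physiologic RR bounds `c(lo, hi)` in seconds.
#' @return an `rr_series`; attribute `guard_flags` holds indices of
#'   intervals outside the guard. Empty series (with a warning) when no
#'   beats are found.
#' @export
detect_rpeaks <- function(ecg, refractory_s = 0.2, guard = c(0.25, 3)) {
  assert_trace(ecg, "ecg")
  rate <- ecg$rate
  x <- st_channel(ecg)
  n <- length(x)
  if (n < 5 * rate) stop("at least 5 s of ECG are required")
  bp <- st_channel(bandpass(signal_trace(x, rate), 3, 5, 15))
  d <- c(bp[2] - bp[1], (bp[3:n] - bp[1:(n - 2)]) / 2, bp[n] - bp[n - 1]) * rate
  sq <- d^2
  integ <- movmean_causal_cpp(sq, as.integer(round(0.15 * rate)))
  # adaptive thresholding on the integrated energy
  refr <- round(refractory_s * rate)
  spki <- max(integ[seq_len(min(n, round(2 * rate)))]) * 0.5
  npki <- mean(integ[seq_len(min(n, round(2 * rate)))]) * 0.5
  thr <- npki + 0.25 * (spki - npki)
  cand <- which(diff(sign(diff(integ))) < 0) + 1L
  peaks <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (integ[i] > thr) {
      if (i - last > refr) {
        peaks <- c(peaks, i)
        last <- i
        spki <- 0.125 * integ[i] + 0.875 * spki
      } else if (length(peaks) && integ[i] > integ[peaks[length(peaks)]]) {
        peaks[length(peaks)] <- i
        last <- i
        spki <- 0.125 * integ[i] + 0.875 * spki
      }
    } else {
      npki <- 0.125 * integ[i] + 0.875 * npki
    }
    thr <- npki + 0.25 * (spki - npki)
  }
  if (!length(peaks)) {
    warning("no beats found")
    return(rr_series(numeric(0)))
  }
  # refine to the raw-signal maximum near each energy peak
  half <- round(0.1 * rate)
  half <- as.integer(half)
  locs <- vapply(as.integer(peaks), function(i) {
    lo <- max(1L, i - 2L * half); hi <- min(n, i + half)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  locs <- sort(unique(locs))
  # drop refractory duplicates after refinement
  keep <- c(TRUE, diff(locs) > refr)
  locs <- locs[keep]
  # missed-beat re-search: look inside gaps > 1.8x the median interval
  if (length(locs) > 3) {
    med_rr <- stats::median(diff(locs))
    med_amp <- stats::median(x[locs])
    repeat {
      gaps <- which(diff(locs) > 1.8 * med_rr)
      if (!length(gaps)) break
      added <- FALSE
      for (g in gaps) {
        lo <- locs[g] + refr; hi <- locs[g + 1] - refr
        if (hi <= lo) next
        j <- lo + which.max(x[lo:hi]) - 1L
        if (x[j] > 0.4 * med_amp) {
          locs <- sort(c(locs, j)); added <- TRUE; break
        }
      }
      if (!added) break
    }
  }
  r_times <- (locs - 1) / rate
  rr <- rr_series(r_times)
  iv <- rr$intervals
  attr(rr, "guard_flags") <- which(iv < guard[1] | iv > guard[2])
  rr
}

#' Read/write R-peak annotations
#'
#' Two-column delimited file: `sample_index` (1-based at `rate`) and
#' `time_s`.
#'
#' @param rr an `rr_series`.
#' @param path file path.
#' @param rate sampling rate used for the sample-index column.
#' @export
write_rpeaks <- function(rr, path, rate = 250) {
  utils::write.table(
    data.frame(sample_index = round(rr$r_times * rate) + 1L,
               time_s = rr$r_times),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rpeaks
#' @export
read_rpeaks <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  rr_series(d$time_s)
}

# ---- inverse-Gaussian density and parameters --------------------------------

#' Inverse-Gaussian inter-beat density
#'
#' Density at waiting time `w` since the previous beat, with mean `mu` and
#' shape parameter `shape` (the standard squared-deviation form; variance
#' `mu^3 / shape`).
#'
#' @param w waiting time(s) since the last beat (s), > 0.
#' @param mu mean interval (s), > 0.
#' @param shape inverse-Gaussian shape (s), > 0.
#' @return density value(s), per second.
#' @export
ig_density <- function(w, mu, shape) {
  if (any(w <= 0) || any(mu <= 0) || any(shape <= 0))
    stop("w, mu and shape must be positive")
  sqrt(shape / (2 * pi * w^3)) * exp(-shape * (w - mu)^2 / (2 * mu^2 * w))
}

#' Inverse-Gaussian cumulative distribution
#'
#' Used by the time-rescaling goodness-of-fit check.
#' @inheritParams ig_density
#' @export
ig_cdf <- function(w, mu, shape) {
  if (any(w <= 0) || any(mu <= 0) || any(shape <= 0))
    stop("w, mu and shape must be positive")
  a <- sqrt(shape / w)
  stats::pnorm(a * (w / mu - 1)) +
    exp(pmin(2 * shape / mu, 700)) * stats::pnorm(-a * (w / mu + 1))
}

#' Point-process model parameters
#'
#' @param theta0 intercept of the AR mean (s).
#' @param ar_coeffs AR coefficients theta_1..theta_p.
#' @param shape inverse-Gaussian shape theta_(p+1) (s), > 0.
#' @return an `ig_params` object with `order = length(ar_coeffs)`.
#' @export
ig_params <- function(theta0, ar_coeffs = numeric(0), shape) {
  if (!is.finite(shape) || shape <= 0) stop("shape must be positive")
  if (any(!is.finite(c(theta0, ar_coeffs)))) stop("coefficients must be finite")
  structure(list(theta0 = theta0, ar_coeffs = as.numeric(ar_coeffs),
                 shape = shape, order = length(ar_coeffs)),
            class = "ig_params")
}

#' AR mean of the next interval
#'
#' `mu = theta0 + sum_i theta_i * history[i]`, where `history[1]` is the most
#' recent interval.
#'
#' @param params an [ig_params()].
#' @param history numeric vector of the last `p` intervals, most recent
#'   first; length must equal `params$order`.
#' @return mean interval (s).
#' @export
mu_rr <- function(params, history = numeric(0)) {
  stopifnot(inherits(params, "ig_params"))
  if (length(history) != params$order)
    stop("history length must equal the AR order")
  params$theta0 + if (params$order) sum(params$ar_coeffs * history) else 0
}

# ---- local maximum-likelihood fitting ---------------------------------------

# Design rows for intervals j = (p+1)..n: x_j = (1, RR_{j-1}, ..., RR_{j-p}).
rr_design <- function(intervals, p) {
  n <- length(intervals)
  if (n < p + 1) return(NULL)
  j <- (p + 1):n
  X <- matrix(1, length(j), p + 1)
  if (p > 0) for (i in seq_len(p)) X[, i + 1] <- intervals[j - i]
  list(X = X, y = intervals[j], j = j)
}

#' Local maximum-likelihood fit of the inverse-Gaussian model
#'
#' Maximizes the forgetting-weighted log-likelihood of the intervals ending
#' in `(t - window, t]`, each weighted `forgetting^(t - end_time)`. The AR
#' mean is linear in theta, so theta is updated by Fisher scoring
#' (iteratively reweighted least squares) with the shape profiled out in
#' closed form at each iteration.
#'
#' @param rr an `rr_series`.
#' @param t fit time (s); defaults to the last beat.
#' @param order AR order p.
#' @param window local window length W (s).
#' @param forgetting per-second forgetting factor rho in (0, 1].
#' @param init optional `ig_params` warm start.
#' @param max_iter,tol iteration controls.
#' @return an `ig_params` with attributes `converged`, `n_beats`,
#'   `loglik`; or NULL (with a warning) when fewer than p+2 usable
#'   intervals fall in the window.
#' @export
local_ml_fit <- function(rr, t = NULL, order = 8, window = 90,
                         forgetting = 0.98, init = NULL,
                         max_iter = 50, tol = 1e-9) {
  stopifnot(inherits(rr, "rr_series"))
  if (is.null(t)) t <- max(rr$r_times)
  p <- as.integer(order)
  des <- rr_design(rr$intervals, p)
  if (is.null(des)) { warning("insufficient beats"); return(NULL) }
  ends <- rr$r_times[des$j + 1L]
  inwin <- ends > t - window & ends <= t
  if (sum(inwin) < p + 2) { warning("insufficient beats in window"); return(NULL) }
  X <- des$X[inwin, , drop = FALSE]
  y <- des$y[inwin]
  w <- forgetting^(t - ends[inwin])
  theta <- if (!is.null(init) && init$order == p) {
    c(init$theta0, init$ar_coeffs)
  } else {
    # weighted least squares start (exact when shape -> infinity)
    qr.coef(qr(X * sqrt(w)), y * sqrt(w))
  }
  theta[!is.finite(theta)] <- 0
  converged <- FALSE
  ll_old <- -Inf
  lam <- NA_real_
  for (it in seq_len(max_iter)) {
    mu <- as.numeric(X %*% theta)
    mu <- pmax(mu, 1e-3)
    lam <- sum(w) / sum(w * (y - mu)^2 / (mu^2 * y))
    if (!is.finite(lam) || lam <= 0) lam <- 1e8
    # Fisher scoring step for theta (weights w / mu^3)
    wi <- w / mu^3
    A <- crossprod(X, X * wi)
    b <- crossprod(X, wi * (y - mu))
    step <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(step)) break
    theta_new <- theta + as.numeric(step)
    mu_new <- pmax(as.numeric(X %*% theta_new), 1e-3)
    ll <- sum(w * (0.5 * log(lam) - 1.5 * log(y) -
                     lam * (y - mu_new)^2 / (2 * mu_new^2 * y)))
    if (it > 1 && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      theta <- theta_new; converged <- TRUE; ll_old <- ll; break
    }
    theta <- theta_new
    ll_old <- ll
  }
  mu <- pmax(as.numeric(X %*% theta), 1e-3)
  lam <- sum(w) / sum(w * (y - mu)^2 / (mu^2 * y))
  out <- ig_params(theta[1], theta[-1], lam)
  attr(out, "converged") <- converged
  attr(out, "n_beats") <- sum(inwin)
  attr(out, "loglik") <- ll_old
  out
}

# ---- time-varying spectrum --------------------------------------------------

#' Parametric spectrum of the fitted AR mean dynamics
#'
#' Evaluates `S(f) = 2 * delta * sigma2 / |1 - sum_i theta_i
#' exp(-i 2 pi f i delta)|^2` with `delta` the local mean interval (the
#' beat-domain sampling step mapped to seconds) and `sigma2 = mu^3/shape`
#' the model interval variance playing the innovation role, then integrates
#' the half-open VLF [0, 0.04), LF [0.04, 0.15) and HF [0.15, 0.5) Hz bands.
#'
#' @param params an [ig_params()].
#' @param mu local mean interval (s), used both as delta and in sigma2.
#' @param df frequency grid step (Hz).
#' @return list with `spectrum` (a `spectrum_psd`), `vlf`, `lf`, `hf`,
#'   `tot` (s^2), `lf_hf`, `lfn`, `hfn`. `lf_hf` is `NA` when hf is 0.
#' @export
instantaneous_spectrum <- function(params, mu, df = 0.002) {
  stopifnot(inherits(params, "ig_params"))
  if (mu <= 0) stop("mu must be positive")
  if (params$order && !ar_stable(params$ar_coeffs))
    warning("unstable AR coefficients; spectrum may be degenerate")
  delta <- mu
  sigma2 <- mu^3 / params$shape
  fmax <- min(0.5, 1 / (2 * delta))
  f <- seq(0, fmax, by = df)
  denom <- rep(1 + 0i, length(f))
  if (params$order) {
    for (i in seq_len(params$order))
      denom <- denom - params$ar_coeffs[i] * exp(-1i * 2 * pi * f * i * delta)
  }
  dens <- 2 * delta * sigma2 / Mod(denom)^2
  sp <- structure(list(frequencies = f, density = matrix(dens, ncol = 1),
                       channels = "RR"), class = "spectrum_psd")
  vlf <- band_power(sp, 0, 0.04)
  lf <- band_power(sp, 0.04, 0.15)
  hf <- band_power(sp, 0.15, 0.5)
  tot <- band_power(sp, 0, 0.5)
  list(spectrum = sp, vlf = vlf, lf = lf, hf = hf, tot = tot,
       lf_hf = if (hf > 0) lf / hf else NA_real_,
       lfn = if (lf + hf > 0) lf / (lf + hf) else NA_real_,
       hfn = if (lf + hf > 0) hf / (lf + hf) else NA_real_)
}

#' Track instantaneous HRV indices over a recording
#'
#' Slides the local maximum-likelihood fit along a regular grid,
#' warm-starting each fit from the previous grid point, and computes at
#' each point the instantaneous mean interval (from the fitted AR mean and
#' the most recent p intervals), the model variance `mu^3/shape`, and the
#' integrated spectral indices.
#'
#' @param rr an `rr_series`.
#' @param grid_step grid spacing (s).
#' @param order,window,forgetting see [local_ml_fit()].
#' @param df spectral grid step (Hz).
#' @return data.frame with one row per grid point: `t`, `mu_rr`, `sigma2`,
#'   `vlf`, `lf`, `hf`, `tot`, `lf_hf`, `lfn`, `hfn`, `converged`. Rows
#'   before the first estimable time are absent; non-converged fits carry
#'   the previous estimate.
#' @export
track <- function(rr, grid_step = 0.005, order = 8, window = 90,
                  forgetting = 0.98, df = 0.002) {
  stopifnot(inherits(rr, "rr_series"))
  p <- as.integer(order)
  nb <- length(rr$intervals)
  cols <- c("t", "mu_rr", "sigma2", "vlf", "lf", "hf", "tot",
            "lf_hf", "lfn", "hfn", "converged")
  if (nb < p + 3) {
    out <- as.data.frame(matrix(numeric(0), 0, length(cols)))
    names(out) <- cols
    return(out)
  }
  t_first <- rr$r_times[p + 3]          # first time with p+2 usable intervals
  t_last <- max(rr$r_times)
  grid <- seq(t_first, t_last, by = grid_step)
  prev <- NULL
  rows <- vector("list", length(grid))
  for (gi in seq_along(grid)) {
    tg <- grid[gi]
    fit <- suppressWarnings(
      local_ml_fit(rr, tg, order = p, window = window,
                   forgetting = forgetting, init = prev, max_iter = 20))
    if (is.null(fit)) {
      if (is.null(prev)) next
      fit <- prev
      conv <- FALSE
    } else {
      conv <- isTRUE(attr(fit, "converged"))
      if (!conv && !is.null(prev)) fit <- prev
      prev <- fit
    }
    k <- findInterval(tg, rr$r_times)
    hist_iv <- if (p > 0) rev(rr$intervals[max(1, k - p):(k - 1)]) else numeric(0)
    if (length(hist_iv) < p) next
    mu <- mu_rr(fit, hist_iv)
    if (!is.finite(mu) || mu <= 0) mu <- mean(rr$intervals)
    sp <- instantaneous_spectrum(fit, mu, df = df)
    rows[[gi]] <- data.frame(t = tg, mu_rr = mu, sigma2 = mu^3 / fit$shape,
                             vlf = sp$vlf, lf = sp$lf, hf = sp$hf,
                             tot = sp$tot, lf_hf = sp$lf_hf,
                             lfn = sp$lfn, hfn = sp$hfn, converged = conv)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- as.data.frame(matrix(numeric(0), 0, length(cols)))
    names(out) <- cols
  }
  out
}

#' Window averages of the instantaneous HRV indices
#'
#' Arithmetic mean of every tracked index over the grid points falling in
#' the half-open window; all-`NA` when the window contains no grid point.
#'
#' @param trk data.frame from [track()].
#' @param window `c(t_start, t_end)` in seconds.
#' @return one-row data.frame of window means.
#' @export
hrv_features <- function(trk, window) {
  keep <- trk$t >= window[1] & trk$t < window[2]
  cols <- c("mu_rr", "sigma2", "vlf", "lf", "hf", "tot", "lf_hf", "lfn", "hfn")
  if (!any(keep)) {
    out <- as.data.frame(as.list(stats::setNames(rep(NA_real_, length(cols)), cols)))
    return(out)
  }
  as.data.frame(lapply(trk[keep, cols], mean, na.rm = TRUE))
}

#' Time-rescaling goodness-of-fit transform
#'
#' Maps each interval through its fitted conditional CDF; under a
#' well-specified model the result is i.i.d. uniform on (0, 1).
#'
#' @param rr an `rr_series`.
#' @param params an [ig_params()] (a global fit suffices for stationary
#'   data).
#' @return numeric vector of rescaled values in (0, 1).
#' @export
time_rescale <- function(rr, params) {
  des <- rr_design(rr$intervals, params$order)
  if (is.null(des)) return(numeric(0))
  mu <- pmax(as.numeric(des$X %*% c(params$theta0, params$ar_coeffs)), 1e-3)
  ig_cdf(des$y, mu, params$shape)
}
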