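## Blood volume pulse chain: 25 Hz anti-aliased decimation to 250 Hz,
## ECG-anchored fiducials (systole = max, diastole = min between
## consecutive R-peaks, onset = steepest point of the rising limb), and the
## volume-pulse (VP) and pulse-arrival-time (PAT) features.

#' Preprocess a raw BVP trace
#'
#' Order-4 zero-phase low-pass at 25 Hz, then decimation to 250 Hz.
#'
#' @param raw a [signal_trace()] (native 2048 Hz in the reference setup).
#' @param cutoff low-pass cutoff (Hz).
#' @param target_rate output rate (Hz).
#' @export
preprocess_bvp <- function(raw, cutoff = 25, target_rate = 250) {
  assert_trace(raw, "raw")
  downsample(zero_phase_lowpass(raw, 4, cutoff), target_rate)
}

#' Locate per-beat pulse fiducials
#'
#' For each pair of consecutive R-peaks, the systole is the BVP maximum and
#' the diastole the minimum in between; the onset is the inflection point
#' (maximum of the first derivative) on the rising limb preceding the
#' systolic peak. Beats with no distinct extrema, no rising limb, or an
#' implausible arrival time (<= 0 or longer than the RR interval) are
#' skipped; the number skipped is reported as attribute `n_skipped`.
#'
#' @param bvp a [signal_trace()] at ~250 Hz.
#' @param rr an `rr_series` with at least two beats covering the trace.
#' @return data.frame with one row per accepted beat: `r_time`, `onset_t`,
#'   `systole_t`, `systole_amp`, `diastole_t`, `diastole_amp`.
#' @export
locate_fiducials <- function(bvp, rr) {
  assert_trace(bvp, "bvp")
  stopifnot(inherits(rr, "rr_series"))
  if (length(rr$r_times) < 2) stop("at least two R-peaks are required")
  x <- st_channel(bvp)
  t <- st_times(bvp)
  rate <- bvp$rate
  n <- length(x)
  rows <- list()
  skipped <- 0L
  for (k in seq_len(length(rr$r_times) - 1L)) {
    i0 <- max(1L, floor(rr$r_times[k] * rate) + 1L)
    i1 <- min(n, floor(rr$r_times[k + 1L] * rate) + 1L)
    if (i1 - i0 < 5L) { skipped <- skipped + 1L; next }
    seg <- i0:i1
    si <- seg[which.max(x[seg])]
    di <- seg[which.min(x[seg])]
    if (x[si] - x[di] < .Machine$double.eps^0.5) { skipped <- skipped + 1L; next }
    if (si - i0 < 2L) { skipped <- skipped + 1L; next }  # no rising limb
    if (si >= i1) { skipped <- skipped + 1L; next }      # monotone: no distinct systole
    rise <- i0:si
    # central-difference derivative on the rising limb
    if (length(rise) < 3L) { skipped <- skipped + 1L; next }
    core <- rise[-c(1, length(rise))]
    dv <- (x[core + 1L] - x[core - 1L]) * rate / 2
    if (max(dv) <= 0) { skipped <- skipped + 1L; next }  # monotone non-rising
    oi <- core[which.max(dv)]
    pat <- t[oi] - rr$r_times[k]
    if (pat <= 0 || pat > rr$r_times[k + 1L] - rr$r_times[k]) {
      skipped <- skipped + 1L; next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      r_time = rr$r_times[k], onset_t = t[oi],
      systole_t = t[si], systole_amp = x[si],
      diastole_t = t[di], diastole_amp = x[di])
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(r_time = numeric(), onset_t = numeric(),
               systole_t = numeric(), systole_amp = numeric(),
               diastole_t = numeric(), diastole_amp = numeric())
  if (skipped > 0)
    warning(sprintf("%d beat(s) skipped (degenerate segment or arrival-time guard)",
                    skipped))
  attr(out, "n_skipped") <- skipped
  out
}

#' VP and PAT features over a window
#'
#' Means over the beats whose R-peak falls in the half-open window:
#' `vp = mean(systole_amp - diastole_amp)` and
#' `pat = mean(onset_t - r_time)`. Onsets (not systoles or diastoles) are
#' used for the arrival time because they are the more stable fiducial.
#'
#' @param fiducials data.frame from [locate_fiducials()].
#' @param window `c(t_start, t_end)` seconds; default all beats.
#' @return one-row data.frame with `vp`, `pat`, `n_beats`; `NA` features
#'   when the window holds no beat.
#' @export
bvp_features <- function(fiducials, window = NULL) {
  if (is.null(window)) window <- c(-Inf, Inf)
  f <- fiducials[fiducials$r_time >= window[1] & fiducials$r_time < window[2], ,
                 drop = FALSE]
  if (nrow(f) == 0)
    return(data.frame(vp = NA_real_, pat = NA_real_, n_beats = 0L))
  data.frame(vp = mean(f$systole_amp - f$diastole_amp),
             pat = mean(f$onset_t - f$r_time),
             n_beats = nrow(f))
}

#' Write a fiducial table to a delimited file
#'
#' @param fiducials data.frame from [locate_fiducials()].
#' @param path output path (tab-separated).
#' @export
write_fiducials <- function(fiducials, path) {
  utils::write.table(fiducials, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fiducials
#' @export
read_fiducials <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}
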