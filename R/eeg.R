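## EEG chain: 21-electrode 10-20 montage with neighbor map, bad-channel
## interpolation, common-average referencing over the 19 scalp channels,
## band filtering (delta/theta/alpha/beta; gamma deliberately excluded),
## Welch band powers by region, and the beta/theta attention index.

#' The 21-electrode 10-20 montage
#'
#' Labels, alias map (e.g. `T3` resolves to `T7/T3`), a nearest-neighbor
#' map per electrode, and the region memberships used for feature
#' aggregation: frontal = Fp1, Fp2, Fz, F3, F4, F7, F8; parietal = Pz, P3,
#' P4, P7/T5, P8/T6; A1/A2 are mastoids (excluded from the common average).
#'
#' @param frontal,parietal optional region overrides (character vectors of
#'   labels).
#' @return a `montage` list with `labels`, `aliases`, `neighbors`,
#'   `frontal`, `parietal`, `mastoids`.
#' @export
montage_1020 <- function(frontal = NULL, parietal = NULL) {
  labels <- c("Fp1", "Fp2", "Fz", "F3", "F4", "F7", "F8", "Cz", "C3", "C4",
              "T7/T3", "T8/T4", "Pz", "P3", "P4", "P7/T5", "P8/T6",
              "O1", "O2", "A1", "A2")
  neighbors <- list(
    "Fp1" = c("Fp2", "F3", "F7", "Fz"),
    "Fp2" = c("Fp1", "F4", "F8", "Fz"),
    "Fz" = c("Fp1", "Fp2", "F3", "F4", "Cz"),
    "F3" = c("Fp1", "Fz", "C3", "F7"),
    "F4" = c("Fp2", "Fz", "C4", "F8"),
    "F7" = c("Fp1", "F3", "T7/T3"),
    "F8" = c("Fp2", "F4", "T8/T4"),
    "Cz" = c("Fz", "C3", "C4", "Pz"),
    "C3" = c("F3", "Cz", "P3", "T7/T3"),
    "C4" = c("F4", "Cz", "P4", "T8/T4"),
    "T7/T3" = c("F7", "C3", "P7/T5"),
    "T8/T4" = c("F8", "C4", "P8/T6"),
    "Pz" = c("P3", "P4", "Cz"),
    "P3" = c("C3", "Pz", "P7/T5", "O1"),
    "P4" = c("C4", "Pz", "P8/T6", "O2"),
    "P7/T5" = c("T7/T3", "P3", "O1"),
    "P8/T6" = c("T8/T4", "P4", "O2"),
    "O1" = c("P3", "P7/T5", "O2"),
    "O2" = c("P4", "P8/T6", "O1"),
    "A1" = c("T7/T3"),
    "A2" = c("T8/T4"))
  aliases <- c("T3" = "T7/T3", "T4" = "T8/T4", "T5" = "P7/T5", "T6" = "P8/T6",
               "T7" = "T7/T3", "T8" = "T8/T4", "P7" = "P7/T5", "P8" = "P8/T6")
  structure(list(
    labels = labels,
    aliases = aliases,
    neighbors = neighbors,
    frontal = frontal %||% c("Fp1", "Fp2", "Fz", "F3", "F4", "F7", "F8"),
    parietal = parietal %||% c("Pz", "P3", "P4", "P7/T5", "P8/T6"),
    mastoids = c("A1", "A2")
  ), class = "montage")
}

#' Resolve a (possibly aliased) channel label
#' @param label channel label, e.g. `"T3"`.
#' @param montage a [montage_1020()].
#' @return canonical label.
#' @export
resolve_channel <- function(label, montage = montage_1020()) {
  if (label %in% montage$labels) return(label)
  if (label %in% names(montage$aliases)) return(unname(montage$aliases[label]))
  stop(sprintf("unknown channel label '%s'", label))
}

channel_region <- function(label, montage) {
  if (label %in% montage$frontal) return("frontal")
  if (label %in% montage$parietal) return("parietal")
  if (label %in% montage$mastoids) return("mastoid")
  "other"
}

#' Replace a corrupted channel by its neighbor average
#'
#' @param trace a multichannel [signal_trace()] with montage labels.
#' @param bad label of the channel to repair (aliases accepted).
#' @param montage a [montage_1020()].
#' @return the trace with the bad channel replaced samplewise by the mean
#'   of its nearest neighbors.
#' @export
interpolate_channel <- function(trace, bad, montage = montage_1020()) {
  assert_trace(trace)
  bad <- resolve_channel(bad, montage)
  if (!bad %in% trace$channels)
    stop(sprintf("channel '%s' not present in the trace", bad))
  nb <- montage$neighbors[[bad]]
  nb <- nb[nb %in% trace$channels]
  if (!length(nb)) stop(sprintf("no neighbors of '%s' present", bad))
  out <- trace$samples
  out[, bad] <- rowMeans(out[, nb, drop = FALSE])
  signal_trace(out, trace$rate, units = trace$units, channels = trace$channels)
}

#' Common-average re-referencing
#'
#' Subtracts, at each sample, the instantaneous mean across the scalp
#' channels (mastoids A1/A2 excluded from both the average and the
#' subtraction, since reference electrodes would bias the common average).
#' Idempotent.
#'
#' @param trace a multichannel [signal_trace()].
#' @param montage a [montage_1020()].
#' @return the re-referenced [signal_trace()].
#' @export
car_reference <- function(trace, montage = montage_1020()) {
  assert_trace(trace)
  scalp <- setdiff(trace$channels, montage$mastoids)
  out <- trace$samples
  avg <- rowMeans(out[, scalp, drop = FALSE])
  out[, scalp] <- out[, scalp, drop = FALSE] - avg
  signal_trace(out, trace$rate, units = trace$units, channels = trace$channels)
}

#' Zero-phase filter into a named EEG band
#'
#' Bands: delta 1-3 Hz, theta 4-7 Hz, alpha 8-12 Hz, beta 16-38 Hz. Gamma
#' (> 38 Hz) is excluded by design: no emotion-related activity is expected
#' there and it is dominated by muscular artifacts.
#'
#' @param trace a [signal_trace()].
#' @param band one of `"delta"`, `"theta"`, `"alpha"`, `"beta"`.
#' @param order low-pass prototype order of the band-pass.
#' @export
band_filter <- function(trace, band, order = 4) {
  band <- match.arg(band, names(EEG_BANDS))
  bandpass(trace, order, EEG_BANDS[[band]][1], EEG_BANDS[[band]][2])
}

#' Regional EEG band powers and attention indices
#'
#' Per region (frontal, parietal), the mean over member channels of the
#' Welch band power integrated over each band, plus the beta/theta
#' attention index per region. Powers are computed per channel and then
#' averaged (power averaging, not signal averaging).
#'
#' @param trace a multichannel [signal_trace()] (already re-referenced).
#' @param montage a [montage_1020()].
#' @param window optional `c(t_start, t_end)` seconds; default whole trace.
#' @param segment_s Welch segment length (s).
#' @param overlap_fraction Welch overlap.
#' @return one-row data.frame: `<band>_frontal`, `<band>_parietal` for the
#'   four bands, and `attention_frontal`, `attention_parietal`
#'   (`NA` when the theta power is 0).
#' @export
eeg_features <- function(trace, montage = montage_1020(), window = NULL,
                         segment_s = 2, overlap_fraction = 0.5) {
  assert_trace(trace)
  if (!is.null(window)) trace <- st_window(trace, window[1], window[2])
  seg <- min(round(segment_s * trace$rate), nrow(trace$samples))
  ps <- welch_psd(trace, seg, overlap_fraction, "hamming", detrend = TRUE)
  out <- list()
  for (region in c("frontal", "parietal")) {
    members <- intersect(montage[[region]], trace$channels)
    if (!length(members)) stop(sprintf("no %s channels present", region))
    for (b in names(EEG_BANDS)) {
      pw <- mean(vapply(members, function(ch)
        band_power(ps, EEG_BANDS[[b]][1], EEG_BANDS[[b]][2], channel = ch),
        numeric(1)))
      out[[paste0(b, "_", region)]] <- pw
    }
    th <- out[[paste0("theta_", region)]]
    out[[paste0("attention_", region)]] <-
      if (th > 0) out[[paste0("beta_", region)]] / th else NA_real_
  }
  as.data.frame(out, check.names = FALSE)
}
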