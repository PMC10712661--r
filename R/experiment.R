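## Whole-experiment simulation: lays ground-truth records onto the protocol
## timeline with optional per-phase effects, generates each requested
## channel at its native rate, and keeps the realized truths alongside the
## traces so that end-to-end recovery tests have a reference.

#' Default pipeline configuration
#'
#' Nested list of every tunable parameter with the reference-setup
#' defaults: native rates (GSR 256, ECG/BVP 2048, EEG 300, pupil 60 Hz),
#' the per-signal preprocessing parameters, the point-process settings, the
#' generator ground-truth defaults and the comparison alpha. Serializable
#' to/from JSON via [write_run_config()].
#'
#' @return a `run_config` list.
#' @export
default_config <- function() {
  structure(list(
    protocol = list(initial_rest_s = 300, neutral_s = 90, stimulus_s = 15,
                    interphase_rest_s = 120, n_phases = 3,
                    n_arousal_sessions = 4, n_stimuli = 6,
                    phase_order_seed = 1),
    signals = c("gsr", "ecg", "bvp", "eeg", "pupil"),
    rates = list(gsr = 256, ecg = 2048, bvp = 2048, eeg = 300, pupil = 60),
    gsr = list(tonic = 2, scr_base_amp = 0.4, scr_prob = 0.75,
               neutral_prob = 0.2, rise_tau = 0.3, decay_tau = 1.2,
               noise_sd = 0.003, onset_threshold = 0.01),
    rr = list(theta0 = 0.8, ar_coeffs = numeric(0), lambda = 200,
              modulation = list(c(0.1, 0.04), c(0.25, 0.03))),
    hrv = list(order = 8, window = 90, forgetting = 0.98, grid_step = 0.25),
    bvp = list(pat = 0.25, vp_amplitude = 1.0),
    eeg = list(segment_s = 2),
    pupil = list(oscillations = list(c(0.1, 0.15), c(0.3, 0.05)),
                 baseline = 5, noise_sd = 0.02,
                 blink_rate = 0.08, blink_dur = 0.25),
    stats = list(alpha = 0.05),
    seed = 1
  ), class = "run_config")
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read/write a pipeline configuration as JSON
#'
#' Values present in the file override the defaults of
#' [default_config()]; everything else keeps its default.
#'
#' @param path JSON file path.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  if (!is.null(raw$rr$modulation))
    raw$rr$modulation <- lapply(raw$rr$modulation, as.numeric)
  if (!is.null(raw$pupil$oscillations))
    raw$pupil$oscillations <- lapply(raw$pupil$oscillations, as.numeric)
  cfg <- merge_config(default_config(), raw)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

effect_for <- function(effect_map, phase, key, default = 1) {
  if (is.null(effect_map) || is.na(phase)) return(default)
  e <- effect_map[[phase]]
  if (is.null(e) || is.null(e[[key]])) return(default)
  e[[key]]
}

# phase label at time t (NA during rests)
phase_at <- function(schedule, t) {
  s <- schedule$sessions
  i <- findInterval(t, s$t_start)
  out <- rep(NA_character_, length(t))
  ok <- i >= 1 & i <= nrow(s)
  out[ok] <- s$phase[i[ok]]
  out
}

#' Simulate a full multimodal recording over a protocol timeline
#'
#' Places SCR events at the stimulus onsets (with configurable per-stimulus
#' probability and arousal-graded amplitudes), runs one heartbeat point
#' process over the whole timeline, couples the pulse waveform to the
#' R-peaks, generates band-structured EEG and an oscillating two-eye pupil
#' trace with blinks. `effect_map` injects per-phase ground-truth
#' modulation, e.g. `list("IADS" = list(scr_amp = 2))` doubles SCR
#' amplitudes during the IADS phase; supported keys are `scr_amp`,
#' `scr_prob`, `theta0`, and per-band EEG multipliers `delta`, `theta`,
#' `alpha`, `beta`.
#'
#' @param schedule a `protocol_schedule`.
#' @param effect_map named per-phase list of modulations (see above).
#' @param seed integer master seed; every channel derives its own stream.
#' @param signals subset of `c("gsr","ecg","bvp","eeg","pupil")` to
#'   generate.
#' @param config a `run_config` (rates and generator defaults).
#' @return a `multimodal_recording`: list with the requested traces
#'   (`gsr`, `ecg`, `bvp`, `eeg`, `pupil_left`, `pupil_right`), the
#'   `schedule` and the realized `truth` records.
#' @export
simulate_experiment <- function(schedule, effect_map = NULL, seed = 1,
                                signals = c("gsr", "ecg", "bvp", "eeg", "pupil"),
                                config = default_config()) {
  stopifnot(inherits(schedule, "protocol_schedule"))
  signals <- match.arg(signals, several.ok = TRUE)
  duration <- schedule_duration(schedule)
  if (duration <= 0) stop("empty schedule")
  rec <- list(schedule = schedule, truth = list(effect_map = effect_map))
  ev <- schedule$events

  if ("gsr" %in% signals) {
    g <- config$gsr
    times <- numeric(0); amps <- numeric(0)
    with_seed(derive_seed(seed, 1), {
      for (i in seq_len(nrow(ev))) {
        ph <- ev$phase[i]; lev <- ev$arousal_level[i]
        p <- if (lev > 0) g$scr_prob else g$neutral_prob
        p <- min(1, p * effect_for(effect_map, ph, "scr_prob"))
        if (stats::runif(1) > p) next
        tt <- ev$onset[i] + stats::runif(1, 1, min(3, ev$duration[i]))
        if (tt >= duration - 1) next
        base <- g$scr_base_amp * (if (lev > 0) 1 + 0.15 * (lev - 1) else 0.8)
        a <- base * effect_for(effect_map, ph, "scr_amp") *
          stats::rlnorm(1, 0, 0.25)
        times <- c(times, tt); amps <- c(amps, a)
      }
    })
    scr <- scr_ground_truth(times, amps, rise_tau = g$rise_tau,
                            decay_tau = g$decay_tau, tonic_level = g$tonic)
    rec$gsr <- simulate_gsr(scr, duration, rate = config$rates$gsr,
                            seed = derive_seed(seed, 2), noise_sd = g$noise_sd)
    rec$truth$scr <- scr
  }

  if (any(c("ecg", "bvp") %in% signals)) {
    rrcfg <- config$rr
    rrt <- rr_ground_truth(rrcfg$theta0, rrcfg$ar_coeffs, rrcfg$lambda,
                           rrcfg$modulation)
    mod_fun <- function(tt) {
      ph <- phase_at(schedule, tt)
      vapply(ph, function(p) effect_for(effect_map, p, "theta0"), numeric(1))
    }
    rr <- simulate_rr_ig(duration - 0.5, rrt, seed = derive_seed(seed, 3),
                         t0 = 0.3, mod_fun = mod_fun)
    bvpt <- bvp_ground_truth(config$bvp$pat, config$bvp$vp_amplitude)
    traces <- simulate_ecg_bvp(rr, bvpt, rate = config$rates$ecg,
                               duration = duration)
    if ("ecg" %in% signals) rec$ecg <- traces$ecg
    if ("bvp" %in% signals) rec$bvp <- traces$bvp
    rec$truth$rr <- rr
    rec$truth$bvp <- bvpt
  }

  if ("eeg" %in% signals) {
    eegt <- eeg_ground_truth()
    env <- NULL
    if (!is.null(effect_map)) {
      env <- function(band, region, t) {
        ph <- phase_at(schedule, t)
        m <- vapply(ph, function(p) effect_for(effect_map, p, band), numeric(1))
        sqrt(m)
      }
    }
    rec$eeg <- simulate_eeg(eegt, duration, rate = config$rates$eeg,
                            seed = derive_seed(seed, 4), gain_envelope = env)
    rec$truth$eeg <- eegt
  }

  if ("pupil" %in% signals) {
    pcfg <- config$pupil
    blinks <- with_seed(derive_seed(seed, 5), {
      n_bl <- stats::rpois(1, pcfg$blink_rate * duration)
      starts <- sort(stats::runif(n_bl, 0, duration - pcfg$blink_dur))
      lapply(starts, function(s) c(s, s + pcfg$blink_dur))
    })
    pt <- pupil_ground_truth(pcfg$baseline, pcfg$oscillations,
                             blink_left = blinks, blink_right = blinks,
                             noise_sd = pcfg$noise_sd)
    eyes <- simulate_pupil(pt, duration, rate = config$rates$pupil,
                           seed = derive_seed(seed, 6))
    rec$pupil_left <- eyes$left
    rec$pupil_right <- eyes$right
    rec$truth$pupil <- pt
  }

  class(rec) <- "multimodal_recording"
  rec
}

#' @export
print.multimodal_recording <- function(x, ...) {
  ch <- intersect(c("gsr", "ecg", "bvp", "eeg", "pupil_left", "pupil_right"),
                  names(x))
  cat(sprintf("<multimodal_recording> %s over %.0f s\n",
              paste(ch, collapse = ", "), schedule_duration(x$schedule)))
  invisible(x)
}

#' Extract every feature family over every analysis window
#'
#' Preprocesses each available channel once over the whole recording, then
#' computes the GSR, HRV, BVP, EEG and pupil features in every
#' (phase, arousal session, segment) window, where segment is the whole
#' session and its low- and high-valence halves. Per-window failures are
#' `NA`-marked and the run continues.
#'
#' @param rec a `multimodal_recording`.
#' @param subject subject identifier for the output rows.
#' @param config a `run_config` (processing parameters).
#' @param segments subset of `c("whole", "low", "high")`.
#' @return a [feature_table()].
#' @export
extract_all_features <- function(rec, subject = "s1",
                                 config = default_config(),
                                 segments = c("whole", "low", "high")) {
  stopifnot(inherits(rec, "multimodal_recording"))
  schedule <- rec$schedule
  chains <- list()
  if (!is.null(rec$gsr)) {
    g5 <- preprocess_gsr(rec$gsr)
    decomp <- extract_phasic(g5)
    peaks <- detect_scr_peaks(decomp, config$gsr$onset_threshold)
    chains$gsr <- list(decomp = decomp, peaks = peaks)
  }
  if (!is.null(rec$ecg)) {
    ecg250 <- preprocess_ecg(rec$ecg)
    rr <- detect_rpeaks(ecg250)
    trk <- if (length(rr$intervals) > config$hrv$order + 3)
      track(rr, grid_step = config$hrv$grid_step, order = config$hrv$order,
            window = config$hrv$window, forgetting = config$hrv$forgetting)
    else NULL
    chains$hrv <- list(rr = rr, trk = trk)
  }
  if (!is.null(rec$bvp) && !is.null(chains$hrv) &&
      length(chains$hrv$rr$r_times) >= 2) {
    bvp250 <- preprocess_bvp(rec$bvp)
    chains$bvp <- suppressWarnings(locate_fiducials(bvp250, chains$hrv$rr))
  }
  if (!is.null(rec$eeg)) chains$eeg <- car_reference(rec$eeg)
  if (!is.null(rec$pupil_left) && !is.null(rec$pupil_right))
    chains$pupil <- suppressWarnings(clean_pupil(rec$pupil_left, rec$pupil_right))

  rows <- list()
  add <- function(phase, session, segment, values) {
    for (nm in names(values)) {
      v <- values[[nm]]
      rows[[length(rows) + 1L]] <<- data.frame(
        subject = subject, phase = phase, session = session,
        segment = segment, feature = nm,
        value = if (is.finite(v)) as.numeric(v) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  phases_here <- unique(stats::na.omit(schedule$sessions$phase))
  for (ph in phases_here) {
    levels_here <- schedule$sessions$arousal_level[
      !is.na(schedule$sessions$phase) & schedule$sessions$phase == ph &
        schedule$sessions$kind == "arousal"]
    for (lev in levels_here) {
      for (segm in segments) {
        vc <- if (segm == "whole") "any" else segm
        win <- select_windows(schedule, ph, "arousal", lev, vc)
        if (nrow(win) != 1) next
        w <- c(win$t_start[1], win$t_end[1])
        vals <- list()
        if (!is.null(chains$gsr)) {
          gf <- tryCatch(gsr_features(chains$gsr$decomp, chains$gsr$peaks, w),
                         error = function(e) NULL)
          if (!is.null(gf)) {
            names(gf) <- paste0("GSR_", c("n_peaks", "amp_peaks", "rise_time",
                                          "recovery_time", "avg", "sd",
                                          "max_signed_amp", "deriv_avg",
                                          "deriv_sd", "deriv_max", "env_avg"))
            vals <- c(vals, as.list(gf))
          }
        }
        if (!is.null(chains$hrv$trk)) {
          hf <- hrv_features(chains$hrv$trk, w)
          names(hf) <- paste0("RR_", c("mu", "sigma2", "VLF", "LF", "HF",
                                       "TOT", "LF_HF", "LFn", "HFn"))
          vals <- c(vals, as.list(hf))
        }
        if (!is.null(chains$bvp)) {
          bf <- bvp_features(chains$bvp, w)
          vals <- c(vals, list(BVP_VP = bf$vp, BVP_PAT = bf$pat))
        }
        if (!is.null(chains$eeg)) {
          ef <- tryCatch(
            eeg_features(chains$eeg, window = w,
                         segment_s = config$eeg$segment_s),
            error = function(e) NULL)
          if (!is.null(ef)) {
            names(ef) <- paste0("EEG_", gsub("(frontal|parietal)",
                                             "\\1", names(ef)))
            vals <- c(vals, as.list(ef))
          }
        }
        if (!is.null(chains$pupil)) {
          pf <- tryCatch(pupil_features(chains$pupil, w),
                         error = function(e) NULL)
          if (!is.null(pf)) {
            names(pf) <- paste0("PUPIL_", c("AVD", "SDD", "DLF", "DHF",
                                            "DVHF", "DLF_DHF", "DLFn", "DHFn"))
            vals <- c(vals, as.list(pf))
          }
        }
        add(ph, lev, segm, vals)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Simulate and compare a full multi-subject study
#'
#' Simulates `n_subjects` independent recordings (per-subject seeds derived
#' from the master seed; each subject gets its own phase-order
#' permutation), extracts all features, and runs the cross-phase
#' comparison for every requested feature key.
#'
#' @param config a `run_config`; `config$protocol` defines the (possibly
#'   scaled-down) timeline and `config$signals` which channels to simulate.
#' @param n_subjects number of subjects.
#' @param seed master seed.
#' @param effect_map per-phase ground-truth modulation, as in
#'   [simulate_experiment()].
#' @param features feature names to compare (default: all extracted).
#' @param sessions arousal sessions to compare (default: all).
#' @param segments segments to compare (default `"whole"`).
#' @return list with `features` (the pooled [feature_table()]) and
#'   `comparisons` (list of `comparison_result`, one per key that had
#'   enough complete blocks).
#' @export
run_study <- function(config = default_config(), n_subjects = 21, seed = 1,
                      effect_map = NULL, features = NULL, sessions = NULL,
                      segments = "whole") {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  tabs <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    sseed <- derive_seed(seed, 100 + s)
    pcfg <- do.call(protocol_config,
                    c(config$protocol[setdiff(names(config$protocol),
                                              "phase_order_seed")],
                      list(phase_order_seed = sseed %% 1e6)))
    schedule <- build_schedule(pcfg)
    rec <- simulate_experiment(schedule, effect_map = effect_map,
                               seed = sseed, signals = config$signals,
                               config = config)
    tabs[[s]] <- extract_all_features(rec, subject = sprintf("s%02d", s),
                                      config = config, segments = segments)
  }
  table <- do.call(rbind, tabs)
  class(table) <- c("feature_table", "data.frame")
  if (is.null(features)) features <- unique(table$feature)
  if (is.null(sessions)) sessions <- unique(table$session)
  comparisons <- list()
  for (f in features) for (se in sessions) for (sg in segments) {
    cmp <- tryCatch(
      compare_feature(table, f, se, sg, alpha = config$stats$alpha),
      error = function(e) NULL)
    if (!is.null(cmp))
      comparisons[[sprintf("%s|s%s|%s", f, se, sg)]] <- cmp
  }
  list(features = table, comparisons = comparisons, seed = seed,
       n_subjects = n_subjects)
}

#' Flatten comparison results into a report table
#'
#' One row per pairwise comparison (plus one omnibus row per key with
#' empty pair columns when the omnibus was not significant).
#'
#' @param comparisons list of `comparison_result` from [run_study()].
#' @return data.frame report.
#' @export
comparison_report <- function(comparisons) {
  rows <- lapply(comparisons, function(cm) {
    base <- data.frame(feature = cm$feature, session = cm$session,
                       segment = cm$segment, dimension = cm$dimension,
                       friedman_stat = cm$friedman_stat,
                       friedman_p = cm$friedman_p,
                       n_blocks = cm$n_blocks, stringsAsFactors = FALSE)
    if (is.null(cm$pairwise)) {
      cbind(base, phase_a = NA_character_, phase_b = NA_character_,
            corrected_p = NA_real_, significant = FALSE)
    } else {
      cbind(base[rep(1, nrow(cm$pairwise)), ],
            cm$pairwise[, c("phase_a", "phase_b", "corrected_p", "significant")])
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
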