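## Three-phase elicitation protocol: IAPS-only (pictures), IADS-only
## (sounds), IAPS+IADS (semantically matched pairs). Each phase alternates
## four arousal sessions of increasing level with 90 s neutral sessions;
## the experiment opens with a 5 min grey-screen rest and phases are
## separated by 2 min rests. Timeline coordinates are seconds from the
## experiment start; all windows are half-open [t_start, t_end).

PHASES <- c("IAPS", "IADS", "IAPS+IADS")
PHASE_MODALITY <- c("IAPS" = "image", "IADS" = "sound", "IAPS+IADS" = "image+sound")

#' Protocol configuration
#'
#' Element durations and counts of the elicitation protocol. Defaults match
#' the published design: 5 min initial rest, four arousal sessions per phase
#' of six 15 s stimuli each (first half low valence, second half high),
#' alternated with 90 s neutral sessions, phases separated by 2 min rests.
#'
#' @param initial_rest_s initial grey-screen rest (s).
#' @param neutral_s neutral session duration (s).
#' @param stimulus_s single stimulus duration (s).
#' @param interphase_rest_s rest between phases (s).
#' @param n_phases number of stimulation phases (taken from the head of the
#'   IAPS/IADS/IAPS+IADS list).
#' @param n_arousal_sessions arousal sessions per phase (levels 1..n).
#' @param n_stimuli stimuli per arousal session (must be even: half low,
#'   half high valence).
#' @param phase_order_seed integer seed for the uniform phase permutation.
#' @return a validated list of class `protocol_config`.
#' @export
protocol_config <- function(initial_rest_s = 300, neutral_s = 90,
                            stimulus_s = 15, interphase_rest_s = 120,
                            n_phases = 3, n_arousal_sessions = 4,
                            n_stimuli = 6, phase_order_seed = 1L) {
  cfg <- list(initial_rest_s = initial_rest_s, neutral_s = neutral_s,
              stimulus_s = stimulus_s, interphase_rest_s = interphase_rest_s,
              n_phases = as.integer(n_phases),
              n_arousal_sessions = as.integer(n_arousal_sessions),
              n_stimuli = as.integer(n_stimuli),
              phase_order_seed = as.integer(phase_order_seed))
  durs <- c(cfg$initial_rest_s, cfg$neutral_s, cfg$stimulus_s, cfg$interphase_rest_s)
  if (any(!is.finite(durs)) || any(durs <= 0))
    stop("protocol durations must be positive")
  if (cfg$n_phases < 0 || cfg$n_arousal_sessions < 1 || cfg$n_stimuli < 1)
    stop("protocol counts must be positive (n_phases may be 0)")
  if (cfg$n_phases > length(PHASES))
    stop(sprintf("at most %d phases are defined", length(PHASES)))
  if (cfg$n_stimuli %% 2L != 0L)
    stop("n_stimuli must be even (half low, half high valence)")
  class(cfg) <- "protocol_config"
  cfg
}

make_events <- function(phase, n_stimuli, stimulus_s, t0, arousal_level) {
  onset <- t0 + (seq_len(n_stimuli) - 1) * stimulus_s
  valence <- if (arousal_level == 0) rep("neutral", n_stimuli)
             else rep(c("low", "high"), each = n_stimuli / 2)
  data.frame(phase = phase,
             modality = unname(PHASE_MODALITY[phase]),
             valence_class = valence,
             arousal_level = arousal_level,
             onset = onset, duration = stimulus_s,
             stringsAsFactors = FALSE)
}

#' Build the experimental timeline
#'
#' Lays out the full protocol: initial rest, then the (seed-permuted) phase
#' blocks, each alternating arousal sessions at strictly increasing levels
#' 1..n with neutral sessions (one neutral after each arousal session), with
#' an inter-phase rest between consecutive blocks. With the default
#' configuration each phase block lasts 720 s and the whole timeline 2700 s.
#'
#' @param config a [protocol_config()].
#' @return a `protocol_schedule`: list with `sessions` (one row per session
#'   or rest window: phase, kind, arousal_level, t_start, t_end), `events`
#'   (one row per stimulus) and the `config`.
#' @export
build_schedule <- function(config = protocol_config()) {
  stopifnot(inherits(config, "protocol_config"))
  empty_sessions <- data.frame(phase = character(), kind = character(),
                               arousal_level = integer(),
                               t_start = numeric(), t_end = numeric(),
                               stringsAsFactors = FALSE)
  if (config$n_phases == 0L) {
    return(structure(list(sessions = empty_sessions,
                          events = make_events("IAPS", 2, 1, 0, 0)[0, ],
                          config = config),
                     class = "protocol_schedule"))
  }
  phase_order <- with_seed(config$phase_order_seed,
                           sample(PHASES[seq_len(config$n_phases)]))
  sessions <- list(); events <- list()
  t <- 0
  add <- function(phase, kind, level, dur) {
    sessions[[length(sessions) + 1L]] <<- data.frame(
      phase = phase, kind = kind, arousal_level = level,
      t_start = t, t_end = t + dur, stringsAsFactors = FALSE)
    t <<- t + dur
  }
  add(NA_character_, "rest", NA_integer_, config$initial_rest_s)
  arousal_dur <- config$n_stimuli * config$stimulus_s
  for (pi in seq_along(phase_order)) {
    ph <- phase_order[pi]
    for (lev in seq_len(config$n_arousal_sessions)) {
      events[[length(events) + 1L]] <-
        make_events(ph, config$n_stimuli, config$stimulus_s, t, lev)
      add(ph, "arousal", lev, arousal_dur)
      events[[length(events) + 1L]] <-
        make_events(ph, config$n_stimuli, config$neutral_s / config$n_stimuli, t, 0L)
      add(ph, "neutral", 0L, config$neutral_s)
    }
    if (pi < length(phase_order))
      add(NA_character_, "rest", NA_integer_, config$interphase_rest_s)
  }
  structure(list(sessions = do.call(rbind, sessions),
                 events = do.call(rbind, events),
                 config = config),
            class = "protocol_schedule")
}

#' @export
print.protocol_schedule <- function(x, ...) {
  cat(sprintf("<protocol_schedule> %d sessions, %d stimuli, %.0f s total\n",
              nrow(x$sessions), nrow(x$events), schedule_duration(x)))
  invisible(x)
}

#' Total scheduled duration in seconds
#' @param schedule a `protocol_schedule`.
#' @export
schedule_duration <- function(schedule) {
  if (nrow(schedule$sessions) == 0) return(0)
  max(schedule$sessions$t_end)
}

#' Select analysis windows from a schedule
#'
#' Returns the half-open time intervals over which features are extracted.
#' For `valence_class = "low"` ("high") the merged span of the first-half
#' (second-half) stimuli of each matching arousal session is returned.
#'
#' @param schedule a `protocol_schedule` from [build_schedule()].
#' @param phase `"IAPS"`, `"IADS"` or `"IAPS+IADS"` (ignored for
#'   `kind = "rest"`).
#' @param kind `"rest"`, `"neutral"` or `"arousal"`.
#' @param arousal_level session level to select (NULL = all); must exist in
#'   the schedule.
#' @param valence_class `"any"`, `"low"` or `"high"`.
#' @return data.frame with columns `t_start`, `t_end` (seconds).
#' @export
select_windows <- function(schedule, phase, kind,
                           arousal_level = NULL, valence_class = "any") {
  stopifnot(inherits(schedule, "protocol_schedule"))
  kinds <- c("rest", "neutral", "arousal")
  if (!kind %in% kinds) stop(sprintf("unknown kind '%s'", kind))
  if (!valence_class %in% c("any", "low", "high"))
    stop(sprintf("unknown valence_class '%s'", valence_class))
  s <- schedule$sessions
  if (kind == "rest") {
    sel <- s[s$kind == "rest", , drop = FALSE]
    return(sel[, c("t_start", "t_end")])
  }
  if (!phase %in% PHASES) stop(sprintf("unknown phase '%s'", phase))
  sel <- s[!is.na(s$phase) & s$phase == phase & s$kind == kind, , drop = FALSE]
  if (!is.null(arousal_level) && kind == "arousal") {
    if (!arousal_level %in% sel$arousal_level)
      stop(sprintf("arousal level %s not present in phase %s", arousal_level, phase))
    sel <- sel[sel$arousal_level == arousal_level, , drop = FALSE]
  }
  if (valence_class == "any" || kind == "neutral")
    return(sel[, c("t_start", "t_end")])
  # valence halves: merge the contiguous first/second-half stimulus spans
  out <- lapply(seq_len(nrow(sel)), function(i) {
    ev <- schedule$events
    ev <- ev[ev$onset >= sel$t_start[i] & ev$onset < sel$t_end[i] &
               ev$valence_class == valence_class, , drop = FALSE]
    if (nrow(ev) == 0) return(NULL)
    data.frame(t_start = min(ev$onset), t_end = max(ev$onset + ev$duration))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(t_start = numeric(), t_end = numeric()) else out
}

#' Write a protocol marker file
#'
#' Delimited (tab-separated) marker stream: one row per session window and
#' one per stimulus event, columns onset_s, duration_s, phase, kind,
#' arousal_level, valence_class, modality.
#'
#' @param schedule a `protocol_schedule`.
#' @param path output file path.
#' @export
write_markers <- function(schedule, path) {
  s <- schedule$sessions
  rows_s <- data.frame(onset_s = s$t_start, duration_s = s$t_end - s$t_start,
                       phase = ifelse(is.na(s$phase), "", s$phase),
                       kind = s$kind,
                       arousal_level = ifelse(is.na(s$arousal_level), -1L,
                                              s$arousal_level),
                       valence_class = "any", modality = "",
                       stringsAsFactors = FALSE)
  e <- schedule$events
  rows_e <- data.frame(onset_s = e$onset, duration_s = e$duration,
                       phase = e$phase, kind = "stimulus",
                       arousal_level = e$arousal_level,
                       valence_class = e$valence_class, modality = e$modality,
                       stringsAsFactors = FALSE)
  out <- rbind(rows_s, rows_e)
  out <- out[order(out$onset_s, out$kind != "stimulus"), ]
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a protocol marker file written by [write_markers()]
#'
#' @param path marker file path.
#' @param config optional [protocol_config()] to attach (defaults are used
#'   otherwise; the timeline itself comes from the file).
#' @return a `protocol_schedule`.
#' @export
read_markers <- function(path, config = protocol_config()) {
  m <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  ses <- m[m$kind != "stimulus", , drop = FALSE]
  ev <- m[m$kind == "stimulus", , drop = FALSE]
  sessions <- data.frame(phase = ifelse(ses$phase == "", NA_character_, ses$phase),
                         kind = ses$kind,
                         arousal_level = ifelse(ses$arousal_level < 0,
                                                NA_integer_,
                                                as.integer(ses$arousal_level)),
                         t_start = ses$onset_s,
                         t_end = ses$onset_s + ses$duration_s,
                         stringsAsFactors = FALSE)
  events <- data.frame(phase = ev$phase, modality = ev$modality,
                       valence_class = ev$valence_class,
                       arousal_level = as.integer(ev$arousal_level),
                       onset = ev$onset_s, duration = ev$duration_s,
                       stringsAsFactors = FALSE)
  structure(list(sessions = sessions, events = events, config = config),
            class = "protocol_schedule")
}

#' Check schedule invariants
#'
#' Verifies the structural invariants of a schedule: positive durations,
#' time-ordered non-overlapping sessions, events contained in their
#' sessions, strictly increasing arousal levels within each phase, and the
#' low/high valence split of arousal sessions. Errors on first violation.
#'
#' @param schedule a `protocol_schedule`.
#' @return `TRUE` invisibly.
#' @export
validate_schedule <- function(schedule) {
  s <- schedule$sessions; e <- schedule$events
  if (nrow(s) == 0) return(invisible(TRUE))
  if (any(s$t_end <= s$t_start)) stop("non-positive session duration")
  if (is.unsorted(s$t_start)) stop("sessions out of order")
  if (any(utils::head(s$t_end, -1) > utils::tail(s$t_start, -1) + 1e-9))
    stop("overlapping sessions")
  if (nrow(e)) {
    if (any(e$duration <= 0)) stop("non-positive stimulus duration")
    bad <- xor(e$valence_class == "neutral", e$arousal_level == 0)
    if (any(bad)) stop("valence 'neutral' must coincide with arousal level 0")
  }
  for (ph in unique(stats::na.omit(s$phase))) {
    lv <- s$arousal_level[!is.na(s$phase) & s$phase == ph & s$kind == "arousal"]
    if (any(diff(lv) <= 0)) stop("arousal levels must strictly increase")
    for (i in which(!is.na(s$phase) & s$phase == ph & s$kind == "arousal")) {
      ev <- e[e$onset >= s$t_start[i] - 1e-9 & e$onset < s$t_end[i], ]
      ev <- ev[ev$arousal_level > 0, ]
      if (any(ev$onset + ev$duration > s$t_end[i] + 1e-9))
        stop("stimulus extends beyond its session")
      nlow <- sum(ev$valence_class == "low")
      nhigh <- sum(ev$valence_class == "high")
      if (nlow != nhigh) stop("arousal session must split low/high evenly")
      if (nlow && max(ev$onset[ev$valence_class == "low"]) >=
            min(ev$onset[ev$valence_class == "high"]))
        stop("low-valence stimuli must precede high-valence stimuli")
    }
  }
  invisible(TRUE)
}
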