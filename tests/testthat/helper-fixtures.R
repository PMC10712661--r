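# Shared fixtures, built in code at test time.

# sinusoid trace
sine_trace <- function(freq, duration, rate, amp = 1, phase = 0) {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  signal_trace(amp * sin(2 * pi * freq * t + phase), rate)
}

# amplitude of the central portion of a single-channel trace
core_amp <- function(trace, trim = 0.15) {
  x <- st_channel(trace)
  n <- length(x)
  idx <- max(1, round(trim * n)):round((1 - trim) * n)
  max(abs(x[idx]))
}

# small protocol for pipeline tests: 1 arousal session/phase, short rests
scaled_protocol <- function(n_arousal = 1) {
  protocol_config(initial_rest_s = 20, neutral_s = 30, stimulus_s = 15,
                  interphase_rest_s = 15, n_phases = 3,
                  n_arousal_sessions = n_arousal, n_stimuli = 6,
                  phase_order_seed = 1)
}

scaled_config <- function(signals = "gsr", n_arousal = 1) {
  cfg <- default_config()
  cfg$protocol <- list(initial_rest_s = 20, neutral_s = 30, stimulus_s = 15,
                       interphase_rest_s = 15, n_phases = 3,
                       n_arousal_sessions = n_arousal, n_stimuli = 6,
                       phase_order_seed = 1)
  cfg$signals <- signals
  cfg$rates <- list(gsr = 64, ecg = 512, bvp = 512, eeg = 150, pupil = 60)
  cfg
}

# subject x phase feature table from a matrix of values
table_from_matrix <- function(m, feature = "f", session = 1,
                              segment = "whole",
                              phases = c("IAPS", "IADS", "IAPS+IADS")) {
  n <- nrow(m)
  feature_table(subject = rep(seq_len(n), times = ncol(m)),
                phase = rep(phases[seq_len(ncol(m))], each = n),
                session = session, segment = segment, feature = feature,
                value = as.numeric(m))
}
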