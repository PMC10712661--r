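test_that("default schedule reproduces the design counts and durations", {
  sch <- build_schedule(protocol_config())
  expect_true(validate_schedule(sch))
  s <- sch$sessions
  phases <- unique(na.omit(s$phase))
  expect_setequal(phases, c("IAPS", "IADS", "IAPS+IADS"))
  for (ph in phases) {
    ar <- s[!is.na(s$phase) & s$phase == ph & s$kind == "arousal", ]
    expect_equal(nrow(ar), 4)
    expect_equal(ar$arousal_level, 1:4)          # strictly increasing 1..4
    expect_equal(ar$t_end - ar$t_start, rep(90, 4))  # 6 x 15 s
    nu <- s[!is.na(s$phase) & s$phase == ph & s$kind == "neutral", ]
    expect_equal(nrow(nu), 4)
    expect_equal(nu$t_end - nu$t_start, rep(90, 4))
    # every arousal session has 6 stimuli of 15 s, 3 low then 3 high
    for (i in seq_len(nrow(ar))) {
      ev <- sch$events[sch$events$onset >= ar$t_start[i] &
                         sch$events$onset < ar$t_end[i] &
                         sch$events$arousal_level > 0, ]
      expect_equal(nrow(ev), 6)
      expect_equal(ev$duration, rep(15, 6))
      expect_equal(ev$valence_class, rep(c("low", "high"), each = 3))
    }
  }
  rests <- s[s$kind == "rest", ]
  expect_equal(rests$t_end - rests$t_start, c(300, 120, 120))
  expect_equal(rests$t_start[1], 0)
  expect_equal(schedule_duration(sch), 2700)  # 45 min from the elements
})

test_that("total duration is invariant to the phase-order seed", {
  durations <- vapply(1:6, function(s) {
    schedule_duration(build_schedule(protocol_config(phase_order_seed = s)))
  }, numeric(1))
  expect_true(all(durations == durations[1]))
  # and phase order really is permuted by the seed
  orders <- vapply(1:10, function(s) {
    sch <- build_schedule(protocol_config(phase_order_seed = s))
    paste(unique(na.omit(sch$sessions$phase)), collapse = "|")
  }, character(1))
  expect_gt(length(unique(orders)), 1)
})

test_that("select_windows returns session and valence-half intervals", {
  sch <- build_schedule(protocol_config())
  w <- select_windows(sch, "IADS", "arousal", 1, "any")
  expect_equal(nrow(w), 1)
  expect_equal(w$t_end - w$t_start, 90)
  wl <- select_windows(sch, "IADS", "arousal", 1, "low")
  expect_equal(wl$t_end - wl$t_start, 45)
  wh <- select_windows(sch, "IADS", "arousal", 1, "high")
  expect_equal(wh$t_end - wh$t_start, 45)
  expect_equal(wl$t_end, wh$t_start)  # halves abut
  expect_error(select_windows(sch, "IAPS", "arousal", 5), "not present")
  expect_error(select_windows(sch, "XXX", "arousal", 1), "unknown phase")
  expect_error(select_windows(sch, "IAPS", "bogus"), "unknown kind")
})

test_that("windows tile each phase block with no overlap", {
  sch <- build_schedule(protocol_config())
  for (ph in c("IAPS", "IADS", "IAPS+IADS")) {
    w <- rbind(select_windows(sch, ph, "arousal"),
               select_windows(sch, ph, "neutral"))
    w <- w[order(w$t_start), ]
    expect_equal(sum(w$t_end - w$t_start), 720)  # 4 x (90 + 90)
    expect_true(all(abs(head(w$t_end, -1) - tail(w$t_start, -1)) < 1e-9))
  }
})

test_that("arousal sessions split valence halves 3/3", {
  sch <- build_schedule(protocol_config())
  ev <- sch$events[sch$events$arousal_level > 0, ]
  byses <- split(ev, paste(ev$phase, ev$arousal_level))
  for (b in byses) {
    expect_equal(sum(b$valence_class == "low"), 3)
    expect_equal(sum(b$valence_class == "high"), 3)
  }
})

test_that("degenerate and invalid configurations are handled", {
  empty <- build_schedule(protocol_config(n_phases = 0))
  expect_equal(nrow(empty$sessions), 0)
  expect_equal(schedule_duration(empty), 0)
  expect_true(validate_schedule(empty))
  expect_error(protocol_config(neutral_s = -1), "positive")
  expect_error(protocol_config(n_stimuli = 0), "positive|even")
  expect_error(protocol_config(n_arousal_sessions = 0), "positive")
})

test_that("marker files round-trip the schedule", {
  sch <- build_schedule(protocol_config(phase_order_seed = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_markers(sch, path)
  sch2 <- read_markers(path)
  expect_equal(sch2$sessions$t_start, sch$sessions$t_start)
  expect_equal(sch2$sessions$kind, sch$sessions$kind)
  expect_equal(sch2$events$valence_class, sch$events$valence_class)
  expect_true(validate_schedule(sch2))
  w1 <- select_windows(sch, "IAPS", "arousal", 2, "low")
  w2 <- select_windows(sch2, "IAPS", "arousal", 2, "low")
  expect_equal(w1, w2)
})
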