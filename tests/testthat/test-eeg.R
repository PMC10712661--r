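test_that("montage: unique labels, aliases, regions", {
  m <- montage_1020()
  expect_equal(length(m$labels), 21)
  expect_false(anyDuplicated(m$labels) > 0)
  expect_equal(resolve_channel("T3"), "T7/T3")
  expect_equal(resolve_channel("Pz"), "Pz")
  expect_error(resolve_channel("XX9"), "unknown channel")
  expect_setequal(m$neighbors[["Pz"]], c("P3", "P4", "Cz"))
})

test_that("interpolate_channel averages the neighbor set", {
  m <- montage_1020()
  n <- 100
  mk <- function(fill) {
    s <- matrix(0, n, 21, dimnames = list(NULL, m$labels))
    for (ch in names(fill)) s[, ch] <- fill[[ch]]
    signal_trace(s, 300, channels = m$labels)
  }
  # neighbors identical -> interpolated equals them
  tr <- mk(list(P3 = 1, P4 = 1, Cz = 1, Pz = 99))
  out <- interpolate_channel(tr, "Pz", m)
  expect_equal(unname(out$samples[, "Pz"]), rep(1, n))
  # neighbors a and -a cancel
  tr2 <- mk(list(F3 = 2, Fz = -2, C3 = 1, `T7/T3` = -1))
  out2 <- interpolate_channel(tr2, "C3", m)  # neighbors F3, Cz, P3, T7/T3
  expect_equal(unname(out2$samples[, "C3"]), rep((2 + 0 + 0 - 1) / 4, n))
  # constant neighbors average: Pz from {1, 2, 3}
  tr3 <- mk(list(P3 = 1, P4 = 2, Cz = 3))
  out3 <- interpolate_channel(tr3, "Pz", m)
  expect_equal(unname(out3$samples[, "Pz"]), rep(2, n))
  expect_error(interpolate_channel(tr, "QQ", m), "unknown channel")
})

test_that("common-average reference: zero mean, common-mode removal, idempotence", {
  eeg <- simulate_eeg(duration = 4, rate = 150, seed = 20)
  m <- montage_1020()
  car <- car_reference(eeg)
  scalp <- setdiff(m$labels, m$mastoids)
  expect_lt(max(abs(rowMeans(car$samples[, scalp]))), 1e-10)
  # a common sinusoid added to every channel is removed
  common <- sin(2 * pi * 7 * st_times(eeg))
  dirty <- signal_trace(eeg$samples + common, eeg$rate, channels = eeg$channels)
  expect_lt(max(abs(car_reference(dirty)$samples[, scalp] -
                      car$samples[, scalp])), 1e-10)
  # idempotent
  expect_equal(car_reference(car)$samples, car$samples, tolerance = 1e-12)
})

test_that("band_filter passes in-band and rejects out-of-band tones", {
  inb <- band_filter(sine_trace(10, 20, 300), "alpha")
  expect_gt(core_amp(inb), 0.9)
  outb <- band_filter(sine_trace(25, 20, 300), "alpha")
  expect_lt(core_amp(outb), 0.1)
  z <- band_filter(signal_trace(numeric(3000), 300), "beta")
  expect_equal(max(abs(z$samples)), 0)
  expect_error(band_filter(sine_trace(10, 5, 300), "gamma"))
})

test_that("eeg_features recovers set band-power ratios", {
  pw <- rbind(frontal = c(delta = 20, theta = 10, alpha = 15, beta = 20),
              parietal = c(delta = 20, theta = 10, alpha = 15, beta = 10),
              other = c(delta = 20, theta = 10, alpha = 15, beta = 10))
  eeg <- car_reference(simulate_eeg(eeg_ground_truth(pw), 40, 300, seed = 21))
  f <- eeg_features(eeg, window = c(0, 40))
  expect_gt(f$attention_frontal, 1.8)
  expect_lt(f$attention_frontal, 2.2)
  expect_true(all(unlist(f[, 1:8]) >= 0))
  # equal powers in every band -> both attention indices ~ 1
  pweq <- matrix(15, 3, 4, dimnames = list(c("frontal", "parietal", "other"),
                                           c("delta", "theta", "alpha", "beta")))
  eq <- car_reference(simulate_eeg(eeg_ground_truth(pweq), 40, 300, seed = 22))
  feq <- eeg_features(eq, window = c(0, 40))
  expect_equal(feq$attention_frontal, 1, tolerance = 0.2)
  expect_equal(feq$attention_parietal, 1, tolerance = 0.2)
  # flat zero EEG: powers 0, attention missing
  z <- simulate_eeg(eeg_ground_truth(pweq * 0), 10, 300)
  fz <- eeg_features(z, window = c(0, 10))
  expect_equal(fz$beta_frontal, 0)
  expect_true(is.na(fz$attention_frontal))
})

test_that("region power is invariant to channel ordering", {
  eeg <- simulate_eeg(duration = 10, rate = 150, seed = 23)
  perm <- sample(ncol(eeg$samples))
  shuffled <- signal_trace(eeg$samples[, perm], eeg$rate,
                           channels = eeg$channels[perm])
  f1 <- eeg_features(eeg, window = c(0, 10))
  f2 <- eeg_features(shuffled, window = c(0, 10))
  expect_equal(f1, f2, tolerance = 1e-12)
})
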