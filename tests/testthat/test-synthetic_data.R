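test_that("inverse-Gaussian RR generator matches its analytic moments", {
  # degenerate variance: huge shape -> all intervals at theta0
  rr0 <- simulate_rr_ig(100, rr_ground_truth(0.8, lambda = 1e9), seed = 1)
  expect_lt(sd(rr0$intervals) / mean(rr0$intervals), 0.01)
  expect_equal(mean(rr0$intervals), 0.8, tolerance = 1e-3)
  expect_true(all(diff(rr0$r_times) > 0))
  # Monte-Carlo mean vs analytic inverse-Gaussian mean at n = 10000
  rr1 <- simulate_rr_ig(10000 * 0.8, rr_ground_truth(0.8, lambda = 50), seed = 2)
  se <- sqrt(0.8^3 / 50 / length(rr1$intervals))
  expect_lt(abs(mean(rr1$intervals) - 0.8), 3 * se)
  # unstable AR rejected
  expect_error(rr_ground_truth(0.8, ar_coeffs = c(1.2), lambda = 50),
               "unstable")
})

test_that("mean modulation at 0.1 Hz shows up in the LF band of the RR spectrum", {
  rr <- simulate_rr_ig(400, rr_ground_truth(0.8, lambda = 200,
                                            mean_modulation = list(c(0.1, 0.1))),
                       seed = 3)
  # Welch oracle on the evenly resampled interval series
  tg <- seq(rr$r_times[2], max(rr$r_times), by = 0.25)
  iv <- approx(rr$r_times[-1], rr$intervals, xout = tg)$y
  ps <- welch_psd(signal_trace(iv, 4), 512)
  pk <- ps$frequencies[-1][which.max(ps$density[-1, 1])]
  expect_gte(pk, 0.04)
  expect_lte(pk, 0.15)
})

test_that("GSR generator: peaks recoverable, sub-threshold invisible, tonic clean", {
  # tonic only, no noise -> phasic ~ 0
  g0 <- simulate_gsr(scr_ground_truth(tonic_level = 2), 60, 256, noise_sd = 0)
  d0 <- extract_phasic(preprocess_gsr(g0))
  expect_lt(max(abs(st_channel(d0$phasic))), 1e-6)
  # 3 events of 0.5 uS, 20 s apart -> detector finds exactly 3
  g3 <- simulate_gsr(scr_ground_truth(c(20, 40, 60), rep(0.5, 3)), 90, 256,
                     seed = 4)
  pk <- detect_scr_peaks(extract_phasic(preprocess_gsr(g3)))
  expect_equal(nrow(pk), 3)
  expect_equal(pk$amplitude, rep(0.5, 3), tolerance = 0.1)
  # single 0.005 uS event: below the 0.01 uS onset threshold
  gs <- simulate_gsr(scr_ground_truth(30, 0.005), 60, 256, seed = 5)
  expect_equal(nrow(detect_scr_peaks(extract_phasic(preprocess_gsr(gs)))), 0)
  # events outside the trace rejected
  expect_error(simulate_gsr(scr_ground_truth(70, 0.5), 60, 256), "inside")
})

test_that("ECG/BVP generator: controllable arrival time and pulse amplitude", {
  rr <- rr_series(seq(0.5, 60, by = 0.8))
  tr <- simulate_ecg_bvp(rr, bvp_ground_truth(pat = 0.25, vp_amplitude = 1),
                         rate = 1024)
  det <- detect_rpeaks(preprocess_ecg(tr$ecg, target_rate = 256))
  expect_equal(length(det$r_times), length(rr$r_times))
  fid <- locate_fiducials(preprocess_bvp(tr$bvp, target_rate = 250), det)
  bf <- bvp_features(fid)
  expect_lt(abs(bf$pat - 0.25), 1 / 250)   # within one sample at 250 Hz
  expect_equal(bf$vp, 1.0, tolerance = 0.02)
  # empty series -> empty traces of the requested duration
  e <- simulate_ecg_bvp(rr_series(numeric(0)), duration = 2, rate = 512)
  expect_equal(nrow(e$ecg$samples), 1024)
  expect_equal(max(abs(e$ecg$samples)), 0)
  # pat must be below the minimum RR interval
  expect_error(simulate_ecg_bvp(rr, bvp_ground_truth(pat = 0.9)), "pat")
})

test_that("EEG generator: band powers land where requested", {
  pw <- rbind(frontal = c(delta = 20, theta = 10, alpha = 15, beta = 20),
              parietal = c(delta = 20, theta = 10, alpha = 15, beta = 10),
              other = c(delta = 20, theta = 10, alpha = 15, beta = 10))
  eeg <- simulate_eeg(eeg_ground_truth(pw), 40, 300, seed = 6)
  f <- eeg_features(eeg, window = c(0, 40))
  expect_gt(f$attention_frontal, 1.8)   # beta = 2 x theta
  expect_lt(f$attention_frontal, 2.2)
  expect_equal(f$attention_parietal, 1, tolerance = 0.2)
  # all powers 0 -> flat zero channels
  z <- simulate_eeg(eeg_ground_truth(matrix(0, 3, 4,
        dimnames = list(c("frontal", "parietal", "other"),
                        c("delta", "theta", "alpha", "beta")))), 10, 300)
  expect_equal(max(abs(z$samples)), 0)
})

test_that("pupil generator: oscillations, blinks and baseline behave", {
  # slow oscillation dominates DLF over DHF
  p <- simulate_pupil(pupil_ground_truth(5, list(c(0.1, 0.2)), noise_sd = 0.01),
                      120, 60, seed = 7)
  pf <- pupil_features(clean_pupil(p$left, p$right))
  expect_gt(pf$dlf_dhf, 1)
  # left-only blink -> cleaned diameter equals the right eye there
  pb <- simulate_pupil(pupil_ground_truth(5, list(c(0.1, 0.2)),
                                          blink_left = list(c(10, 10.5)),
                                          noise_sd = 0), 30, 60)
  pn <- simulate_pupil(pupil_ground_truth(5, list(c(0.1, 0.2)), noise_sd = 0),
                       30, 60)
  expect_equal(st_channel(clean_pupil(pb$left, pb$right)),
               st_channel(clean_pupil(pn$left, pn$right)), tolerance = 1e-9)
  # constant 5 mm baseline, no oscillation/noise -> AVD 5, SDD ~ 0
  pc <- simulate_pupil(pupil_ground_truth(5, noise_sd = 0), 60, 60)
  pfc <- pupil_features(clean_pupil(pc$left, pc$right))
  expect_equal(pfc$avd, 5, tolerance = 1e-6)
  expect_lt(pfc$sdd, 1e-6)
  expect_error(pupil_ground_truth(baseline = 1), "physiological")
})

test_that("all generators are deterministic under a fixed seed", {
  r1 <- simulate_rr_ig(60, seed = 42); r2 <- simulate_rr_ig(60, seed = 42)
  expect_identical(r1$r_times, r2$r_times)
  g1 <- simulate_gsr(scr_ground_truth(10, 0.5), 30, 64, seed = 42)
  g2 <- simulate_gsr(scr_ground_truth(10, 0.5), 30, 64, seed = 42)
  expect_identical(g1$samples, g2$samples)
  e1 <- simulate_eeg(duration = 5, rate = 150, seed = 42)
  e2 <- simulate_eeg(duration = 5, rate = 150, seed = 42)
  expect_identical(e1$samples, e2$samples)
  p1 <- simulate_pupil(duration = 5, rate = 60, seed = 42)
  p2 <- simulate_pupil(duration = 5, rate = 60, seed = 42)
  expect_identical(p1$left$samples, p2$left$samples)
  # and the seeded call does not disturb the caller's RNG stream
  set.seed(1); a <- rnorm(1)
  set.seed(1); invisible(simulate_rr_ig(10, seed = 9)); b <- rnorm(1)
  expect_identical(a, b)
})

test_that("simulate_experiment records per-phase effects and is reproducible", {
  cfg <- scaled_config(signals = c("gsr"))
  sch <- build_schedule(scaled_protocol())
  r1 <- simulate_experiment(sch, effect_map = list(IADS = list(scr_amp = 2)),
                            seed = 5, signals = "gsr", config = cfg)
  r2 <- simulate_experiment(sch, effect_map = list(IADS = list(scr_amp = 2)),
                            seed = 5, signals = "gsr", config = cfg)
  expect_identical(r1$gsr$samples, r2$gsr$samples)
  # IADS events got the doubled amplitudes, on average
  ev <- r1$truth$scr
  ph <- sapply(ev$event_times, function(tt) {
    s <- sch$sessions
    i <- findInterval(tt, s$t_start)
    s$phase[i]
  })
  expect_gt(mean(ev$amplitudes[ph == "IADS"]),
            mean(ev$amplitudes[ph == "IAPS"]))
})
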