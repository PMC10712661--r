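test_that("preprocess_ecg rate contract and stopband", {
  tr <- signal_trace(rep(1, 2048 * 10), 2048)
  out <- preprocess_ecg(tr)
  expect_equal(out$rate, 250)
  expect_equal(nrow(out$samples), 2500)
  expect_equal(st_channel(out), rep(1, 2500), tolerance = 1e-8)
  tone <- sine_trace(200, 10, 2048)
  expect_lt(core_amp(preprocess_ecg(tone)), 0.1)
})

test_that("detect_rpeaks recovers a regular spike train and flags gaps", {
  rr <- rr_series(seq(0.5, 60, by = 0.8))
  tr <- simulate_ecg_bvp(rr, rate = 2048)
  det <- detect_rpeaks(preprocess_ecg(tr$ecg))
  expect_equal(length(det$r_times), length(rr$r_times))
  expect_true(all(abs(det$intervals - 0.8) < 0.004))
  # flat signal -> empty series with warning
  expect_warning(flat <- detect_rpeaks(signal_trace(numeric(2500), 250)),
                 "no beats")
  expect_equal(length(flat$r_times), 0)
  # a widened gap that cannot be re-filled is flagged by the guard
  times <- c(seq(0.5, 20, by = 0.8), seq(24.1, 40, by = 0.8))
  tr2 <- simulate_ecg_bvp(rr_series(times), rate = 2048)
  det2 <- detect_rpeaks(preprocess_ecg(tr2$ecg))
  expect_gt(length(attr(det2, "guard_flags")), 0)
})

test_that("ig_density matches quadrature oracles over random parameters", {
  set.seed(13)
  for (i in 1:20) {
    mu <- runif(1, 0.4, 1.4)
    shape <- runif(1, 5, 500)
    norm <- integrate(ig_density, 0, Inf, mu = mu, shape = shape,
                      rel.tol = 1e-10)$value
    m1 <- integrate(function(w) w * ig_density(w, mu, shape), 0, Inf,
                    rel.tol = 1e-10)$value
    expect_equal(norm, 1, tolerance = 1e-6)
    expect_equal(m1, mu, tolerance = 1e-6)
  }
  expect_error(ig_density(-1, 0.8, 50), "positive")
  # density vanishes at w -> 0+
  expect_lt(ig_density(1e-6, 0.8, 50), 1e-12)
})

test_that("sigma^2 = mu^3 / shape exactly, and the CDF matches quadrature", {
  mu <- 0.8; shape <- 50
  v <- integrate(function(w) (w - mu)^2 * ig_density(w, mu, shape), 0, Inf,
                 rel.tol = 1e-10)$value
  expect_equal(v, mu^3 / shape, tolerance = 1e-6)
  q <- integrate(ig_density, 0, 1.1, mu = mu, shape = shape,
                 rel.tol = 1e-10)$value
  expect_equal(ig_cdf(1.1, mu, shape), q, tolerance = 1e-8)
})

test_that("mu_rr implements the AR mean exactly", {
  expect_equal(mu_rr(ig_params(0.7, shape = 50)), 0.7)
  expect_equal(mu_rr(ig_params(0.1, 0.5, shape = 50), 0.8), 0.5)
  # constant history r with sum(theta) = s -> theta0 + s * r
  p <- ig_params(0.2, c(0.3, 0.2, 0.1), shape = 50)
  expect_equal(mu_rr(p, rep(0.9, 3)), 0.2 + 0.6 * 0.9)
  expect_error(mu_rr(p, c(0.8)), "history length")
})

test_that("local_ml_fit recovers generator parameters", {
  # p = 0: theta0 within 2%, lambda within 15% at ~n=500 beats
  rr <- simulate_rr_ig(500 * 0.8, rr_ground_truth(0.8, lambda = 50), seed = 14)
  fit <- local_ml_fit(rr, order = 0, window = 1e6, forgetting = 1)
  expect_equal(fit$theta0, 0.8, tolerance = 0.02)
  expect_equal(fit$shape, 50, tolerance = 0.15)
  # p = 2 with known AR coefficients: RMSE < 0.1 at n ~ 1000
  truth2 <- rr_ground_truth(0.4, c(0.3, 0.2), lambda = 200)
  rr2 <- simulate_rr_ig(1000 * 0.8, truth2, seed = 15)
  fit2 <- local_ml_fit(rr2, order = 2, window = 1e6, forgetting = 1)
  rmse <- sqrt(mean((fit2$ar_coeffs - c(0.3, 0.2))^2))
  expect_lt(rmse, 0.1)
  # constant intervals: mu = the constant, variance ~ 0
  rrc <- rr_series(seq(0, 80, by = 0.8))
  fitc <- local_ml_fit(rrc, order = 0, window = 1e6, forgetting = 1)
  expect_equal(fitc$theta0, 0.8, tolerance = 1e-9)
  expect_lt(fitc$theta0^3 / fitc$shape, 1e-10)
  # insufficient beats -> NULL with warning
  expect_warning(out <- local_ml_fit(rr_series(c(0, 0.8, 1.6)), order = 8),
                 "insufficient")
  expect_null(out)
})

test_that("fitted likelihood beats the generator's on nearly all synthetic fits", {
  wins <- 0L
  for (i in 1:20) {
    rr <- simulate_rr_ig(300 * 0.8, rr_ground_truth(0.8, lambda = 100),
                         seed = 100 + i)
    fit <- local_ml_fit(rr, order = 0, window = 1e6, forgetting = 1)
    des <- rr$intervals
    ll <- function(th0, lam) sum(log(ig_density(des, th0, lam)))
    if (ll(fit$theta0, fit$shape) >= ll(0.8, 100) - 1e-8) wins <- wins + 1L
  }
  expect_gte(wins, 19L)  # >= 95%
})

test_that("instantaneous_spectrum: flat closed form, resonance, normalization", {
  # no AR terms: flat spectrum, lfn = 0.11 / 0.46
  sp <- instantaneous_spectrum(ig_params(0.8, shape = 200), mu = 0.8)
  expect_equal(sp$lfn, (0.15 - 0.04) / (0.5 - 0.04), tolerance = 1e-6)
  expect_equal(sp$lfn + sp$hfn, 1)
  expect_true(all(c(sp$vlf, sp$lf, sp$hf, sp$tot) >= 0))
  expect_equal(sp$vlf + sp$lf + sp$hf, sp$tot, tolerance = 1e-9)
  # AR(2) resonant at 0.25 Hz (inside HF): hf > lf
  delta <- 0.8
  r <- 0.95; w <- 2 * pi * 0.25 * delta
  ar2 <- c(2 * r * cos(w), -r^2)
  sp2 <- instantaneous_spectrum(ig_params(0.8, ar2, shape = 200), mu = 0.8)
  expect_gt(sp2$hf, sp2$lf)
})

test_that("track recovers stationary and LF-modulated dynamics", {
  rr <- simulate_rr_ig(220, rr_ground_truth(0.8, lambda = 200), seed = 16)
  trk <- suppressWarnings(track(rr, grid_step = 0.5))
  expect_equal(mean(trk$mu_rr), 0.8, tolerance = 0.02)
  expect_true(all(abs(trk$lfn + trk$hfn - 1) < 1e-9))
  expect_true(all(trk$tot >= 0))
  # LF-modulated generator: mean LF/HF above 1
  rrm <- simulate_rr_ig(300, rr_ground_truth(0.8, lambda = 200,
          mean_modulation = list(c(0.1, 0.1))), seed = 17)
  trkm <- suppressWarnings(track(rrm, grid_step = 0.5))
  expect_gt(mean(trkm$lf_hf, na.rm = TRUE), 1)
  # empty series -> empty track
  expect_equal(nrow(track(rr_series(numeric(0)))), 0)
})

test_that("hrv_features averages the track over windows", {
  trk <- data.frame(t = c(1, 2, 3), mu_rr = c(0.8, 0.9, 1.0),
                    sigma2 = 1e-3, vlf = 1, lf = 2, hf = 1, tot = 4,
                    lf_hf = 2, lfn = 2 / 3, hfn = 1 / 3, converged = TRUE)
  one <- hrv_features(trk, c(1.5, 2.5))
  expect_equal(one$mu_rr, 0.9)
  expect_equal(one$lf, 2)
  out <- hrv_features(trk, c(10, 20))
  expect_true(all(is.na(out)))
})

test_that("time-rescaling yields uniform values on well-specified data", {
  rr <- simulate_rr_ig(500 * 0.8, rr_ground_truth(0.8, lambda = 100), seed = 18)
  fit <- local_ml_fit(rr, order = 0, window = 1e6, forgetting = 1)
  u <- time_rescale(rr, fit)
  ks <- suppressWarnings(ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("R-peak annotations round-trip through the delimited file", {
  rr <- rr_series(c(0.5, 1.3, 2.1, 2.9))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rpeaks(rr, path, rate = 250)
  rr2 <- read_rpeaks(path)
  expect_equal(rr2$r_times, rr$r_times)
})
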