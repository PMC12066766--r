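make_recording <- function(intensity_fun, n = 256L, fs = 10) {
  m <- default_montage()
  arr <- array(NA_real_, dim = c(20, 2, n),
               dimnames = list(m$channel, c("wl760", "wl850"), NULL))
  for (i in 1:20) for (w in 1:2) arr[i, w, ] <- intensity_fun(i, w, n)
  nirs_recording("px", fs, arr, m)
}

test_that("optical density matches the -ln(I/mean) definition", {
  set.seed(21)
  rec <- make_recording(function(i, w, n) exp(rnorm(n, 8, 0.05)))
  od <- intensity_to_od(rec)
  i_series <- rec$intensity[3, 2, ]
  expect_equal(od$od[3, 2, ], -log(i_series / mean(i_series)),
               tolerance = 1e-12)
  # constant intensity gives exactly zero OD
  rec_c <- make_recording(function(i, w, n) rep(5 + i, n))
  expect_true(all(intensity_to_od(rec_c)$od == 0))
})

test_that("the periodized DWT reconstructs exactly and preserves energy", {
  set.seed(22)
  for (n in c(96L, 200L, 1000L)) {
    x <- rnorm(n)
    w <- dwt(x, levels = 5)
    expect_equal(idwt(w), x, tolerance = 1e-10)
  }
  # orthonormality: coefficient energy of an exact-length series equals
  # signal energy (Parseval)
  x <- rnorm(256)
  w <- dwt(x, levels = 5)
  expect_equal(sum(unlist(w$details)^2) + sum(w$approx^2), sum(x^2),
               tolerance = 1e-10)
  expect_error(dwt(rnorm(16), levels = 5), "too short")
})

test_that("wavelet despiking is a near no-op below threshold and removes spikes", {
  set.seed(23)
  n <- 1000L
  noise <- rnorm(n, 0, 0.2)
  clean <- sin(2 * pi * 0.05 * (1:n) / 5) + noise
  # sub-threshold series passes through nearly unchanged
  d0 <- wavelet_despike(clean, threshold = 10, diagnostics = TRUE)
  expect_equal(d0$series, clean, tolerance = 1e-10)
  expect_equal(sum(d0$n_zeroed), 0L)
  # spikes raise detail kurtosis; correction brings every level back under
  x <- clean
  x[c(300, 500, 800)] <- x[c(300, 500, 800)] + c(8, -10, 12) * sd(clean)
  d <- wavelet_despike(x, threshold = 3.30, diagnostics = TRUE)
  expect_true(any(d$kurtosis_before > 3.30))
  expect_true(all(d$kurtosis_after[is.finite(d$kurtosis_after)] <= 3.30 + 1e-6))
  rmse_pre <- sqrt(mean((x - clean)^2))
  rmse_post <- sqrt(mean((d$series - clean)^2))
  expect_lt(rmse_post, rmse_pre)
})

test_that("motion detection flags steps but not clean or flat series", {
  set.seed(24)
  fs <- 10
  n <- 1500L
  expect_equal(nrow(detect_motion_segments(rep(1, n), fs)), 0L)
  slow <- sin(2 * pi * 0.02 * (1:n) / fs) + rnorm(n, 0, 0.05)
  step <- slow + 5 * sd(slow) * ((1:n) >= 800)
  seg <- detect_motion_segments(step, fs)
  expect_gte(nrow(seg), 1L)
  expect_true(any(seg[, "start"] <= 800 & seg[, "end"] >= 800))
})

test_that("spline-SG removes baseline shifts and passes clean signals through", {
  set.seed(25)
  fs <- 10; n <- 2000L
  cfg <- preprocess_config()
  clean_sig <- 0.3 * sin(2 * pi * 0.02 * (1:n) / fs) + rnorm(n, 0, 0.01)
  # clean low-frequency signal: correlation with input >= 0.99
  y_clean <- nirsgraph:::spline_sg_series(clean_sig, fs, cfg)
  expect_gte(cor(y_clean, clean_sig), 0.99)
  # step artifact: level gap across the step reduced by >= 80%
  slow <- 0.3 * sin(2 * pi * 0.02 * (1:n) / fs) + rnorm(n, 0, 0.05)
  x <- slow + 5 * sd(slow) * ((1:n) >= 1000)
  y <- nirsgraph:::spline_sg_series(x, fs, cfg)
  gap_in <- abs(mean(x[1:999]) - mean(x[1000:n]))
  gap_out <- abs(mean(y[1:999]) - mean(y[1000:n]))
  expect_lte(gap_out, 0.2 * gap_in)
})

test_that("a too-short Savitzky-Golay window is a config error", {
  rec <- make_recording(function(i, w, n) runif(n, 1, 2), n = 64L, fs = 10)
  od <- intensity_to_od(rec)
  cfg <- preprocess_config(sg_window_s = 0.2, sg_order = 3)
  expect_error(spline_sg_correct(od, cfg), "sg_order")
})

test_that("the band-pass is zero-phase with the specified pass/stop behavior", {
  fs <- 10; n <- 6000L
  t <- (0:(n - 1)) / fs
  cfg <- preprocess_config()
  # DC is removed entirely
  expect_lt(max(abs(nirsgraph:::bandpass_series(rep(3, n), fs, cfg))), 3e-3)
  # 0.1 Hz passes at unit gain
  pass <- nirsgraph:::bandpass_series(sin(2 * pi * 0.1 * t), fs, cfg)
  expect_gte(fft_amplitude(pass, 0.1, fs), 0.95)
  expect_lte(fft_amplitude(pass, 0.1, fs), 1.05)
  # 1.2 Hz (cardiac band) is attenuated below 10%
  stop_ <- nirsgraph:::bandpass_series(sin(2 * pi * 1.2 * t), fs, cfg)
  expect_lt(fft_amplitude(stop_, 1.2, fs), 0.1)
  # zero phase: cross-correlation peak of filtered vs clean tone at lag 0
  cc <- stats::ccf(pass, sin(2 * pi * 0.1 * t), lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # low-pass above Nyquist is rejected with the sampling rate in the message
  expect_error(
    nirsgraph:::bandpass_series(rnorm(100), 0.8, cfg),
    "Nyquist"
  )
})

test_that("MBLL inversion is exact against the forward model", {
  set.seed(26)
  cfg <- preprocess_config()
  E <- cfg$extinction
  m <- default_montage()
  d_cm <- m$distance_mm[1] / 10
  n <- 1000L
  hbo_true <- runif(n, -2, 2) # uM
  hbr_true <- runif(n, -2, 2)
  od_f <- (E %*% rbind(hbo_true, hbr_true) / 1000) * d_cm
  arr <- array(NA_real_, dim = c(20, 2, n),
               dimnames = list(m$channel, NULL, NULL))
  for (i in 1:20) for (w in 1:2) arr[i, w, ] <- od_f[w, ] * cfg$dpf[w]
  od_obj <- nirsgraph:::new_optical_density(
    arr, list(sampling_rate = 10, wavelengths = c(760, 850), montage = m,
              participant_id = "px"),
    reference_intensity = NULL, provenance = list()
  )
  hemo <- od_to_concentration(od_obj, cfg)
  expect_lt(max(abs(hemo$hbo[1, ] - hbo_true)) / max(abs(hbo_true)), 1e-9)
  expect_lt(max(abs(hemo$hbr[1, ] - hbr_true)) / max(abs(hbr_true)), 1e-9)
  # zero OD maps to zero concentrations
  arr0 <- arr; arr0[] <- 0
  od0 <- nirsgraph:::new_optical_density(
    arr0, list(sampling_rate = 10, wavelengths = c(760, 850), montage = m,
               participant_id = "px"),
    reference_intensity = NULL, provenance = list()
  )
  h0 <- od_to_concentration(od0, cfg)
  expect_true(all(h0$hbo == 0) && all(h0$hbr == 0))
  # swapping the wavelength rows consistently leaves the result unchanged
  cfg_sw <- preprocess_config(extinction = E[2:1, ], dpf = cfg$dpf[2:1])
  arr_sw <- arr[, 2:1, , drop = FALSE]
  od_sw <- nirsgraph:::new_optical_density(
    arr_sw, list(sampling_rate = 10, wavelengths = c(850, 760), montage = m,
                 participant_id = "px"),
    reference_intensity = NULL, provenance = list()
  )
  h_sw <- od_to_concentration(od_sw, cfg_sw)
  expect_equal(h_sw$hbo, hemo$hbo, tolerance = 1e-12)
})

test_that("a singular extinction matrix is rejected", {
  expect_error(
    preprocess_config(extinction = matrix(c(1, 2, 2, 4), 2, byrow = TRUE)),
    "singular"
  )
})

test_that("the full chain records provenance in pipeline order", {
  spec <- quiet_cohort_spec(n_participants = 4, profile = "reduced", seed = 5)
  p <- simulate_participants(spec)[1, ]
  log <- simulate_trial_log(spec, p)
  rec <- simulate_recording(spec, p, log)$recording
  hemo <- run_preprocessing(rec)
  expect_equal(
    vapply(hemo$provenance, function(s) s$step, character(1)),
    c("wavelet_motion_correct", "spline_sg_correct", "bandpass_filter",
      "beer_lambert")
  )
  # filtering after conversion yields the same signal (linear conversion)
  h_pre <- run_preprocessing(rec, inversion_config())
  h_post <- run_preprocessing(rec, inversion_config(filter_before_mbll = FALSE))
  expect_equal(h_pre$hbo, h_post$hbo, tolerance = 1e-8)
})

test_that("the deterministic chain inverts a noise-free recording", {
  spec <- quiet_cohort_spec(n_participants = 4, profile = "reduced", seed = 5)
  p <- simulate_participants(spec)[1, ]
  log <- simulate_trial_log(spec, p)
  sim <- simulate_recording(spec, p, log)
  # pure OD -> MBLL recovers the clean HbO up to a per-channel constant
  h0 <- run_preprocessing(sim$recording, inversion_config(apply_bandpass = FALSE))
  tr <- sim$truth$clean_hbo
  tr_c <- tr - rowMeans(tr)
  h0_c <- h0$hbo - rowMeans(h0$hbo)
  expect_lt(sqrt(mean((h0_c - tr_c)^2)) / sqrt(mean(tr_c^2)), 1e-9)
  # with the band-pass, the output matches the band-limited truth and
  # correlates strongly with it
  h1 <- run_preprocessing(sim$recording, inversion_config())
  truth_f <- t(apply(tr, 1, function(x)
    nirsgraph:::bandpass_series(x, spec$sampling_rate, preprocess_config())))
  expect_lt(sqrt(mean((h1$hbo - truth_f)^2)) / sqrt(mean(truth_f^2)), 0.05)
  expect_gte(cor(as.vector(h1$hbo), as.vector(truth_f)), 0.9)
})

test_that("correction steps are nearly idempotent on representative signals", {
  set.seed(27)
  fs <- 10; n <- 2000L
  cfg <- preprocess_config()
  x <- 0.5 * sin(2 * pi * 0.03 * (1:n) / fs) + rnorm(n, 0, 0.2)
  once <- wavelet_despike(x, cfg$kurtosis_threshold)
  twice <- wavelet_despike(once, cfg$kurtosis_threshold)
  expect_lt(sqrt(mean((twice - once)^2)), 0.01 * sqrt(mean(once^2)))
  y1 <- nirsgraph:::spline_sg_series(x, fs, cfg)
  y2 <- nirsgraph:::spline_sg_series(y1, fs, cfg)
  expect_lt(sqrt(mean((y2 - y1)^2)), 0.05 * sqrt(mean(y1^2)))
})
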