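make_hemo <- function(hbo, fs = 10) {
  m <- default_montage()
  if (is.null(dim(hbo))) {
    hbo <- matrix(rep(hbo, each = 20), nrow = 20,
                  dimnames = list(m$channel, NULL))
  }
  structure(
    list(hbo = hbo, hbr = -0.25 * hbo, sampling_rate = fs, montage = m,
         participant_id = "p1", provenance = list()),
    class = "hemo_series"
  )
}

test_that("baseline mean follows the closed form on ramps and constants", {
  fs <- 10
  hemo_c <- make_hemo(rep(2.5, 1800), fs)
  expect_equal(unname(baseline_mean(hemo_c)[1]), 2.5)
  # linear ramp 0 -> 1 over 180 s, window [60, 180): mean = 2/3
  ramp <- seq(0, 1, length.out = 1800)
  expect_equal(unname(baseline_mean(make_hemo(ramp, fs))[1]), 2 / 3,
               tolerance = 1e-3)
  expect_error(baseline_mean(make_hemo(ramp, fs), baseline_window(0, 181)),
               "outside")
})

test_that("trial segments are extracted half-open, disjoint, one per trial", {
  fs <- 10
  hemo <- make_hemo(matrix(seq_len(20 * 1200), nrow = 20,
                           dimnames = list(default_montage()$channel, NULL)),
                    fs)
  log <- trial_log(data.frame(
    participant_id = "p1", phase = "evaluation", interaction = "poking",
    trial = 1:3, t_start_s = c(10, 20, 30), t_end_s = c(20, 30, 38)
  ))
  segs <- extract_trial_segments(hemo, log, interaction = "poking")
  expect_length(segs, 3L)
  idx <- lapply(segs, function(sg) sg$hbo[1, ])
  # half-open convention: consecutive trials share no sample
  expect_length(intersect(idx[[1]], idx[[2]]), 0L)
  expect_equal(ncol(segs[[1]]$hbo), 100L)
  # trial outside the recording errors with the trial named
  bad <- trial_log(data.frame(
    participant_id = "p1", phase = "evaluation", interaction = "moving",
    trial = 1, t_start_s = 110, t_end_s = 130
  ))
  expect_error(extract_trial_segments(hemo, bad), "moving")
  # a trial shorter than one sample period has no samples
  tiny <- trial_log(data.frame(
    participant_id = "p1", phase = "evaluation", interaction = "poking",
    trial = 1, t_start_s = 10.01, t_end_s = 10.05
  ))
  expect_error(extract_trial_segments(hemo, tiny), "no samples")
})

test_that("mean trial activation subtracts the baseline exactly", {
  m <- default_montage()
  seg <- matrix(3, nrow = 20, ncol = 50, dimnames = list(m$channel, NULL))
  base <- setNames(rep(1, 20), m$channel)
  expect_equal(unname(mean_trial_activation(seg, base)), rep(2, 20))
  # segment equal to baseline level gives zero
  expect_equal(unname(mean_trial_activation(seg, setNames(rep(3, 20), m$channel))),
               rep(0, 20))
  # random segment matches the independent mean-then-subtract oracle
  set.seed(31)
  segr <- matrix(rnorm(20 * 50), nrow = 20, dimnames = list(m$channel, NULL))
  br <- setNames(rnorm(20), m$channel)
  expect_equal(mean_trial_activation(segr, br),
               apply(segr, 1, mean) - br, tolerance = 1e-12)
  expect_error(mean_trial_activation(segr[, 0], br), "empty")
})

test_that("ROI averaging is channels-within-trial first, then trials", {
  # two channels of one region with trial means 1 and 3 -> trial value 2;
  # three trials with values 1, 2, 3 -> interaction value 2
  m <- default_montage()
  ch <- roi_channels(m, "SMA")[1:2]
  trials <- tibble::tibble(
    participant_id = "p1", interaction = "poking",
    trial = rep(1:3, each = 2), channel = rep(ch, 3),
    mean_hbo_raw = 0,
    mean_hbo_corrected = c(1, 3, 0, 2, 2.5, 3.5)
  )
  tbl <- roi_activation_table(trials, m)
  expect_equal(tbl$mean_dHbO[tbl$roi == "SMA"], 2)
  # a missing channel drops out of the trial ROI mean
  trials$mean_hbo_corrected[2] <- NA
  tbl2 <- roi_activation_table(trials, m)
  expect_equal(tbl2$mean_dHbO[tbl2$roi == "SMA"], mean(c(1, 1, 3)))
  # a region with no valid channels is flagged missing, not zero
  trials$mean_hbo_corrected <- NA_real_
  tbl3 <- roi_activation_table(trials, m)
  expect_true(all(tbl3$missing))
})

test_that("the IQR filter matches hand-computed fences and is order-invariant", {
  vals <- c(1:9, 100)
  # type-7 quartiles by hand: Q1 at position 3.25 -> 3.25, Q3 at
  # position 7.75 -> 7.75, IQR = 4.5, fences [-3.5, 14.5] -> only 100 out
  res <- iqr_outlier_filter(vals)
  expect_equal(unname(res$fences), c(3.25 - 6.75, 7.75 + 6.75))
  expect_equal(res$removed, 100)
  expect_equal(res$kept, 1:9)
  # all-equal and symmetric inputs lose nothing
  expect_length(iqr_outlier_filter(rep(4, 10))$removed, 0L)
  expect_length(iqr_outlier_filter(c(-3, -1, 0, 1, 3))$removed, 0L)
  # permutation invariance of the kept/removed sets
  set.seed(32)
  x <- c(rnorm(20), 50, -40)
  perm <- sample(x)
  expect_setequal(iqr_outlier_filter(x)$removed,
                  iqr_outlier_filter(perm)$removed)
  expect_setequal(iqr_outlier_filter(x)$kept, iqr_outlier_filter(perm)$kept)
  expect_warning(iqr_outlier_filter(c(1, 2, 3)), "fewer than 4")
})

test_that("pipeline activation recovers the ground-truth trial means", {
  # noise-free long-trial cohort: the measured activation must match the
  # trial means of the generator's clean HbO (the measure-level truth)
  long_times <- default_completion_times()
  long_times$mean_s <- 90
  long_times$sd_s <- 9
  spec <- quiet_cohort_spec(n_participants = 4, profile = "reduced", seed = 6,
                            completion_time_params = long_times)
  p <- simulate_participants(spec)[2, ]
  log <- simulate_trial_log(spec, p)
  sim <- simulate_recording(spec, p, log)
  hemo <- run_preprocessing(sim$recording, inversion_config(apply_bandpass = FALSE))
  base <- baseline_mean(hemo, baseline_window(60, 180))
  act <- trial_activation(hemo, log, base)
  # oracle from the stored clean series
  fs <- spec$sampling_rate
  seg1 <- log[1, ]
  idx <- nirsgraph:::sample_range(seg1$t_start_s, seg1$t_end_s, fs,
                                  ncol(sim$truth$clean_hbo), "trial")
  truth_mean <- rowMeans(sim$truth$clean_hbo[, idx])
  got <- act[act$interaction == seg1$interaction & act$trial == seg1$trial, ]
  expect_equal(setNames(got$mean_hbo_corrected, got$channel),
               truth_mean, tolerance = 1e-6)
})

test_that("injected regional amplitudes are recovered across repetitions", {
  # moderate noise, long trials: relative amplitude error below 20%
  long_times <- default_completion_times()
  long_times$mean_s <- 120
  long_times$sd_s <- 6
  spec <- cohort_spec(
    n_participants = 4, profile = "reduced", seed = 8,
    completion_time_params = long_times,
    activation_effects = NULL, coupling_effects = NULL,
    noise = list(cardiac = c(1.1, 0.2), resp = c(0.25, 0.05),
                 mayer = c(0.1, 0.05), drift_um = 0.3, idio_um = 0.15,
                 latent_roi_um = 0.1, latent_global_um = 0.05,
                 latent_tau_s = 3),
    artifacts = list(spikes_per_min = 0.2, shifts_per_min = 0.1,
                     spike_amp_sd = c(5, 15), shift_amp_sd = c(3, 8),
                     spike_width_s = 0.2)
  )
  parts <- simulate_participants(spec)
  rel_err <- vapply(seq_len(nrow(parts)), function(i) {
    p <- parts[i, ]
    log <- simulate_trial_log(spec, p)
    sim <- simulate_recording(spec, p, log)
    hemo <- run_preprocessing(sim$recording, inversion_config(apply_bandpass = FALSE))
    base <- baseline_mean(hemo, baseline_window(60, 180))
    act <- trial_activation(hemo, log, base)
    tbl <- roi_activation_table(act, sim$recording$montage)
    got <- mean(tbl$mean_dHbO[tbl$roi == "SMA"])
    # oracle: trial means of the clean series, same averaging
    truth_tbl <- vapply(seq_len(nrow(log)), function(k) {
      idx <- nirsgraph:::sample_range(log$t_start_s[k], log$t_end_s[k],
                                      spec$sampling_rate,
                                      ncol(sim$truth$clean_hbo), "trial")
      mean(rowMeans(sim$truth$clean_hbo[roi_channels(sim$recording$montage,
                                                     "SMA"), idx, drop = FALSE]))
    }, numeric(1))
    abs(got - mean(truth_tbl)) / abs(mean(truth_tbl))
  }, numeric(1))
  expect_lt(stats::median(rel_err), 0.2)
})
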