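#' Evaluation completion-time parameters (seconds)
#'
#' Mean and SD of total evaluation completion time per interaction and
#' training group used as the generator defaults. The AR group is faster
#' and less variable than the video group on every interaction.
#'
#' @return tibble with `interaction`, `group`, `mean_s`, `sd_s`.
#' @export
default_completion_times <- function() {
  tibble::tribble(
    ~interaction, ~group, ~mean_s, ~sd_s,
    "poking",     "AR",    15.56,  3.56,
    "poking",     "video", 23.64,  7.09,
    "raycasting", "AR",    28.73, 10.18,
    "raycasting", "video", 78.78, 66.89,
    "scrolling",  "AR",    22.38, 11.59,
    "scrolling",  "video", 62.02, 32.13,
    "moving",     "AR",     9.84,  4.93,
    "moving",     "video", 16.33,  8.94
  )
}

#' Synthetic cohort specification
#'
#' All knobs of the synthetic study generator. The defaults describe the
#' reference cohort: 33 participants (17 male / 16 female) randomized to
#' AR (8m/8f) or video (9m/8f) training; an evaluation phase of four
#' selection interactions with three consecutive trials each and rest
#' periods in between, trial durations drawn from the per-group
#' completion-time parameters; 20-channel two-wavelength recordings over
#' six motor-related regions with HRF-convolved task activity,
#' cardiac/respiratory/Mayer-wave oscillations, slow drift, shared latent
#' signals that induce inter-channel coupling, and spike/shift motion
#' artifacts. Group and sex effects are *injected*: by default AR females
#' receive an SMA/LM1 activation boost and males a coupling (shared
#' latent) boost, mirroring the qualitative pattern the pipeline is meant
#' to recover; pass `NULL` to either to simulate a null cohort.
#'
#' Effect magnitudes in physical units are not identifiable from
#' published group statistics, so activation amplitudes are specified on
#' the generator's own uM scale relative to the 1 uM base response. The
#' default boost of 3 uM is deliberately large: trial-mean activation of
#' short trials captures only a fraction of the response amplitude, with
#' a participant-level spread driven by trial-duration variability, and
#' the boost is sized (by a design-stage power analysis, see the methods
#' vignette) so that one cohort of 33 detects the injected interaction
#' with probability above 99% on the referenced SMA contrast, keeping
#' repeated-cohort recovery rates stable.
#'
#' @param n_participants cohort size (default 33).
#' @param profile `"full"` (10 Hz, 120 s rests) or `"reduced"` (5 Hz,
#'   20 s rests) — the reduced profile keeps the same design and task
#'   durations but shortens the silent parts of the recording for fast
#'   repeated-cohort studies.
#' @param completion_time_params per interaction x group total-time mean
#'   and SD (s), see [default_completion_times()].
#' @param activation_effects tibble `roi`, `group`, `sex`, `amplitude`
#'   (uM) of injected activation boosts, or `NULL` for none.
#' @param coupling_effects tibble `sex` (or `group`), `boost` (uM added to
#'   the shared global latent loading), or `NULL` for none.
#' @param base_amplitude,amplitude_sd task response amplitude (uM): every
#'   region responds at `base_amplitude` plus a per-participant
#'   `N(0, amplitude_sd)` deviation.
#' @param channel_gain_jitter multiplicative per-channel gain spread
#'   (uniform in `1 +/- jitter`).
#' @param latency_jitter_s per-channel hemodynamic latency spread in
#'   seconds (uniform in `+/- latency_jitter_s`): regional vascular
#'   response delays differ, which decorrelates the task-evoked component
#'   across channels.
#' @param hbr_ratio HbR is `hbr_ratio * HbO` (typical inverse relation).
#' @param noise list of physiological noise settings: `cardiac`, `resp`,
#'   `mayer` as `c(freq_hz, amp_um)`; `drift_um` slow drift scale;
#'   `idio_um` in-band idiosyncratic noise SD; `latent_roi_um`,
#'   `latent_global_um` shared latent loadings; `latent_tau_s` latent
#'   autocorrelation time.
#' @param artifacts list: `spikes_per_min`, `shifts_per_min`,
#'   `spike_amp_sd` (range, x series SD), `shift_amp_sd` (range),
#'   `spike_width_s`.
#' @param sampling_rate Hz; `NULL` takes the profile default.
#' @param rest_between_s rest between interaction blocks (s); `NULL`
#'   takes the profile default.
#' @param baseline_s rest recording prepended as baseline (default 180).
#' @param n_eval_trials,n_training_trials trials per interaction.
#' @param include_training also schedule (and record) the training phase;
#'   default `FALSE` since the neural analysis uses the evaluation phase.
#' @param trial_min_s truncation floor for per-trial durations.
#' @param seed cohort seed; every participant derives a sub-seed from it,
#'   so any participant regenerates in isolation.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_participants = 33,
                        profile = c("full", "reduced"),
                        completion_time_params = default_completion_times(),
                        activation_effects = tibble(
                          roi = c("SMA", "LM1"), group = "AR",
                          sex = "female", amplitude = 3.0
                        ),
                        coupling_effects = tibble(sex = "male", boost = 0.45),
                        base_amplitude = 1.0,
                        amplitude_sd = 0.25,
                        channel_gain_jitter = 0.2,
                        latency_jitter_s = 1.5,
                        hbr_ratio = -0.25,
                        noise = list(
                          cardiac = c(1.1, 0.4), resp = c(0.25, 0.15),
                          mayer = c(0.1, 0.10), drift_um = 1.0,
                          idio_um = 0.35, latent_roi_um = 0.35,
                          latent_global_um = 0.15, latent_tau_s = 3
                        ),
                        artifacts = list(
                          spikes_per_min = 0.5, shifts_per_min = 0.2,
                          spike_amp_sd = c(5, 15), shift_amp_sd = c(3, 8),
                          spike_width_s = 0.2
                        ),
                        sampling_rate = NULL,
                        rest_between_s = NULL,
                        baseline_s = 180,
                        n_eval_trials = 3,
                        n_training_trials = 6,
                        include_training = FALSE,
                        trial_min_s = 1,
                        seed = 1L) {
  profile <- match.arg(profile)
  sampling_rate <- sampling_rate %||% switch(profile, full = 10, reduced = 5)
  rest_between_s <- rest_between_s %||% switch(profile, full = 120, reduced = 20)
  counts <- default_design_counts(n_participants)
  if (!is.null(coupling_effects)) {
    max_loading <- noise$latent_global_um + max(coupling_effects$boost)
    if (max_loading < 0) abort("coupling boost drives a negative latent loading")
  }
  structure(
    list(
      n_participants = n_participants, profile = profile,
      design_counts = counts,
      completion_time_params = completion_time_params,
      activation_effects = activation_effects,
      coupling_effects = coupling_effects,
      base_amplitude = base_amplitude, amplitude_sd = amplitude_sd,
      channel_gain_jitter = channel_gain_jitter,
      latency_jitter_s = latency_jitter_s, hbr_ratio = hbr_ratio,
      noise = noise, artifacts = artifacts,
      sampling_rate = sampling_rate, rest_between_s = rest_between_s,
      baseline_s = baseline_s,
      n_eval_trials = n_eval_trials, n_training_trials = n_training_trials,
      include_training = isTRUE(include_training),
      trial_min_s = trial_min_s, seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# The study's group x sex allocation, scaled proportionally when a smaller
# smoke cohort is requested. Reference design: AR 8m/8f, video 9m/8f.
default_design_counts <- function(n) {
  ref <- c(ar_m = 8, ar_f = 8, vid_m = 9, vid_f = 8)
  if (n == 33) return(ref)
  scaled <- pmax(1, round(ref * n / 33))
  while (sum(scaled) > n) scaled[which.max(scaled)] <- scaled[which.max(scaled)] - 1
  while (sum(scaled) < n) scaled[which.min(scaled)] <- scaled[which.min(scaled)] + 1
  scaled
}

participant_seed <- function(spec, index) {
  (as.numeric(spec$seed) * 48271 + index * 9973) %% 2147483647
}

#' Participant table of a synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @return tibble `participant_id`, `group`, `sex`, `index`.
#' @export
simulate_participants <- function(spec) {
  counts <- spec$design_counts
  tibble(
    participant_id = sprintf("P%02d", seq_len(spec$n_participants)),
    group = rep(c("AR", "AR", "video", "video"), counts),
    sex = rep(c("male", "female", "male", "female"), counts),
    index = seq_len(spec$n_participants)
  )
}

#' Canonical double-gamma hemodynamic response function
#'
#' Response peak near 6 s, undershoot near 16 s, normalized to unit peak;
#' `hrf(0) = 0` and the tail beyond 40 s is negligible.
#'
#' @param t time in seconds (>= 0).
#' @param peak_shape,under_shape,rate,under_ratio gamma-density shape
#'   parameters of the positive lobe and the undershoot.
#' @return response values, unit peak.
#' @export
hrf <- function(t, peak_shape = 7, under_shape = 16, rate = 1,
                under_ratio = 1 / 6) {
  if (any(t < 0)) abort("hrf is defined for t >= 0")
  h <- stats::dgamma(t, shape = peak_shape, rate = rate) -
    under_ratio * stats::dgamma(t, shape = under_shape, rate = rate)
  grid <- seq(0, 40, by = 0.01)
  peak <- max(stats::dgamma(grid, shape = peak_shape, rate = rate) -
                under_ratio * stats::dgamma(grid, shape = under_shape, rate = rate))
  h / peak
}

truncated_normal <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  bad <- x < lower
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- x < lower
  }
  x
}

interaction_order <- function(index) {
  first <- if (index %% 2L == 0L) c("poking", "raycasting") else c("raycasting", "poking")
  second <- if ((index %/% 2L) %% 2L == 0L) c("moving", "scrolling") else c("scrolling", "moving")
  c(first, second)
}

#' Simulate one participant's trial log
#'
#' Evaluation schedule: baseline rest, then the four interactions in
#' counterbalanced order (poking/raycasting always before
#' moving/scrolling), each a block of consecutive trials separated from
#' the next block by a rest period. Per-trial durations are
#' `Normal(mean/k, sd/k)` truncated above `trial_min_s`, where `k` is the
#' trial count and mean/sd are the per-group completion-time totals, so
#' interaction totals match the completion-time scale.
#'
#' @param spec a [cohort_spec()].
#' @param participant one row of [simulate_participants()].
#' @return a `trial_log`.
#' @export
simulate_trial_log <- function(spec, participant) {
  withr::with_seed(participant_seed(spec, participant$index) + 1, {
    rows <- list()
    t_cursor <- spec$baseline_s
    schedule <- list()
    if (spec$include_training && participant$group == "AR") {
      schedule <- c(schedule, list(list(phase = "training",
                                        k = spec$n_training_trials)))
    }
    schedule <- c(schedule, list(list(phase = "evaluation",
                                      k = spec$n_eval_trials)))
    for (ph in schedule) {
      for (int in interaction_order(participant$index)) {
        pars <- spec$completion_time_params
        pars <- pars[pars$interaction == int & pars$group == participant$group, ]
        k <- ph$k
        dur <- truncated_normal(k, pars$mean_s / spec$n_eval_trials,
                                pars$sd_s / spec$n_eval_trials,
                                spec$trial_min_s)
        for (j in seq_len(k)) {
          rows[[length(rows) + 1L]] <- tibble(
            participant_id = participant$participant_id, phase = ph$phase,
            interaction = int, trial = j,
            t_start_s = t_cursor, t_end_s = t_cursor + dur[j]
          )
          t_cursor <- t_cursor + dur[j]
        }
        t_cursor <- t_cursor + spec$rest_between_s
      }
    }
    trial_log(dplyr::bind_rows(rows))
  })
}

ar1_noise <- function(n, sd, fs, tau_s) {
  if (sd <= 0) return(numeric(n))
  phi <- exp(-1 / (fs * tau_s))
  innov_sd <- sd * sqrt(1 - phi^2)
  x <- numeric(n)
  e <- rnorm(n, 0, innov_sd)
  x[1L] <- rnorm(1, 0, sd)
  for (i in 2:n) x[i] <- phi * x[i - 1L] + e[i]
  x
}

sinusoid <- function(n, fs, freq, amp) {
  if (amp <= 0) return(numeric(n))
  amp * sin(2 * pi * freq * (seq_len(n) - 1) / fs + runif(1, 0, 2 * pi))
}

lookup_boost <- function(effects, participant, value_col) {
  if (is.null(effects) || !nrow(effects)) return(0)
  hit <- rep(TRUE, nrow(effects))
  for (col in intersect(c("group", "sex"), names(effects))) {
    hit <- hit & (is.na(effects[[col]]) | effects[[col]] == participant[[col]])
  }
  sum(effects[[value_col]][hit])
}

#' Simulate one participant's recording (with ground truth)
#'
#' Forward model: per channel, clean task HbO is the trial boxcar
#' convolved with the canonical HRF, scaled by the participant's regional
#' amplitude (base + subject deviation + any injected group/sex boost)
#' and a per-channel gain. Shared AR(1) latent signals (one global, one
#' per region) plus sinusoidal cardiac/respiratory/Mayer components,
#' slow drift, and idiosyncratic in-band noise are added; injected
#' coupling boosts raise the global latent loading of the matching
#' participants. HbR is a fixed negative ratio of HbO. Both chromophores
#' are pushed through the Beer-Lambert forward model to two-wavelength
#' optical density, spike and baseline-shift motion artifacts are added
#' in OD space, and intensities are exponentiated around per-channel
#' reference levels. The baseline rest occupies the first `baseline_s`
#' seconds.
#'
#' @param spec a [cohort_spec()].
#' @param participant one row of [simulate_participants()].
#' @param log the participant's [simulate_trial_log()] output.
#' @param cfg [preprocess_config()] supplying the extinction/DPF used by
#'   the forward model (defaults match the analysis defaults).
#' @return list with `recording` (an [nirs_recording()]) and `truth`
#'   (regional amplitudes, clean task HbO, latent loadings, artifact
#'   times).
#' @export
simulate_recording <- function(spec, participant, log,
                               cfg = preprocess_config()) {
  montage <- default_montage()
  fs <- spec$sampling_rate
  n <- as.integer(ceiling((max(log$t_end_s) + 5) * fs))
  n_ch <- nrow(montage)
  withr::with_seed(participant_seed(spec, participant$index) + 2, {
    # regional amplitudes: base + subject deviation + injected boosts
    rois <- default_rois()
    amp_roi <- setNames(
      spec$base_amplitude + rnorm(length(rois), 0, spec$amplitude_sd),
      rois
    )
    if (!is.null(spec$activation_effects)) {
      for (k in seq_len(nrow(spec$activation_effects))) {
        eff <- spec$activation_effects[k, ]
        if ((is.na(eff$group) || eff$group == participant$group) &&
            (is.na(eff$sex) || eff$sex == participant$sex)) {
          amp_roi[eff$roi] <- amp_roi[eff$roi] + eff$amplitude
        }
      }
    }
    # task regressor: evaluation (and any training) trials as a boxcar
    box <- numeric(n)
    for (i in seq_len(nrow(log))) {
      idx <- sample_range(log$t_start_s[i], log$t_end_s[i], fs, n, "trial")
      box[idx] <- 1
    }
    # kernel normalized to unit area so a sustained block plateaus at 1
    # and regional amplitudes stay on the uM scale
    kern <- hrf(seq(0, 40, by = 1 / fs))
    kern <- kern / sum(kern)
    task <- stats::convolve(box, rev(kern), type = "open")[seq_len(n)]
    lags <- as.integer(round(runif(n_ch, -spec$latency_jitter_s,
                                   spec$latency_jitter_s) * fs))
    shift_series <- function(x, lag) {
      if (lag == 0L) return(x)
      if (lag > 0L) c(rep(0, lag), x[seq_len(n - lag)])
      else c(x[(1L - lag):n], rep(0, -lag))
    }
    # latent structure
    nz <- spec$noise
    g_load <- nz$latent_global_um + lookup_boost(spec$coupling_effects,
                                                 participant, "boost")
    latent_global <- ar1_noise(n, 1, fs, nz$latent_tau_s)
    latent_roi <- lapply(rois, function(r) ar1_noise(n, 1, fs, nz$latent_tau_s))
    names(latent_roi) <- rois
    gains <- runif(n_ch, 1 - spec$channel_gain_jitter,
                   1 + spec$channel_gain_jitter)
    clean <- matrix(0, n_ch, n, dimnames = list(montage$channel, NULL))
    hbo <- matrix(0, n_ch, n, dimnames = list(montage$channel, NULL))
    for (i in seq_len(n_ch)) {
      roi <- montage$roi[i]
      clean[i, ] <- gains[i] * amp_roi[roi] * shift_series(task, lags[i])
      noise_i <- nz$latent_roi_um * latent_roi[[roi]] +
        g_load * latent_global +
        ar1_noise(n, nz$idio_um, fs, 1.5) +
        sinusoid(n, fs, nz$cardiac[1], nz$cardiac[2]) +
        sinusoid(n, fs, nz$resp[1], nz$resp[2]) +
        sinusoid(n, fs, nz$mayer[1], nz$mayer[2]) +
        (if (nz$drift_um > 0) nz$drift_um * cumsum(rnorm(n)) / sqrt(n) else 0)
      hbo[i, ] <- clean[i, ] + noise_i
    }
    hbr <- spec$hbr_ratio * hbo
    # forward Beer-Lambert to optical density, then intensities
    E <- cfg$extinction
    d_cm <- montage$distance_mm / 10
    intensity <- array(
      NA_real_, dim = c(n_ch, 2L, n),
      dimnames = list(montage$channel,
                      paste0("wl", c(760, 850)), NULL)
    )
    spikes <- list(); shifts <- list()
    art <- spec$artifacts
    minutes <- n / fs / 60
    n_spend <- stats::rpois(1, art$spikes_per_min * minutes)
    n_shift <- stats::rpois(1, art$shifts_per_min * minutes)
    spike_at <- sort(sample.int(n, min(n_spend, n)))
    shift_at <- sort(sample.int(n, min(n_shift, n)))
    spike_ch <- sample.int(n_ch, length(spike_at), replace = TRUE)
    shift_ch <- sample.int(n_ch, length(shift_at), replace = TRUE)
    tgrid <- seq_len(n)
    for (i in seq_len(n_ch)) {
      conc_mM <- rbind(hbo[i, ], hbr[i, ]) / 1000
      od <- (E %*% conc_mM) * d_cm[i] # rows: wavelengths; DPF applied below
      for (w in 1:2) {
        od_w <- od[w, ] * cfg$dpf[w]
        s_od <- max(sd(od_w), 1e-6)
        for (k in which(spike_ch == i)) {
          amp <- runif(1, art$spike_amp_sd[1], art$spike_amp_sd[2]) * s_od *
            sample(c(-1, 1), 1)
          width <- art$spike_width_s * fs
          od_w <- od_w + amp * exp(-0.5 * ((tgrid - spike_at[k]) / width)^2)
        }
        for (k in which(shift_ch == i)) {
          amp <- runif(1, art$shift_amp_sd[1], art$shift_amp_sd[2]) * s_od *
            sample(c(-1, 1), 1)
          od_w <- od_w + amp * (tgrid >= shift_at[k])
        }
        i0 <- 1e6 * runif(1, 0.5, 2)
        intensity[i, w, ] <- i0 * exp(-od_w)
      }
    }
    rec <- nirs_recording(
      participant_id = participant$participant_id,
      sampling_rate = fs, intensity = intensity, montage = montage
    )
    truth <- list(
      participant_id = participant$participant_id,
      amp_roi = amp_roi, gains = gains, clean_hbo = clean,
      global_loading = g_load,
      spike_samples = spike_at, shift_samples = shift_at,
      hbr_ratio = spec$hbr_ratio
    )
    list(recording = rec, truth = truth)
  })
}

#' Simulate a complete cohort
#'
#' Generates the participant table, per-participant trial logs,
#' recordings and ground truth, and the behavioral table of evaluation
#' completion times. Fully determined by `spec$seed`. When `dir` is
#' given, everything is also written to disk as plain text (recordings as
#' CSV/YAML pairs, logs as CSV, tables as TSV) together with a MANIFEST.
#'
#' @param spec a [cohort_spec()].
#' @param dir optional output directory.
#' @param cfg forward-model [preprocess_config()].
#' @return a `cohort` list: `spec`, `participants`, `logs`, `recordings`,
#'   `truths`, `behavior`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), dir = NULL,
                            cfg = preprocess_config()) {
  participants <- simulate_participants(spec)
  logs <- list(); recordings <- list(); truths <- list()
  for (i in seq_len(nrow(participants))) {
    p <- participants[i, ]
    log <- simulate_trial_log(spec, p)
    sim <- simulate_recording(spec, p, log, cfg)
    logs[[p$participant_id]] <- log
    recordings[[p$participant_id]] <- sim$recording
    truths[[p$participant_id]] <- sim$truth
  }
  behavior <- purrr::map_dfr(logs, function(lg) {
    lg |>
      dplyr::filter(.data$phase == "evaluation") |>
      dplyr::group_by(.data$participant_id, .data$interaction) |>
      dplyr::summarise(
        completion_time_s = sum(.data$t_end_s - .data$t_start_s),
        .groups = "drop"
      )
  }) |>
    dplyr::left_join(participants, by = "participant_id") |>
    dplyr::select("participant_id", "group", "sex", "interaction",
                  "completion_time_s")
  cohort <- structure(
    list(spec = spec, participants = participants, logs = logs,
         recordings = recordings, truths = truths, behavior = behavior),
    class = "cohort"
  )
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (pid in names(cohort$recordings)) {
    rec_path <- file.path(dir, paste0(pid, "_recording.csv"))
    write_recording(cohort$recordings[[pid]], rec_path)
    log_path <- file.path(dir, paste0(pid, "_trials.csv"))
    write_trial_log(cohort$logs[[pid]], log_path)
    files <- c(files, basename(rec_path),
               paste0(pid, "_recording_meta.yml"), basename(log_path))
  }
  utils::write.table(cohort$behavior, file.path(dir, "behavior.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  truth_tbl <- purrr::map_dfr(cohort$truths, function(tr) {
    tibble(participant_id = tr$participant_id, roi = names(tr$amp_roi),
           amplitude = unname(tr$amp_roi),
           global_loading = tr$global_loading)
  })
  utils::write.table(truth_tbl, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  files <- c(files, "behavior.tsv", "ground_truth.tsv")
  manifest <- tibble(file = files, seed = cohort$spec$seed)
  utils::write.table(manifest, file.path(dir, "MANIFEST.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Measure-level activation simulator for statistical calibration
#'
#' Draws one activation value per participant directly at the measure
#' level (unit within-cell SD), bypassing the recording pipeline; used to
#' calibrate type-I error and power of the factorial branch at the
#' study's 8/8/9/8 design. Effect sizes are in within-cell SD units;
#' `interaction_effect` displaces each cell by that amount in the crossed
#' `+a/-a/-a/+a` pattern.
#'
#' @param spec a [cohort_spec()] (supplies the design counts).
#' @param group_effect,sex_effect,interaction_effect effect sizes (SD
#'   units).
#' @param seed RNG seed.
#' @return tibble `participant_id`, `group`, `sex`, `y`.
#' @export
simulate_activation_table <- function(spec = cohort_spec(),
                                      group_effect = 0, sex_effect = 0,
                                      interaction_effect = 0, seed = 1L) {
  participants <- simulate_participants(spec)
  withr::with_seed(seed, {
    sg <- ifelse(participants$group == "AR", 1, -1)
    ss <- ifelse(participants$sex == "male", 1, -1)
    participants$y <- group_effect * sg / 2 + sex_effect * ss / 2 +
      interaction_effect * sg * ss + rnorm(nrow(participants))
  })
  participants[, c("participant_id", "group", "sex", "y")]
}
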