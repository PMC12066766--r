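#' Splice evaluation task segments into one continuous series
#'
#' Concatenates the samples of all evaluation trials of the four
#' interactions, in task order (rest periods removed), per channel.
#' Connectivity is computed on this pooled series because single
#' interactions are too short for stable correlation estimates.
#'
#' @param hemo a task `hemo_series`.
#' @param log a `trial_log` covering all four interactions for this
#'   participant.
#' @param phase phase to splice (default `"evaluation"`).
#' @param demean_segments demean each trial segment before concatenation
#'   (default `FALSE`; kept available for sensitivity analysis).
#' @return a `hemo_series` whose length is the sum of the segment lengths.
#' @export
splice_task_segments <- function(hemo, log, phase = "evaluation",
                                 demean_segments = FALSE) {
  rows <- log[log$phase == phase, ]
  if (!is.null(hemo$participant_id) &&
      hemo$participant_id %in% rows$participant_id) {
    rows <- rows[rows$participant_id == hemo$participant_id, ]
  }
  missing_int <- setdiff(interactions(), unique(rows$interaction))
  if (length(missing_int)) {
    abort(paste0("log is missing evaluation trials for: ",
                 paste(missing_int, collapse = ", ")))
  }
  rows <- rows[order(rows$t_start_s), ]
  # keep task (time) order: pass the sorted rows directly, a trial_log
  # constructor would re-sort them by interaction
  segs <- extract_trial_segments(hemo, rows, phase = phase)
  pieces_hbo <- purrr::map(segs, function(sg) {
    m <- sg$hbo
    if (demean_segments) m <- m - rowMeans(m)
    m
  })
  fs <- hemo$sampling_rate
  idx_all <- unlist(purrr::map(segs, function(sg) {
    sample_range(sg$trial$t_start_s, sg$trial$t_end_s, fs, ncol(hemo$hbo),
                 "trial")
  }))
  out <- hemo
  out$hbo <- do.call(cbind, pieces_hbo)
  out$hbr <- hemo$hbr[, idx_all, drop = FALSE]
  if (demean_segments) {
    out$hbr <- NULL # segment demeaning tracked only for the analysis signal
  }
  out$provenance <- c(hemo$provenance, list(list(
    step = "splice_task_segments", phase = phase,
    n_trials = nrow(rows), demean_segments = demean_segments
  )))
  out
}

#' Channel-pair Pearson correlation matrix
#'
#' Standard Pearson correlation between every pair of channel HbO series:
#' symmetric, unit diagonal. A zero-variance channel gets `NA` entries
#' (flagged missing, never coerced to 0).
#'
#' @param hemo a `hemo_series` (typically spliced evaluation data).
#' @param threshold spuriousness threshold `|r*|` carried with the result
#'   (default 0.291, the Monte Carlo calibrated 99th-percentile null value;
#'   see [calibrate_threshold()]).
#' @return an `fc_result` with elements `r`, `threshold`, `montage`,
#'   `participant_id`.
#' @export
correlation_matrix <- function(hemo, threshold = 0.291) {
  x <- t(hemo$hbo)
  if (nrow(x) < 3L) abort("need at least 3 samples for a correlation matrix")
  sds <- apply(x, 2L, sd)
  r <- suppressWarnings(cor(x))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r)[sds > 0] <- 1
  structure(
    list(r = r, threshold = threshold, montage = hemo$montage,
         participant_id = hemo$participant_id),
    class = "fc_result"
  )
}

#' Monte Carlo calibration of the spuriousness threshold
#'
#' Simulates pairs of independent null series, computes their Pearson
#' correlation, and returns the empirical `1 - alpha` quantile of `|r|`:
#' correlations below this magnitude are indistinguishable from noise at
#' level `alpha`. The `"iid-gaussian"` null reproduces the analytic
#' t-distribution critical value; the `"filtered-gaussian"` null passes the
#' same white noise through the preprocessing band-pass, whose
#' autocorrelation inflates the null and therefore the threshold — the
#' reason calibrated fNIRS thresholds (such as the 0.291 default) exceed
#' the white-noise value.
#'
#' @param n_samples series length.
#' @param alpha two-sided false-positive rate (default 0.01).
#' @param n_sims number of simulated pairs (>= 1000).
#' @param seed RNG seed (calibration is seed-reproducible).
#' @param noise_model `"iid-gaussian"` or `"filtered-gaussian"`.
#' @param cfg [preprocess_config()] supplying the band-pass for the
#'   filtered null.
#' @param sampling_rate sampling rate assumed for the filtered null (Hz).
#' @return the threshold `|r*|` (single number).
#' @export
calibrate_threshold <- function(n_samples, alpha = 0.01, n_sims = 10000,
                                seed = 1L,
                                noise_model = c("iid-gaussian",
                                                "filtered-gaussian"),
                                cfg = preprocess_config(),
                                sampling_rate = 10) {
  noise_model <- match.arg(noise_model)
  if (n_samples < 4L) abort("n_samples must be at least 4")
  if (n_sims < 1000L) abort("n_sims must be at least 1000")
  rvals <- withr::with_seed(seed, {
    vapply(seq_len(n_sims), function(i) {
      a <- rnorm(n_samples)
      b <- rnorm(n_samples)
      if (noise_model == "filtered-gaussian") {
        a <- bandpass_series(a, sampling_rate, cfg)
        b <- bandpass_series(b, sampling_rate, cfg)
      }
      cor(a, b)
    }, numeric(1))
  })
  unname(quantile(abs(rvals), 1 - alpha, type = 7))
}

#' Analytic white-noise critical correlation
#'
#' Two-sided critical Pearson r at level `alpha` for independent Gaussian
#' series of length `n`, from the exact t relation
#' `r* = t / sqrt(n - 2 + t^2)` with `t = qt(1 - alpha/2, n - 2)`. Used as
#' the closed-form cross-check of the Monte Carlo calibration.
#'
#' @param n series length.
#' @param alpha two-sided level.
#' @export
critical_r <- function(n, alpha = 0.01) {
  tcrit <- qt(1 - alpha / 2, df = n - 2)
  tcrit / sqrt(n - 2 + tcrit^2)
}

#' Count non-spurious connections within and between region blocks
#'
#' A channel pair is retained iff `|r| > threshold` (strictly greater: the
#' closed interval `[-r*, r*]` is the spurious band). Each unordered pair
#' is counted once, into `within_motor` (both channels in a motor region),
#' `within_frontal` (both in a frontal region), or `between` (one of
#' each). Pairs with missing correlations are excluded and reported.
#'
#' @param conn an `fc_result`.
#' @param montage montage override (defaults to the one in `conn`).
#' @param motor_rois,frontal_rois region labels defining the two blocks.
#' @return tibble with one row: the three counts, `n_missing_pairs`, and
#'   the threshold.
#' @export
count_connections <- function(conn, montage = conn$montage,
                              motor_rois = c("LM1", "RM1"),
                              frontal_rois = c("FEF/CG", "SMA", "RPMC",
                                               "LPMC")) {
  r <- conn$r
  ch <- rownames(r) %||% montage$channel
  roi <- setNames(montage$roi, montage$channel)[ch]
  is_motor <- roi %in% motor_rois
  is_frontal <- roi %in% frontal_rois
  n <- nrow(r)
  within_motor <- 0L; within_frontal <- 0L; between <- 0L
  n_missing <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      rij <- r[i, j]
      if (is.na(rij)) { n_missing <- n_missing + 1L; next }
      if (abs(rij) > conn$threshold) {
        if (is_motor[i] && is_motor[j]) within_motor <- within_motor + 1L
        else if (is_frontal[i] && is_frontal[j]) within_frontal <- within_frontal + 1L
        else if ((is_motor[i] && is_frontal[j]) ||
                 (is_frontal[i] && is_motor[j])) between <- between + 1L
      }
    }
  }
  tibble(
    participant_id = conn$participant_id %||% NA_character_,
    within_motor = within_motor, within_frontal = within_frontal,
    between = between, n_missing_pairs = n_missing,
    threshold = conn$threshold
  )
}
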