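#' Baseline window within a rest recording
#'
#' Default is the second two minutes (`[60, 180)` s) of the three-minute
#' rest: the first minute is discarded to let the signal settle.
#'
#' @param t_start,t_end window bounds in seconds (half-open interval).
#' @return a `baseline_window` list.
#' @export
baseline_window <- function(t_start = 60, t_end = 180) {
  if (!(t_end > t_start)) abort("baseline window must have positive duration")
  structure(list(t_start = t_start, t_end = t_end), class = "baseline_window")
}

sample_range <- function(t_start, t_end, fs, n, what) {
  # sample i has time (i - 1) / fs; keep samples in [t_start, t_end)
  i0 <- as.integer(ceiling(t_start * fs - 1e-9)) + 1L
  i1 <- as.integer(ceiling(t_end * fs - 1e-9))
  if (i0 < 1L || i1 > n) {
    abort(sprintf(
      "%s [%g, %g) s lies outside the recording (0 to %g s)",
      what, t_start, t_end, n / fs
    ))
  }
  if (i1 < i0) {
    abort(sprintf("%s [%g, %g) s contains no samples at %g Hz",
                  what, t_start, t_end, fs))
  }
  i0:i1
}

#' Per-channel baseline HbO mean
#'
#' Averages each channel's HbO over the baseline window of a rest
#' recording; this global baseline is later subtracted from every trial
#' mean.
#'
#' @param hemo a `hemo_series` from the rest recording.
#' @param window a [baseline_window()]; default `[60, 180)` s.
#' @return named numeric vector, one mean per channel (uM).
#' @export
baseline_mean <- function(hemo, window = baseline_window()) {
  idx <- sample_range(window$t_start, window$t_end, hemo$sampling_rate,
                      ncol(hemo$hbo), "baseline window")
  rowMeans(hemo$hbo[, idx, drop = FALSE])
}

#' Extract per-trial HbO segments
#'
#' One segment per matching trial-log row, holding the samples whose times
#' fall in the half-open interval `[t_start, t_end)`. Segments of an
#' overlap-free log are therefore pairwise disjoint in sample indices.
#'
#' @param hemo a `hemo_series` (task recording, clock origin 0).
#' @param log a `trial_log`; only rows matching the hemo participant are
#'   used when participant ids are present in both.
#' @param phase phase to extract (default `"evaluation"`).
#' @param interaction optional single interaction to restrict to.
#' @return list of segments; each has `trial` (the log row) and `hbo`
#'   (channels x samples matrix).
#' @export
extract_trial_segments <- function(hemo, log, phase = "evaluation",
                                   interaction = NULL) {
  rows <- log[log$phase == phase, ]
  if (!is.null(hemo$participant_id) &&
      hemo$participant_id %in% rows$participant_id) {
    rows <- rows[rows$participant_id == hemo$participant_id, ]
  }
  if (!is.null(interaction)) rows <- rows[rows$interaction == interaction, ]
  fs <- hemo$sampling_rate
  n <- ncol(hemo$hbo)
  purrr::map(seq_len(nrow(rows)), function(i) {
    tr <- rows[i, ]
    idx <- sample_range(
      tr$t_start_s, tr$t_end_s, fs, n,
      sprintf("trial %s/%s/%d", tr$participant_id, tr$interaction, tr$trial)
    )
    list(trial = tr, hbo = hemo$hbo[, idx, drop = FALSE])
  })
}

#' Baseline-corrected mean activation of one trial
#'
#' Per channel: mean HbO over the trial samples minus the participant's
#' global baseline mean.
#'
#' @param segment a segment from [extract_trial_segments()] or a channels x
#'   samples matrix.
#' @param baseline named per-channel baseline vector from
#'   [baseline_mean()].
#' @return named numeric vector of corrected means (uM).
#' @export
mean_trial_activation <- function(segment, baseline) {
  hbo <- if (is.list(segment) && !is.null(segment$hbo)) segment$hbo else segment
  if (!is.matrix(hbo) || ncol(hbo) == 0L) abort("empty trial segment")
  m <- rowMeans(hbo)
  if (!is.null(names(baseline))) baseline <- baseline[names(m)]
  m - baseline
}

#' Trial-level activation table
#'
#' Runs segment extraction and baseline correction for every trial of a
#' phase, returning one row per (trial, channel).
#'
#' @param hemo task `hemo_series`.
#' @param log `trial_log`.
#' @param baseline per-channel baseline vector.
#' @param phase phase to analyse (default `"evaluation"`).
#' @return tibble with columns `participant_id`, `interaction`, `trial`,
#'   `channel`, `mean_hbo_raw`, `mean_hbo_corrected`.
#' @export
trial_activation <- function(hemo, log, baseline, phase = "evaluation") {
  segs <- extract_trial_segments(hemo, log, phase = phase)
  purrr::map_dfr(segs, function(sg) {
    raw <- rowMeans(sg$hbo)
    corr <- mean_trial_activation(sg, baseline)
    tibble(
      participant_id = sg$trial$participant_id,
      interaction = sg$trial$interaction,
      trial = sg$trial$trial,
      channel = names(raw) %||% rownames(sg$hbo),
      mean_hbo_raw = unname(raw),
      mean_hbo_corrected = unname(corr)
    )
  })
}

#' Region-of-interest activation table
#'
#' Averaging order is channels-within-trial first, then trials: each
#' trial's ROI value is the mean of that region's channel activations
#' (missing channels are dropped; a region with no valid channel is flagged
#' missing, not zero), and the per-interaction value is the mean over the
#' interaction's trials.
#'
#' @param trials tibble from [trial_activation()] (any number of
#'   participants).
#' @param montage montage tibble providing the channel-to-region map.
#' @param participants optional tibble `participant_id`, `group`, `sex` to
#'   annotate rows with the factorial design.
#' @return tibble with one row per (participant, interaction, roi):
#'   `mean_dHbO` plus `n_trials` and `missing` flags.
#' @export
roi_activation_table <- function(trials, montage, participants = NULL) {
  roi_map <- setNames(montage$roi, montage$channel)
  unmapped <- setdiff(unique(trials$channel), names(roi_map))
  if (length(unmapped)) {
    abort(paste0("channels without a region: ", paste(unmapped, collapse = ", ")))
  }
  per_trial <- trials |>
    dplyr::mutate(roi = unname(roi_map[.data$channel])) |>
    dplyr::group_by(.data$participant_id, .data$interaction, .data$trial,
                    .data$roi) |>
    dplyr::summarise(
      roi_mean = if (all(is.na(.data$mean_hbo_corrected))) NA_real_ else
        mean(.data$mean_hbo_corrected, na.rm = TRUE),
      .groups = "drop"
    )
  out <- per_trial |>
    dplyr::group_by(.data$participant_id, .data$interaction, .data$roi) |>
    dplyr::summarise(
      mean_dHbO = if (all(is.na(.data$roi_mean))) NA_real_ else
        mean(.data$roi_mean, na.rm = TRUE),
      n_trials = sum(!is.na(.data$roi_mean)),
      .groups = "drop"
    ) |>
    dplyr::mutate(missing = is.na(.data$mean_dHbO))
  if (!is.null(participants)) {
    out <- dplyr::left_join(out, participants, by = "participant_id") |>
      dplyr::select("participant_id", "group", "sex", "interaction", "roi",
                    "mean_dHbO", "n_trials", "missing")
  }
  out
}

#' 1.5 x IQR outlier filter
#'
#' Removes values below `Q1 - 1.5 IQR` or above `Q3 + 1.5 IQR`, quartiles
#' by linear interpolation (`stats::quantile` type 7). With fewer than 4
#' values the filter refuses and keeps everything (with a warning), since
#' quartiles are not meaningful.
#'
#' @param values numeric vector (NAs are passed through as kept).
#' @return list with `kept`, `removed`, `keep` (logical mask aligned to the
#'   input) and the `fences`.
#' @export
iqr_outlier_filter <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 4L) {
    warn("fewer than 4 values: outlier filter refuses, keeping all")
    return(list(kept = values, removed = values[0],
                keep = rep(TRUE, length(values)),
                fences = c(lower = -Inf, upper = Inf)))
  }
  q <- quantile(values[ok], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2L] - q[1L]
  fences <- c(lower = q[1L] - 1.5 * iqr, upper = q[2L] + 1.5 * iqr)
  keep <- is.na(values) | (values >= fences[1L] & values <= fences[2L])
  list(kept = values[keep], removed = values[!keep], keep = keep,
       fences = fences)
}

#' Apply the outlier filter per measurement family
#'
#' Physiological measures are filtered across participants within each
#' family (by default each interaction x region cell) before group
#' statistics; removed rows are flagged, not dropped, so downstream code
#' decides.
#'
#' @param tbl a tibble (e.g. from [roi_activation_table()]).
#' @param value value column to filter (tidy-eval).
#' @param family character vector of grouping columns defining the family.
#' @return `tbl` with a logical `outlier` column.
#' @export
filter_outliers <- function(tbl, value, family = c("interaction", "roi")) {
  value <- rlang::enquo(value)
  tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(family))) |>
    dplyr::mutate(outlier = {
      v <- rlang::eval_tidy(value, data = dplyr::pick(dplyr::everything()))
      !iqr_outlier_filter(v)$keep
    }) |>
    dplyr::ungroup()
}
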