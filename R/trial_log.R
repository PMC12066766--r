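#' Recognized experiment phases and interaction types
#' @export
phases <- function() c("training", "evaluation")

#' @rdname phases
#' @export
interactions <- function() c("poking", "raycasting", "scrolling", "moving")

#' Construct and validate a trial log
#'
#' A trial log is a tibble of per-trial records: participant, phase
#' (training or evaluation), interaction, 1-based trial index, and start/end
#' times in seconds on the recording clock. Intervals are half-open
#' `[t_start, t_end)`: the sample at `t_end` belongs to the next event. A
#' participant's trials must not overlap.
#'
#' @param df data frame with columns `participant_id`, `phase`,
#'   `interaction`, `trial`, `t_start_s`, `t_end_s`.
#' @return a validated `trial_log` tibble sorted by participant, phase,
#'   interaction, trial.
#' @export
trial_log <- function(df) {
  required <- c("participant_id", "phase", "interaction", "trial",
                "t_start_s", "t_end_s")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort(paste0("trial log is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- as_tibble(df)[required]
  if (nrow(out)) {
    bad_phase <- setdiff(unique(out$phase), phases())
    if (length(bad_phase)) {
      abort(paste0("unknown phase: ", paste(bad_phase, collapse = ", ")))
    }
    bad_int <- setdiff(unique(out$interaction), interactions())
    if (length(bad_int)) {
      abort(paste0("unknown interaction: ", paste(bad_int, collapse = ", ")))
    }
    nonpos <- which(out$t_end_s <= out$t_start_s)
    if (length(nonpos)) {
      abort(sprintf("t_end_s <= t_start_s at row %d (and %d more)",
                    nonpos[1L], length(nonpos) - 1L))
    }
    for (pid in unique(out$participant_id)) {
      rows <- out[out$participant_id == pid, ]
      o <- order(rows$t_start_s)
      starts <- rows$t_start_s[o]
      ends <- rows$t_end_s[o]
      if (any(starts[-1L] < ends[-length(ends)])) {
        i <- which(starts[-1L] < ends[-length(ends)])[1L]
        abort(sprintf(
          "overlapping trials for participant %s near t = %g s", pid, starts[i + 1L]
        ))
      }
    }
  }
  out <- dplyr::arrange(out, .data$participant_id, .data$phase,
                        .data$interaction, .data$trial)
  class(out) <- c("trial_log", class(tibble()))
  out
}

#' Read a trial log CSV
#'
#' Columns: `participant_id, phase, interaction, trial, t_start_s, t_end_s`.
#' An empty file (header only, or zero bytes) yields an empty log. Rows with
#' `t_end_s <= t_start_s` or overlapping trials raise a validation error
#' naming the first offending row.
#'
#' @param path CSV path.
#' @return a `trial_log` tibble.
#' @export
read_trial_log <- function(path) {
  if (!file.exists(path)) abort(paste0("trial log not found: ", path))
  if (file.size(path) == 0L) {
    return(trial_log(tibble(
      participant_id = character(), phase = character(),
      interaction = character(), trial = integer(),
      t_start_s = numeric(), t_end_s = numeric()
    )))
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  trial_log(df)
}

#' @rdname read_trial_log
#' @param log a `trial_log`.
#' @export
write_trial_log <- function(log, path) {
  write.csv(as.data.frame(log), path, row.names = FALSE)
  invisible(path)
}
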