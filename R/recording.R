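#' Construct a raw two-wavelength fNIRS recording
#'
#' The container for a continuous-wave recording: strictly positive detector
#' intensities for every channel at two nominal wavelengths, plus the probe
#' montage and sampling metadata. Times are seconds on the recording clock
#' with origin `t0`; all event intervals downstream are half-open
#' `[t_start, t_end)`.
#'
#' @param participant_id opaque participant identifier.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param intensity numeric array `channels x wavelengths x samples` of raw
#'   detector units (strictly positive). The first array dimension must be
#'   named with channel ids matching `montage$channel`.
#' @param montage a montage tibble (see [default_montage()]).
#' @param wavelengths two nominal wavelengths in nm (default 760, 850).
#' @param t0 recording clock origin in seconds (default 0).
#' @return an object of class `nirs_recording`.
#' @export
nirs_recording <- function(participant_id, sampling_rate, intensity, montage,
                           wavelengths = c(760, 850), t0 = 0) {
  rec <- structure(
    list(
      participant_id = as.character(participant_id),
      sampling_rate = as.numeric(sampling_rate),
      wavelengths = as.numeric(wavelengths),
      intensity = intensity,
      montage = montage,
      t0 = as.numeric(t0)
    ),
    class = "nirs_recording"
  )
  validate_recording(rec)
}

#' Validate a raw recording
#'
#' Checks the invariants every downstream stage relies on: positive sampling
#' rate, exactly two wavelengths present for every channel, identical sample
#' counts across channels, strictly positive intensities, and a channel set
#' identical to the montage (in montage order).
#'
#' @param rec an `nirs_recording`.
#' @return `rec`, invisibly reordered to montage channel order.
#' @export
validate_recording <- function(rec) {
  if (!is.numeric(rec$sampling_rate) || length(rec$sampling_rate) != 1L ||
      !is.finite(rec$sampling_rate) || rec$sampling_rate <= 0) {
    abort("sampling_rate must be a single positive number (Hz)")
  }
  if (length(rec$wavelengths) != 2L || anyDuplicated(rec$wavelengths)) {
    abort("exactly two distinct nominal wavelengths are required")
  }
  dm <- dim(rec$intensity)
  if (is.null(dm) || length(dm) != 3L) {
    abort("intensity must be a channels x wavelengths x samples array")
  }
  if (dm[2L] != 2L) {
    abort(sprintf(
      "both wavelengths must be present for every channel (got %d wavelength series)",
      dm[2L]
    ))
  }
  rec$montage <- validate_montage(rec$montage, strict = FALSE)
  ch <- dimnames(rec$intensity)[[1L]]
  if (is.null(ch)) abort("intensity must carry channel names on dim 1")
  if (!setequal(ch, rec$montage$channel)) {
    abort(paste0(
      "intensity channels and montage channels differ: intensity-only {",
      paste(setdiff(ch, rec$montage$channel), collapse = ", "),
      "}, montage-only {",
      paste(setdiff(rec$montage$channel, ch), collapse = ", "), "}"
    ))
  }
  rec$intensity <- rec$intensity[rec$montage$channel, , , drop = FALSE]
  bad <- which(!is.finite(rec$intensity) | rec$intensity <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    b <- bad[1L, ]
    abort(sprintf(
      "non-positive or non-finite intensity at channel %s, wavelength %g nm, sample %d (%d offending values)",
      rec$montage$channel[b[1L]], rec$wavelengths[b[2L]], b[3L], nrow(bad)
    ))
  }
  rec
}

#' @export
print.nirs_recording <- function(x, ...) {
  dm <- dim(x$intensity)
  cat(sprintf(
    "<nirs_recording> participant %s: %d channels x %d wavelengths (%s nm) x %d samples @ %g Hz (%.1f s)\n",
    x$participant_id, dm[1], dm[2], paste(x$wavelengths, collapse = "/"),
    dm[3], x$sampling_rate, dm[3] / x$sampling_rate
  ))
  cat(sprintf("  regions: %s\n",
              paste(sort(unique(x$montage$roi)), collapse = ", ")))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec an `nirs_recording`.
#' @export
n_samples <- function(rec) dim(rec$intensity)[3L]

recording_paths <- function(path) {
  stem <- sub("\\.csv$", "", path)
  list(csv = paste0(stem, ".csv"), meta = paste0(stem, "_meta.yml"))
}

#' Write a recording to the package's plain-text container
#'
#' The on-disk format is a pair of files: `<stem>.csv`, a wide CSV with one
#' row per sample and one column per channel-wavelength series (named
#' `S..D.._<wavelength>`), and `<stem>_meta.yml`, a YAML sidecar holding
#' participant id, sampling rate, wavelengths, clock origin, and the montage
#' (channels, distances, region map). The pair round-trips through
#' [read_recording()] up to floating-point representation.
#'
#' @param rec an `nirs_recording`.
#' @param path output path; the `.csv` extension is optional.
#' @return the CSV path, invisibly.
#' @export
write_recording <- function(rec, path) {
  rec <- validate_recording(rec)
  p <- recording_paths(path)
  dm <- dim(rec$intensity)
  cols <- lapply(seq_len(dm[1L]), function(i) {
    lapply(seq_len(2L), function(w) rec$intensity[i, w, ])
  })
  mat <- do.call(cbind, lapply(unlist(cols, recursive = FALSE), unlist))
  colnames(mat) <- as.vector(t(outer(
    rec$montage$channel, rec$wavelengths,
    function(ch, wl) sprintf("%s_%g", ch, wl)
  )))
  write.csv(as.data.frame(mat), p$csv, row.names = FALSE)
  meta <- list(
    format = "nirsgraph-recording-v1",
    participant_id = rec$participant_id,
    sampling_rate = rec$sampling_rate,
    wavelengths = rec$wavelengths,
    t0 = rec$t0,
    montage = lapply(seq_len(nrow(rec$montage)), function(i) {
      as.list(rec$montage[i, c("channel", "source", "detector",
                               "distance_mm", "roi")])
    })
  )
  yaml::write_yaml(meta, p$meta)
  invisible(p$csv)
}

#' Read a recording from the plain-text container
#'
#' Reads the CSV + YAML pair written by [write_recording()], validates it,
#' and returns channels in deterministic montage order (source then detector
#' ascending). A series column missing for either wavelength of any montage
#' channel is a format error.
#'
#' @param path path to the `.csv` half of the pair (extension optional).
#' @return a validated `nirs_recording`.
#' @export
read_recording <- function(path) {
  p <- recording_paths(path)
  if (!file.exists(p$csv)) abort(paste0("recording file not found: ", p$csv))
  if (!file.exists(p$meta)) abort(paste0("metadata sidecar not found: ", p$meta))
  meta <- yaml::read_yaml(p$meta)
  if (!identical(meta$format, "nirsgraph-recording-v1")) {
    abort(paste0("unrecognized recording format in ", p$meta))
  }
  montage <- dplyr::bind_rows(lapply(meta$montage, as_tibble))
  montage <- validate_montage(montage, strict = FALSE)
  dat <- read.csv(p$csv, check.names = FALSE)
  wavelengths <- as.numeric(meta$wavelengths)
  want <- as.vector(t(outer(montage$channel, wavelengths,
                            function(ch, wl) sprintf("%s_%g", ch, wl))))
  missing_series <- setdiff(want, names(dat))
  if (length(missing_series)) {
    abort(paste0("format error: missing wavelength series: ",
                 paste(missing_series, collapse = ", ")))
  }
  n <- nrow(dat)
  arr <- array(
    NA_real_, dim = c(nrow(montage), 2L, n),
    dimnames = list(montage$channel, paste0("wl", wavelengths), NULL)
  )
  for (i in seq_len(nrow(montage))) {
    for (w in 1:2) {
      arr[i, w, ] <- dat[[sprintf("%s_%g", montage$channel[i], wavelengths[w])]]
    }
  }
  nirs_recording(
    participant_id = meta$participant_id,
    sampling_rate = as.numeric(meta$sampling_rate),
    intensity = arr,
    montage = montage,
    wavelengths = wavelengths,
    t0 = as.numeric(meta$t0 %||% 0)
  )
}
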