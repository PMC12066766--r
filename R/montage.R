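#' Region-of-interest labels covered by the default probe layout
#'
#' The six cortical regions monitored by the 20-channel motor/premotor
#' montage: frontal eye fields / cingulate gyrus (FEF/CG), supplementary
#' motor area (SMA), left and right premotor cortex (LPMC, RPMC), and left
#' and right primary motor cortex (LM1, RM1).
#'
#' @export
default_rois <- function() {
  c("FEF/CG", "SMA", "LPMC", "RPMC", "LM1", "RM1")
}

#' Default 20-channel montage over six motor-related regions
#'
#' Builds the package's reference montage: 20 source-detector channels from
#' an 8x8 optode set, grouped into the six regions returned by
#' [default_rois()]. Channel identity is the (source, detector) pair and
#' channels are ordered lexicographically by source then detector, so matrix
#' layouts are reproducible. The region assignment is configuration, not a
#' measured registration; override it with [map_channels_to_rois()] when the
#' real probe layout differs.
#'
#' @param distance_mm source-detector separation in millimetres applied to
#'   every channel (default 30, a typical adult CW-fNIRS separation).
#' @return a `montage` tibble with columns `channel`, `source`, `detector`,
#'   `distance_mm`, `roi`.
#' @export
default_montage <- function(distance_mm = 30) {
  layout <- tibble::tribble(
    ~source, ~detector, ~roi,
    1L, 1L, "FEF/CG",
    1L, 2L, "FEF/CG",
    2L, 1L, "FEF/CG",
    2L, 2L, "FEF/CG",
    3L, 2L, "SMA",
    3L, 3L, "SMA",
    4L, 3L, "SMA",
    4L, 4L, "LPMC",
    5L, 4L, "LPMC",
    5L, 5L, "LPMC",
    4L, 5L, "RPMC",
    6L, 5L, "RPMC",
    6L, 6L, "RPMC",
    7L, 6L, "LM1",
    7L, 7L, "LM1",
    8L, 6L, "LM1",
    8L, 7L, "LM1",
    7L, 8L, "RM1",
    8L, 8L, "RM1",
    6L, 8L, "RM1"
  )
  new_montage(layout, distance_mm = distance_mm)
}

new_montage <- function(layout, distance_mm = 30) {
  m <- layout |>
    dplyr::arrange(.data$source, .data$detector) |>
    dplyr::mutate(
      channel = sprintf("S%02dD%02d", .data$source, .data$detector),
      distance_mm = if ("distance_mm" %in% names(layout)) .data$distance_mm else distance_mm
    ) |>
    dplyr::select("channel", "source", "detector", "distance_mm", "roi")
  validate_montage(m)
}

#' Validate a montage table
#'
#' Enforces the structural invariants assumed downstream: unique channels,
#' exactly one region label per channel (a disjoint cover), and strictly
#' positive source-detector distances.
#'
#' @param montage a montage tibble (see [default_montage()]).
#' @param rois permitted region labels; defaults to [default_rois()].
#' @param strict error on region labels outside `rois` (default `TRUE`).
#' @return the validated montage, invisibly classed as `montage`.
#' @export
validate_montage <- function(montage, rois = default_rois(), strict = TRUE) {
  required <- c("channel", "source", "detector", "distance_mm", "roi")
  missing_cols <- setdiff(required, names(montage))
  if (length(missing_cols)) {
    abort(paste0("montage is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(montage$channel)) {
    dup <- unique(montage$channel[duplicated(montage$channel)])
    abort(paste0("montage channels are not a disjoint cover; duplicated: ",
                 paste(dup, collapse = ", ")))
  }
  if (any(!is.finite(montage$distance_mm) | montage$distance_mm <= 0)) {
    abort("montage distances must be strictly positive")
  }
  if (any(is.na(montage$roi))) {
    abort(paste0("channels without a region label: ",
                 paste(montage$channel[is.na(montage$roi)], collapse = ", ")))
  }
  unknown <- setdiff(unique(montage$roi), rois)
  if (length(unknown) && strict) {
    abort(paste0("unknown region labels: ", paste(unknown, collapse = ", "),
                 " (pass strict = FALSE to allow)"))
  }
  out <- as_tibble(montage)[required]
  class(out) <- c("montage", class(tibble()))
  out
}

#' Assign channels to regions of interest
#'
#' Replaces (or fills in) the region column of a montage from an explicit
#' channel-to-region map, and checks that the result is a partition: every
#' channel mapped exactly once, no channel unmapped.
#'
#' @param montage a montage tibble.
#' @param roi_spec named character vector or list mapping channel id (e.g.
#'   `"S01D01"`) to a region label.
#' @param rois permitted labels, defaults to [default_rois()].
#' @param strict error on labels outside `rois` (default `TRUE`).
#' @return the montage with the new region assignment.
#' @export
map_channels_to_rois <- function(montage, roi_spec, rois = default_rois(),
                                 strict = TRUE) {
  spec <- unlist(roi_spec)
  if (anyDuplicated(names(spec))) {
    dup <- unique(names(spec)[duplicated(names(spec))])
    abort(paste0("channel mapped to more than one region: ",
                 paste(dup, collapse = ", ")))
  }
  unmapped <- setdiff(montage$channel, names(spec))
  if (length(unmapped)) {
    abort(paste0("channels missing from roi_spec: ",
                 paste(unmapped, collapse = ", ")))
  }
  extra <- setdiff(names(spec), montage$channel)
  if (length(extra)) {
    abort(paste0("roi_spec names channels not in the montage: ",
                 paste(extra, collapse = ", ")))
  }
  montage$roi <- unname(spec[montage$channel])
  validate_montage(montage, rois = rois, strict = strict)
}

#' Channels belonging to a set of regions
#' @param montage a montage tibble.
#' @param rois character vector of region labels.
#' @return character vector of channel ids.
#' @export
roi_channels <- function(montage, rois) {
  montage$channel[montage$roi %in% rois]
}
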