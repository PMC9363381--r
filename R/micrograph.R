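#' Multi-channel micrograph container
#'
#' A `micrograph` bundles one 2D intensity matrix per stain with the metadata
#' the pipeline needs to place the image in an experiment: condition label,
#' replicate index and (for recovery series) a timepoint in minutes.
#' Intensities are non-negative and in arbitrary fluorescence units;
#' coordinates are (row, col) with pixel centres at integer positions.
#'
#' @param channels named list of numeric matrices, one per stain, all with the
#'   same dimensions. Names are stain names (e.g. `"atxn7"`, `"tia1"`,
#'   `"g3bp1"`, `"dna"`) and must be unique.
#' @param pixel_size optional pixel size in micrometres per pixel.
#' @param condition experimental condition label.
#' @param replicate replicate index (the biological replicate is the
#'   statistical unit downstream).
#' @param timepoint optional recovery timepoint in minutes.
#' @param source_path optional path the image was read from.
#'
#' @return an object of class `micrograph`.
#' @export
micrograph <- function(channels, pixel_size = NULL, condition = NA_character_,
                       replicate = NA_integer_, timepoint = NA_real_,
                       source_path = NA_character_) {
  if (!is.list(channels) || length(channels) == 0L) {
    abort("`channels` must be a non-empty named list of matrices.",
          class = "gs_invalid_micrograph")
  }
  nm <- names(channels)
  if (is.null(nm) || anyNA(nm) || any(nm == "") || anyDuplicated(nm)) {
    abort("channel (stain) names must be present and unique.",
          class = "gs_invalid_micrograph")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(channels, function(m) !is.matrix(m) || !is.numeric(m), logical(1)))) {
    abort("every channel must be a 2D numeric matrix.",
          class = "gs_invalid_micrograph")
  }
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    abort("all channels must share one (height, width) shape.",
          class = "gs_invalid_micrograph")
  }
  if (any(vapply(channels, function(m) any(m < 0), logical(1)))) {
    abort("channel intensities must be non-negative.",
          class = "gs_invalid_micrograph")
  }
  structure(
    list(channels = channels, pixel_size = pixel_size, condition = condition,
         replicate = replicate, timepoint = timepoint,
         source_path = source_path),
    class = "micrograph"
  )
}

#' @export
dim.micrograph <- function(x) dim(x$channels[[1]])

#' Stain names of a micrograph
#' @param x a [micrograph()].
#' @return character vector of stain names.
#' @export
channel_names <- function(x) names(x$channels)

#' Extract one channel of a micrograph as a matrix
#' @param x a [micrograph()].
#' @param stain stain name.
#' @return numeric matrix of intensities.
#' @export
get_channel <- function(x, stain) {
  if (!stain %in% names(x$channels)) {
    abort(sprintf("stain '%s' not present; available: %s.", stain,
                  paste(names(x$channels), collapse = ", ")),
          class = "gs_missing_channel")
  }
  x$channels[[stain]]
}

#' @export
print.micrograph <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<micrograph> %d x %d px, channels: %s\n", d[1], d[2],
              paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  condition: %s  replicate: %s  timepoint: %s\n",
              x$condition, x$replicate,
              if (is.na(x$timepoint)) "-" else paste0(x$timepoint, " min")))
  invisible(x)
}

#' Integer label mask for segmented objects
#'
#' Wraps a 2D integer matrix in which 0 is background and k >= 1 is object k.
#' Labels are kept consecutive from 1; each object is one connected component
#' under the connectivity the detector used.
#'
#' @param mask integer matrix (0 = background).
#' @param kind what the objects are: `"nucleus"`, `"aggregate"` or `"speckle"`.
#' @param stain stain (channel) the mask was derived from.
#' @param relabel relabel objects to consecutive integers starting at 1
#'   (preserving order of first appearance by original label).
#' @return an object of class `label_mask`.
#' @export
label_mask <- function(mask, kind = c("nucleus", "aggregate", "speckle"),
                       stain = NA_character_, relabel = TRUE) {
  kind <- match.arg(kind)
  if (!is.matrix(mask) || !is.numeric(mask)) {
    abort("`mask` must be an integer matrix.", class = "gs_invalid_mask")
  }
  m <- mask
  storage.mode(m) <- "integer"
  if (any(m < 0, na.rm = TRUE)) {
    abort("labels must be non-negative integers.", class = "gs_invalid_mask")
  }
  labs <- sort(unique(m[m > 0L]))
  if (relabel && length(labs) > 0L && !identical(labs, seq_along(labs))) {
    m[] <- match(m, labs, nomatch = 0L)
    m[is.na(m)] <- 0L
    labs <- seq_along(labs)
  }
  structure(list(mask = m, kind = kind, stain = stain), class = "label_mask")
}

#' Number of objects in a label mask
#' @param x a [label_mask()].
#' @return integer count.
#' @export
n_objects <- function(x) {
  if (inherits(x, "label_mask")) x <- x$mask
  as.integer(max(0L, max(x)))
}

#' @export
dim.label_mask <- function(x) dim(x$mask)

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<label_mask> %s (%s), %d x %d px, %d objects\n",
              x$kind, x$stain, d[1], d[2], n_objects(x)))
  invisible(x)
}
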