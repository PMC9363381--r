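#' Read a multi-channel micrograph from a TIFF file
#'
#' Reads a multipage TIFF (one page per channel) and maps stain names to
#' channel indices via `channel_map`. Intensities are returned on the 16-bit
#' scale (0..65535).
#'
#' @param path TIFF file path.
#' @param channel_map named integer vector, stain name -> page index
#'   (1-based), e.g. `c(atxn7 = 1, tia1 = 2, g3bp1 = 3, dna = 4)`.
#' @param pixel_size,condition,replicate,timepoint metadata attached to the
#'   returned [micrograph()].
#' @return a [micrograph()].
#' @export
read_micrograph <- function(path, channel_map, pixel_size = NULL,
                            condition = NA_character_, replicate = NA_integer_,
                            timepoint = NA_real_) {
  if (!file.exists(path)) {
    abort(sprintf("image file does not exist: %s", path),
          class = "gs_missing_file")
  }
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1)))) {
    abort("expected 2D single-sample TIFF pages; got higher-dimensional data.",
          class = "gs_not_2d")
  }
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), character(1))
  if (length(unique(shapes)) != 1L) {
    abort("TIFF pages disagree in shape; channels must share one shape.",
          class = "gs_shape_mismatch")
  }
  if (is.null(names(channel_map)) || any(names(channel_map) == "")) {
    abort("`channel_map` must be a named stain -> index vector.",
          class = "gs_invalid_channel_map")
  }
  idx <- as.integer(channel_map)
  if (any(idx < 1L) || any(idx > length(pages))) {
    abort(sprintf("channel_map requests page(s) %s but the file has %d page(s).",
                  paste(idx[idx < 1L | idx > length(pages)], collapse = ", "),
                  length(pages)),
          class = "gs_channel_out_of_range")
  }
  chans <- lapply(idx, function(k) round(pages[[k]] * 65535))
  names(chans) <- names(channel_map)
  micrograph(chans, pixel_size = pixel_size, condition = condition,
             replicate = replicate, timepoint = timepoint, source_path = path)
}

#' Write a micrograph as a 16-bit multipage TIFF
#'
#' One page per channel, in the order of `channel_names(image)`. Values must
#' lie in [0, 65535]; the round trip through [read_micrograph()] is lossless
#' for integer intensities.
#'
#' @param image a [micrograph()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(image, path) {
  vals <- image$channels
  if (any(vapply(vals, max, numeric(1)) > 65535)) {
    abort("intensities exceed the 16-bit range (65535).",
          class = "gs_range_error")
  }
  pages <- lapply(vals, function(m) m / 65535)
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 16L), silent = TRUE)
  if (inherits(ok, "try-error")) {
    abort(sprintf("could not write TIFF to %s", path), class = "gs_write_error")
  }
  invisible(path)
}

#' Write / read a label mask as a 16-bit label TIFF
#'
#' Background is 0; object k is stored as gray value k. Masks with more than
#' 65535 labels cannot be represented and raise an error.
#'
#' @param mask a [label_mask()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  m <- mask$mask
  if (max(m) > 65535L) {
    abort(sprintf("mask has %d labels; 16-bit label TIFF supports at most 65535.",
                  max(m)),
          class = "gs_range_error")
  }
  ok <- try(tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L),
            silent = TRUE)
  if (inherits(ok, "try-error")) {
    abort(sprintf("could not write label TIFF to %s", path),
          class = "gs_write_error")
  }
  invisible(path)
}

#' @rdname write_label_mask
#' @param kind,stain metadata for the reconstructed [label_mask()].
#' @export
read_label_mask <- function(path, kind = "speckle", stain = NA_character_) {
  if (!file.exists(path)) {
    abort(sprintf("mask file does not exist: %s", path),
          class = "gs_missing_file")
  }
  m <- round(tiff::readTIFF(path) * 65535)
  label_mask(m, kind = kind, stain = stain, relabel = FALSE)
}

#' Write / read measurement tables as CSV
#'
#' Plain comma-separated UTF-8 with '.' decimal and one header row; an empty
#' record set yields a header-only file. Round trips preserve values exactly
#' for the column types the pipeline emits.
#'
#' @param records a data frame.
#' @param path output path.
#' @return `path` invisibly (write) or a tibble (read).
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records)) {
    abort("`records` must be a data frame.", class = "gs_invalid_table")
  }
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("table does not exist: %s", path), class = "gs_missing_file")
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Run manifest: images, conditions, replicates, timepoints
#'
#' A run manifest lists every image of an experiment with its condition,
#' replicate and optional timepoint, the channel map resolving stain names to
#' TIFF pages, the control condition for fold changes, and the reference
#' condition used to calibrate the per-replicate minimum threshold.
#'
#' @param entries tibble with columns `path`, `condition`, `replicate`, and
#'   optionally `timepoint`.
#' @param channel_map named stain -> page index vector shared by all entries.
#' @param control_condition condition label used as fold-change control.
#' @param reference_condition condition whose images calibrate the minimum
#'   threshold (per replicate).
#' @return an object of class `run_manifest`.
#' @export
run_manifest <- function(entries, channel_map,
                         control_condition,
                         reference_condition = control_condition) {
  entries <- as_tibble(entries)
  needed <- c("path", "condition", "replicate")
  if (!all(needed %in% names(entries))) {
    abort(sprintf("manifest entries need columns %s.",
                  paste(needed, collapse = ", ")),
          class = "gs_invalid_manifest")
  }
  if (!"timepoint" %in% names(entries)) entries$timepoint <- NA_real_
  if (!control_condition %in% entries$condition) {
    abort(sprintf("control condition '%s' has no entries in the manifest.",
                  control_condition),
          class = "gs_invalid_manifest")
  }
  structure(list(entries = entries, channel_map = channel_map,
                 control_condition = control_condition,
                 reference_condition = reference_condition),
            class = "run_manifest")
}

#' @rdname run_manifest
#' @param path YAML file path.
#' @export
read_run_manifest <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("manifest does not exist: %s", path),
          class = "gs_missing_file")
  }
  y <- yaml::read_yaml(path)
  entries <- list_rbind(lapply(y$entries, function(e) {
    tibble(path = e$path, condition = e$condition,
           replicate = as.integer(e$replicate),
           timepoint = if (is.null(e$timepoint)) NA_real_ else as.numeric(e$timepoint))
  }))
  run_manifest(entries, unlist(y$channel_map), y$control_condition,
               y$reference_condition %||% y$control_condition)
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @export
write_run_manifest <- function(manifest, path) {
  y <- list(
    channel_map = as.list(manifest$channel_map),
    control_condition = manifest$control_condition,
    reference_condition = manifest$reference_condition,
    entries = lapply(seq_len(nrow(manifest$entries)), function(i) {
      e <- manifest$entries[i, ]
      out <- list(path = e$path, condition = e$condition,
                  replicate = e$replicate)
      if (!is.na(e$timepoint)) out$timepoint <- e$timepoint
      out
    })
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
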