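#' Parameters for speckle detection
#'
#' Encodes the manual counting rules for protein speckles: a speckle must be
#' rounded or oval (eccentricity bound), within an area range, and its
#' staining intensity must be at least `min_fold` times the immediate
#' background (median of a 2 px wide ring starting 2 px outside the object,
#' excluding pixels of other objects). The intensity statistic compared
#' against the background is the object's peak (max) intensity by default;
#' `fold_statistic = "mean"` uses the mean over the segmented mask instead.
#'
#' @param min_fold minimum fold over immediate background (default 8, the
#'   eightfold manual counting rule).
#' @param min_area,max_area object area bounds in px^2.
#' @param max_eccentricity maximum moments-ellipse eccentricity (rounded or
#'   oval rule).
#' @param connectivity 4 or 8 (8 is standard for bright puncta).
#' @param fold_statistic `"max"` (peak intensity) or `"mean"`.
#' @return an object of class `speckle_params`.
#' @export
speckle_params <- function(min_fold = 8, min_area = 4, max_area = 80,
                           max_eccentricity = 0.95, connectivity = 8,
                           fold_statistic = c("max", "mean")) {
  fold_statistic <- match.arg(fold_statistic)
  if (min_fold <= 1) {
    abort("`min_fold` must exceed 1.", class = "gs_invalid_spec")
  }
  if (min_area <= 0 || min_area > max_area) {
    abort("need 0 < min_area <= max_area.", class = "gs_invalid_spec")
  }
  if (max_eccentricity < 0 || max_eccentricity >= 1) {
    abort("`max_eccentricity` must lie in [0, 1).", class = "gs_invalid_spec")
  }
  if (!connectivity %in% c(4, 8)) {
    abort("`connectivity` must be 4 or 8.", class = "gs_invalid_spec")
  }
  structure(list(min_fold = min_fold, min_area = min_area, max_area = max_area,
                 max_eccentricity = max_eccentricity,
                 connectivity = connectivity, fold_statistic = fold_statistic),
            class = "speckle_params")
}

# Label connected foreground components. EBImage::bwlabel is 8-connected;
# 4-connectivity is emulated by severing diagonal-only links.
label_components <- function(fg, connectivity = 8) {
  if (!any(fg)) return(matrix(0L, nrow(fg), ncol(fg)))
  lab <- EBImage::bwlabel(fg * 1)
  if (connectivity == 4) {
    # relabel each 8-component into 4-components by flood fill on rows/cols
    lab4 <- matrix(0L, nrow(fg), ncol(fg))
    nxt <- 0L
    for (k in seq_len(max(lab))) {
      sub <- lab == k
      while (any(sub)) {
        seed <- which(sub, arr.ind = TRUE)[1, , drop = FALSE]
        comp <- EBImage::floodFill(sub * 1, pt = seed[, c(2, 1)], col = 2) == 2
        nxt <- nxt + 1L
        lab4[comp] <- nxt
        sub[comp] <- FALSE
      }
    }
    lab <- lab4
  }
  m <- lab
  storage.mode(m) <- "integer"
  m
}

# Median intensity of a ring (width px wide, starting gap px outside each
# object), excluding pixels belonging to any object. Computed on a local
# window per object for speed. Returns one value per label.
ring_background <- function(image, labels, gap = 2L, width = 2L) {
  n <- max(labels)
  if (n == 0L) return(numeric(0))
  nr <- nrow(labels); nc <- ncol(labels)
  inner <- EBImage::makeBrush(2L * gap + 1L, shape = "disc")
  outer_b <- EBImage::makeBrush(2L * (gap + width) + 1L, shape = "disc")
  pad <- gap + width + 1L
  out <- numeric(n)
  w <- which(labels > 0)
  labs <- labels[w]
  rows <- ((w - 1L) %% nr) + 1L
  cols <- ((w - 1L) %/% nr) + 1L
  by_lab <- split(seq_along(w), labs)
  for (lb in names(by_lab)) {
    ii <- by_lab[[lb]]
    r0 <- max(1L, min(rows[ii]) - pad); r1 <- min(nr, max(rows[ii]) + pad)
    c0 <- max(1L, min(cols[ii]) - pad); c1 <- min(nc, max(cols[ii]) + pad)
    sub_lab <- labels[r0:r1, c0:c1]
    obj <- (sub_lab == as.integer(lb)) * 1
    ring <- EBImage::dilate(obj, outer_b) > 0 & !(EBImage::dilate(obj, inner) > 0)
    ring <- ring & sub_lab == 0L
    vals <- image[r0:r1, c0:c1][ring]
    out[as.integer(lb)] <- if (length(vals)) median(vals) else NA_real_
  }
  out
}

#' Detect nuclei in the DNA channel
#'
#' Two-class Otsu threshold, hole filling, a small opening, area filtering and
#' a distance-map watershed to split touching nuclei.
#'
#' @param dna numeric matrix (DNA channel) or a [micrograph()] containing a
#'   `"dna"` channel.
#' @param min_area minimum nucleus area in px^2.
#' @param opening_radius radius of the pre-watershed opening brush.
#' @return a [label_mask()] of kind `"nucleus"`. An image with no foreground
#'   yields an empty mask (0 labels) with a warning.
#' @export
detect_nuclei <- function(dna, min_area = 60, opening_radius = 2) {
  if (inherits(dna, "micrograph")) dna <- get_channel(dna, "dna")
  rng <- range(dna)
  if (diff(rng) <= 0) {
    warn("DNA channel is constant; no nuclei found.")
    return(label_mask(matrix(0L, nrow(dna), ncol(dna)), kind = "nucleus",
                      stain = "dna"))
  }
  scaled <- (dna - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  fg <- scaled > thr
  if (!any(fg)) {
    warn("no foreground after thresholding; 0 nuclei.")
    return(label_mask(matrix(0L, nrow(dna), ncol(dna)), kind = "nucleus",
                      stain = "dna"))
  }
  fg <- EBImage::fillHull(fg * 1) > 0
  if (opening_radius > 0) {
    brush <- EBImage::makeBrush(2 * opening_radius + 1, shape = "disc")
    fg <- EBImage::opening(fg * 1, brush) > 0
  }
  if (!any(fg)) {
    warn("no foreground after opening; 0 nuclei.")
    return(label_mask(matrix(0L, nrow(dna), ncol(dna)), kind = "nucleus",
                      stain = "dna"))
  }
  dm <- EBImage::distmap(fg * 1)
  ws <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  m <- matrix(as.integer(ws), nrow(dna), ncol(dna))
  # area filter, then relabel consecutively
  tab <- tabulate(m[m > 0L])
  drop <- which(tab < min_area)
  if (length(drop)) m[m %in% drop] <- 0L
  label_mask(m, kind = "nucleus", stain = "dna")
}

#' Detect speckles with the three-class Otsu + fold rules
#'
#' Candidate objects are 8-connected components of pixels above the applied
#' threshold (`max(t_high, threshold_floor)`, where `t_high` is the upper
#' threshold of [otsu_three_class()] and the floor comes from per-replicate
#' calibration). Each candidate is retained iff its area lies within the
#' bounds, its eccentricity does not exceed the rounded-or-oval bound, and
#' its intensity is at least `min_fold` times the immediate ring background.
#'
#' @param image numeric matrix (one stain channel).
#' @param params a [speckle_params()].
#' @param threshold_floor optional per-replicate minimum threshold.
#' @param stain stain name recorded in the returned mask.
#' @return a list: `mask` (a [label_mask()] of the retained speckles,
#'   relabelled consecutively), `records` (tibble of all candidates with
#'   measurements, retention verdict and rejection reason), `threshold`
#'   (the applied `threshold_result`).
#' @export
detect_speckles <- function(image, params = speckle_params(),
                            threshold_floor = NULL, stain = NA_character_) {
  if (inherits(image, "micrograph")) {
    abort("pass a single channel matrix (use get_channel()).",
          class = "gs_invalid_input")
  }
  thr <- otsu_three_class(image)
  ap <- apply_threshold(image, thr, threshold_floor)
  lab <- label_components(ap$foreground, params$connectivity)
  props <- region_props(lab, image, min_shape_area = 5L)
  if (nrow(props) == 0L) {
    return(list(mask = label_mask(lab, kind = "speckle", stain = stain),
                records = props, threshold = ap$threshold))
  }
  bg <- ring_background(image, lab)
  props$ring_background <- bg[props$label]
  stat <- if (params$fold_statistic == "max") props$max_intensity else props$mean_intensity
  props$fold_over_background <- ifelse(!is.na(props$ring_background) &
                                         props$ring_background > 0,
                                       stat / props$ring_background, Inf)
  area_ok <- props$area >= params$min_area & props$area <= params$max_area
  # small candidates without defined shape pass the shape rule by default;
  # border-clipped objects are kept for counting, shape rule not applicable
  ecc_ok <- is.na(props$eccentricity) |
    props$eccentricity <= params$max_eccentricity
  fold_ok <- props$fold_over_background >= params$min_fold
  props$retained <- area_ok & ecc_ok & fold_ok
  props$reject_reason <- dplyr::case_when(
    props$retained ~ "",
    !area_ok ~ "area",
    !ecc_ok ~ "shape",
    TRUE ~ "intensity")
  keep <- props$label[props$retained]
  m2 <- lab
  m2[!(m2 %in% keep)] <- 0L
  mask <- label_mask(m2, kind = "speckle", stain = stain)
  props$mask_label <- ifelse(props$retained, match(props$label, sort(keep)),
                             NA_integer_)
  props$applied_threshold <- ap$applied
  list(mask = mask, records = as_tibble(props), threshold = ap$threshold)
}

#' Detect ATXN7 aggregates and classify their compartment
#'
#' Aggregates are the top Otsu class of the ATXN7 channel (three classes,
#' middle class to background) with an aggregate-specific area floor that
#' separates them from small ATXN7 speckles. An aggregate is `"nuclear"` when
#' its centroid falls inside a nucleus label and `"cytoplasmic"` otherwise.
#'
#' Because the diffuse ATXN7 level differs between nucleus and cytoplasm, the
#' three-class threshold is computed separately over the nuclear region and
#' the extra-nuclear region, and the foreground is the union of the two
#' top classes; this keeps cytoplasmic aggregates from being swallowed by the
#' brighter nuclear diffuse class.
#'
#' @param atxn7 numeric matrix (ATXN7 channel).
#' @param nuclei a [label_mask()] of nuclei aligned with the channel.
#' @param min_area aggregate area floor in px^2; separates aggregates from
#'   small ATXN7 speckles.
#' @param min_fold minimum peak intensity over the immediate ring background;
#'   rejects diffuse-noise blobs in images without true aggregates, where the
#'   top Otsu class necessarily falls inside the noise of the diffuse stain.
#' @param threshold_floor optional minimum threshold.
#' @return list: `mask` (a [label_mask()] of kind `"aggregate"`), `records`
#'   (tibble with compartment, centroid, area, intensity and shape columns),
#'   `threshold` (the extra-nuclear `threshold_result`).
#' @export
detect_aggregates <- function(atxn7, nuclei, min_area = 20, min_fold = 2.5,
                              threshold_floor = NULL) {
  nuc_m <- (if (inherits(nuclei, "label_mask")) nuclei$mask else nuclei) > 0
  fg <- matrix(FALSE, nrow(atxn7), ncol(atxn7))
  regional_threshold <- function(vals) {
    if (length(unique(vals)) < 3L) return(NULL)
    otsu_three_class(matrix(vals, ncol = 1))
  }
  thr_out <- regional_threshold(atxn7[!nuc_m]) %||% otsu_three_class(atxn7)
  ap <- apply_threshold(atxn7, thr_out, threshold_floor)
  fg[!nuc_m] <- atxn7[!nuc_m] > ap$applied
  if (any(nuc_m)) {
    thr_in <- regional_threshold(atxn7[nuc_m])
    if (!is.null(thr_in)) {
      ap_in <- apply_threshold(atxn7, thr_in, threshold_floor)
      fg[nuc_m] <- atxn7[nuc_m] > ap_in$applied
    } else {
      fg[nuc_m] <- atxn7[nuc_m] > ap$applied
    }
  }
  # declump touching aggregates with a distance-map watershed
  lab <- if (any(fg)) {
    ws <- EBImage::watershed(EBImage::distmap(fg * 1), tolerance = 1, ext = 1)
    m <- matrix(as.integer(ws), nrow(atxn7), ncol(atxn7))
    m
  } else {
    matrix(0L, nrow(atxn7), ncol(atxn7))
  }
  props <- region_props(lab, atxn7)
  nuc <- if (inherits(nuclei, "label_mask")) nuclei$mask else nuclei
  if (nrow(props)) {
    props <- filter(props, .data$area >= min_area)
  }
  if (nrow(props) && min_fold > 0) {
    bg <- ring_background(atxn7, lab)
    fold <- ifelse(!is.na(bg[props$label]) & bg[props$label] > 0,
                   props$max_intensity / bg[props$label], Inf)
    props$fold_over_background <- fold
    props <- filter(props, .data$fold_over_background >= min_fold)
  }
  keep <- props$label
  m2 <- lab
  m2[!(m2 %in% keep)] <- 0L
  mask <- label_mask(m2, kind = "aggregate", stain = "atxn7")
  if (nrow(props)) {
    ctr <- cbind(pmin(pmax(round(props$centroid_row), 1), nrow(nuc)),
                 pmin(pmax(round(props$centroid_col), 1), ncol(nuc)))
    props$compartment <- ifelse(nuc[ctr] > 0L, "nuclear", "cytoplasmic")
    props$label <- match(props$label, keep)   # follow the relabelled mask
  } else {
    props$compartment <- character(0)
  }
  list(mask = mask, records = as_tibble(props), threshold = ap$threshold)
}

#' Call double-positive stress granules from two speckle masks
#'
#' A G3BP1 object is a stress granule iff its centroid falls inside a TIA1
#' object, or vice versa (symmetric centroid containment). Returns the
#' matched pairs and their count.
#'
#' @param mask_a,mask_b [label_mask()]s on the same image (e.g. G3BP1 and
#'   TIA1 speckles).
#' @return list: `n` (number of double-positive granules), `pairs` (tibble
#'   with `label_a`, `label_b`, and which direction matched).
#' @export
call_double_positive <- function(mask_a, mask_b) {
  ma <- if (inherits(mask_a, "label_mask")) mask_a$mask else mask_a
  mb <- if (inherits(mask_b, "label_mask")) mask_b$mask else mask_b
  if (!all(dim(ma) == dim(mb))) {
    abort("masks must be aligned (same shape).", class = "gs_shape_mismatch")
  }
  centroid_hits <- function(from, to) {
    pr <- region_props(from)
    if (nrow(pr) == 0L) {
      return(tibble(label_from = integer(0), label_to = integer(0)))
    }
    ctr <- cbind(pmin(pmax(round(pr$centroid_row), 1), nrow(to)),
                 pmin(pmax(round(pr$centroid_col), 1), ncol(to)))
    hit <- to[ctr]
    tibble(label_from = pr$label[hit > 0L], label_to = hit[hit > 0L])
  }
  ab <- centroid_hits(ma, mb)
  ba <- centroid_hits(mb, ma)
  pairs <- bind_rows(
    tibble(label_a = ab$label_from, label_b = ab$label_to, direction = "a_in_b"),
    tibble(label_a = ba$label_to, label_b = ba$label_from, direction = "b_in_a")
  )
  pairs <- distinct(pairs, .data$label_a, .data$label_b, .keep_all = TRUE)
  list(n = nrow(pairs), pairs = pairs)
}
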