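# Second-central-moment machinery. Pixels are modelled as unit squares centred
# on integer coordinates, so 1/12 (the variance of a unit square) is added to
# the diagonal moments; the cross moment needs no correction.

moments_from_coords <- function(rows, cols) {
  mr <- mean(rows); mc <- mean(cols)
  dr <- rows - mr; dc <- cols - mc
  list(
    centroid = c(mr, mc),
    c20 = mean(dr^2) + 1 / 12,
    c02 = mean(dc^2) + 1 / 12,
    c11 = mean(dr * dc)
  )
}

ellipse_params_from_moments <- function(mo) {
  tr <- mo$c20 + mo$c02
  dt <- mo$c20 * mo$c02 - mo$c11^2
  disc <- sqrt(max(tr^2 / 4 - dt, 0))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, 0)
  ecc <- if (l1 <= 0) 0 else sqrt(max(1 - l2 / l1, 0))
  degenerate <- l2 < 1e-9
  if (degenerate) ecc <- min(ecc, 0.9999)
  list(
    eccentricity = ecc,
    degenerate = degenerate,
    orientation = 0.5 * atan2(2 * mo$c11, mo$c20 - mo$c02),
    major_axis = 4 * sqrt(l1),
    minor_axis = 4 * sqrt(l2)
  )
}

#' Eccentricity of the moments-matched ellipse of an object
#'
#' Eccentricity of the ellipse with the same second central moments as the
#' object: 0 for a circle, approaching 1 for a line. Matches the CellProfiler
#' convention. Pixels are treated as unit squares (a 1/12 term on the diagonal
#' moments). For degenerate (collinear) objects the value is capped below 1
#' and flagged via the `"degenerate"` attribute.
#'
#' @param mask logical/0-1 matrix of one object, or a matrix of pixel
#'   coordinates (n x 2).
#' @return eccentricity in [0, 1).
#' @export
eccentricity <- function(mask) {
  coords <- if (is.matrix(mask) && ncol(mask) == 2 && !all(mask %in% c(0, 1))) {
    mask
  } else {
    which(mask > 0, arr.ind = TRUE)
  }
  if (nrow(coords) < 5L) {
    abort("eccentricity needs an object of at least 5 pixels.",
          class = "gs_degenerate_input")
  }
  ep <- ellipse_params_from_moments(moments_from_coords(coords[, 1], coords[, 2]))
  structure(ep$eccentricity, degenerate = ep$degenerate)
}

# Moore-neighbour boundary tracing of one 8-connected object. Terminates
# when the (pixel, backtrack-direction) state repeats, which guarantees one
# full cycle of the outer contour even when the contour passes through a
# pixel more than once. Returns boundary pixel coordinates in order.
trace_boundary <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) <= 1L) return(unname(idx))
  # clockwise neighbour ring starting W
  offs <- rbind(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
                c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  nr <- nrow(mask); nc <- ncol(mask)
  is_fg <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc &&
    mask[r, c] > 0
  # first pixel in column-major order: smallest col then row -> W neighbour
  # is guaranteed background, a valid backtrack
  start <- as.integer(idx[1, ])
  p <- start
  dir_from <- 1L               # index of the backtrack neighbour (W)
  boundary <- list()           # boundary[[i]] is the pixel of state i
  states <- character(0)
  repeat {
    key <- paste(p[1], p[2], dir_from, sep = ",")
    hit <- match(key, states)
    if (!is.na(hit)) {
      # one full period of the contour cycle (any transient prefix dropped)
      return(do.call(rbind, boundary[hit:length(boundary)]))
    }
    states <- c(states, key)
    boundary[[length(boundary) + 1L]] <- p
    found_d <- NA_integer_
    for (s in 0:7) {
      d <- ((dir_from - 1L + s) %% 8L) + 1L
      if (is_fg(p[1] + offs[d, 1], p[2] + offs[d, 2])) {
        found_d <- d
        break
      }
    }
    if (is.na(found_d)) return(matrix(p, 1, 2))   # isolated pixel
    nxt <- c(p[1] + offs[found_d, 1], p[2] + offs[found_d, 2])
    # backtrack for the next pixel: the neighbour checked just before the
    # found one, re-expressed relative to the new pixel
    prev_d <- ((found_d - 2L) %% 8L) + 1L
    back <- c(p[1] + offs[prev_d, 1], p[2] + offs[prev_d, 2])
    p <- nxt
    rel <- back - p
    dir_from <- which(offs[, 1] == rel[1] & offs[, 2] == rel[2])
    if (length(dir_from) != 1L) dir_from <- 1L
  }
}

# Corner-corrected chain-code perimeter (Vossepoel-Smeulders weights) from an
# ordered closed boundary.
perimeter_from_boundary <- function(boundary) {
  n <- nrow(boundary)
  if (n == 1L) return(4 * 0.948 / 2)      # lone pixel: nominal tiny contour
  nxt <- rbind(boundary[-1, , drop = FALSE], boundary[1, , drop = FALSE])
  step <- nxt - boundary
  d <- abs(step)
  diag_step <- d[, 1] == 1 & d[, 2] == 1
  ax_step <- (d[, 1] + d[, 2]) == 1
  code <- atan2(step[, 2], step[, 1])
  corners <- sum(code != c(code[-1], code[1]))
  0.980 * sum(ax_step) + 1.406 * sum(diag_step) - 0.091 * corners
}

#' Perimeter of a single object
#'
#' Contour-path length along the object's Moore-traced boundary with
#' corner-corrected chain-code weights (0.980 axial, 1.406 diagonal, -0.091
#' per corner), which removes the systematic over-estimate of raw pixel-edge
#' counting.
#'
#' @param mask logical/0-1 matrix containing one 8-connected object.
#' @return perimeter in pixels.
#' @export
object_perimeter <- function(mask) {
  b <- trace_boundary(mask)
  if (nrow(b) == 0L) {
    abort("empty mask has no perimeter.", class = "gs_degenerate_input")
  }
  perimeter_from_boundary(b)
}

#' Form factor of a single object
#'
#' `4 * pi * area / perimeter^2`: 1 for a circle, smaller for elongated or
#' rough shapes. Uses [object_perimeter()].
#'
#' @param mask logical/0-1 matrix containing one 8-connected object.
#' @return dimensionless form factor.
#' @export
form_factor <- function(mask) {
  area <- sum(mask > 0)
  p <- object_perimeter(mask)
  if (p <= 0) abort("zero perimeter.", class = "gs_degenerate_input")
  4 * pi * area / p^2
}

#' Per-object morphometry table for a label mask
#'
#' Computes, for every labelled object: area, centroid, eccentricity,
#' orientation and axis lengths of the moments ellipse, corner-corrected
#' perimeter, form factor, and (when an intensity image is supplied) mean,
#' maximum and total intensity. Objects touching the image border are kept
#' (flagged `on_border`) but their shape metrics are set to `NA`, since shape
#' is undefined for clipped objects; objects below `min_shape_area` pixels
#' also get `NA` shape metrics.
#'
#' @param mask a [label_mask()] or integer label matrix.
#' @param image optional numeric intensity matrix aligned with the mask.
#' @param min_shape_area minimum pixel count for shape metrics (default 5).
#' @return a tibble with one row per object.
#' @export
region_props <- function(mask, image = NULL, min_shape_area = 5L) {
  m <- if (inherits(mask, "label_mask")) mask$mask else mask
  nr <- nrow(m); nc <- ncol(m)
  w <- which(m > 0)
  if (length(w) == 0L) {
    return(tibble(label = integer(0), area = integer(0), centroid_row = numeric(0),
                  centroid_col = numeric(0), eccentricity = numeric(0),
                  orientation = numeric(0), major_axis = numeric(0),
                  minor_axis = numeric(0), perimeter = numeric(0),
                  form_factor = numeric(0), on_border = logical(0),
                  mean_intensity = numeric(0), max_intensity = numeric(0),
                  total_intensity = numeric(0)))
  }
  labs <- m[w]
  rows <- ((w - 1L) %% nr) + 1L
  cols <- ((w - 1L) %/% nr) + 1L
  by_lab <- split(seq_along(w), labs)

  out <- lapply(names(by_lab), function(lb) {
    ii <- by_lab[[lb]]
    r <- rows[ii]; c <- cols[ii]
    area <- length(ii)
    on_border <- any(r == 1L | r == nr | c == 1L | c == nc)
    mo <- moments_from_coords(r, c)
    shape_ok <- area >= min_shape_area && !on_border
    if (shape_ok) {
      ep <- ellipse_params_from_moments(mo)
      r0 <- min(r); c0 <- min(c)
      sub <- matrix(0L, max(r) - r0 + 3L, max(c) - c0 + 3L)
      sub[cbind(r - r0 + 2L, c - c0 + 2L)] <- 1L
      perim <- perimeter_from_boundary(trace_boundary(sub))
      ff <- if (perim > 0) 4 * pi * area / perim^2 else NA_real_
    } else {
      ep <- list(eccentricity = NA_real_, orientation = NA_real_,
                 major_axis = NA_real_, minor_axis = NA_real_)
      perim <- NA_real_; ff <- NA_real_
    }
    tibble(
      label = as.integer(lb), area = area,
      centroid_row = mo$centroid[1], centroid_col = mo$centroid[2],
      eccentricity = ep$eccentricity, orientation = ep$orientation,
      major_axis = ep$major_axis, minor_axis = ep$minor_axis,
      perimeter = perim, form_factor = ff, on_border = on_border,
      mean_intensity = if (is.null(image)) NA_real_ else mean(image[w[ii]]),
      max_intensity = if (is.null(image)) NA_real_ else max(image[w[ii]]),
      total_intensity = if (is.null(image)) NA_real_ else sum(image[w[ii]]))
  })
  arrange(list_rbind(out), .data$label)
}

#' Texture of a staining as intensity variance
#'
#' Population variance of pixel intensities over an analysis region (the
#' whole image when no mask is given). High variance means the signal is
#' granular/speckled rather than diffuse. For condition contrasts, restrict
#' the region to the cell area (see [cell_region_mask()]) so empty background
#' does not dilute the measure.
#'
#' @param image numeric matrix.
#' @param mask optional logical matrix selecting the analysis region.
#' @return variance (intensity squared units).
#' @export
texture_variance <- function(image, mask = NULL) {
  x <- if (is.null(mask)) as.numeric(image) else as.numeric(image[mask > 0])
  if (length(x) == 0L) {
    abort("texture region is empty.", class = "gs_degenerate_input")
  }
  mean((x - mean(x))^2)
}

#' Cell-area region from a nucleus mask
#'
#' Union of all nuclei dilated by `width` pixels: a simple whole-cell region
#' for per-cell texture and intensity measures.
#'
#' @param nuclei a [label_mask()] of nuclei.
#' @param width dilation radius in px (about the cytoplasm width).
#' @return logical matrix.
#' @export
cell_region_mask <- function(nuclei, width = 10) {
  m <- (if (inherits(nuclei, "label_mask")) nuclei$mask else nuclei) > 0
  if (!any(m)) return(m)
  brush <- EBImage::makeBrush(2 * floor(width) + 1, shape = "disc")
  EBImage::dilate(m * 1, brush) > 0
}

#' Total image intensity normalised per nucleus
#'
#' Sums all pixel intensities of a channel and divides by the number of
#' segmented nuclei, the per-cell normalisation used for total-stain
#' comparisons across conditions. Images without nuclei cannot be normalised
#' and return `NA` with a warning.
#'
#' @param image numeric matrix (one channel).
#' @param nuclei a [label_mask()] of nuclei.
#' @return a one-row tibble: `total_intensity`, `n_nuclei`,
#'   `intensity_per_nucleus`, `texture_variance` (whole image).
#' @export
intensity_per_nucleus <- function(image, nuclei) {
  n <- n_objects(nuclei)
  total <- sum(image)
  if (n == 0L) {
    warn("image has no segmented nuclei; per-nucleus intensity is undefined and the image should be excluded.")
    per <- NA_real_
  } else {
    per <- total / n
  }
  tibble(total_intensity = total, n_nuclei = n, intensity_per_nucleus = per,
         texture_variance = texture_variance(image))
}
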