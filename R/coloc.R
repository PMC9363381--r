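#' Extract an intensity profile along a line through an aggregate
#'
#' Draws a line through the aggregate's centroid along its principal axis
#' (total length `max(length, 3 x major axis)`), samples every channel at
#' 1 px steps by bilinear interpolation, and returns a long tibble of class
#' `intensity_profile` (columns `position`, `channel`, `intensity`) with the
#' line endpoints and aggregate id as attributes. If the line exits the image
#' it is truncated symmetrically around the centroid; fewer than 7 remaining
#' samples is an error.
#'
#' When a cell-region mask is supplied (see [cell_region_mask()]), samples
#' are marked with an `in_region` flag; [score_profile()] then estimates the
#' immediate background from in-cell samples only, so the dark exterior of
#' the cell does not masquerade as background staining.
#'
#' @param image a [micrograph()].
#' @param aggregate one-row data frame with `centroid_row`, `centroid_col`,
#'   `orientation`, `major_axis` and (optionally) `label` — as produced by
#'   [detect_aggregates()].
#' @param length minimum line length in px.
#' @param step sampling step in px.
#' @param region optional logical matrix (cell area); samples outside it are
#'   trimmed from the line ends.
#' @return an `intensity_profile` tibble.
#' @export
extract_profile <- function(image, aggregate, length = 0, step = 1,
                            region = NULL) {
  stopifnot(inherits(image, "micrograph"))
  r0 <- aggregate$centroid_row[[1]]
  c0 <- aggregate$centroid_col[[1]]
  theta <- aggregate$orientation[[1]]
  if (is.na(theta)) theta <- 0
  major <- aggregate$major_axis[[1]]
  if (is.na(major)) major <- 0
  total <- max(length, 3 * major)
  if (total < 6) total <- max(total, 12)   # floor for tiny/degenerate objects
  half <- total / 2
  d <- dim(image)
  u <- seq(-half, half, by = step)
  rr <- r0 + u * cos(theta)
  cc <- c0 + u * sin(theta)
  # symmetric truncation: keep the largest |u| window fully inside bounds
  # (1-px margin for bilinear interpolation)
  ok <- rr >= 1 & rr <= d[1] - 1e-9 & cc >= 1 & cc <= d[2] - 1e-9
  inside <- function(uu) {
    r <- r0 + uu * cos(theta); c <- c0 + uu * sin(theta)
    r >= 1 && r <= d[1] && c >= 1 && c <= d[2]
  }
  if (!all(ok)) {
    bad <- abs(u[!ok])
    lim <- min(bad) - step
    keep <- abs(u) <= lim
    u <- u[keep]; rr <- rr[keep]; cc <- cc[keep]
  }
  if (length(u) < 7L) {
    abort("profile line has fewer than 7 in-bounds samples; aggregate too close to the border.",
          class = "gs_profile_too_short")
  }
  inreg <- if (is.null(region)) {
    rep(TRUE, length(u))
  } else {
    region[cbind(pmin(pmax(round(rr), 1L), d[1]),
                 pmin(pmax(round(cc), 1L), d[2]))] > 0
  }
  prof <- lapply(channel_names(image), function(ch) {
    tibble(position = u - min(u), channel = ch,
           intensity = bilinear_sample(get_channel(image, ch), rr, cc),
           in_region = inreg)
  })
  out <- list_rbind(prof)
  class(out) <- c("intensity_profile", class(out))
  attr(out, "endpoints") <- rbind(c(rr[1], cc[1]), c(rr[length(rr)], cc[length(cc)]))
  attr(out, "aggregate_id") <- aggregate$label[[1]] %||% NA_integer_
  attr(out, "centre_position") <- -min(u)
  out
}

# Vectorised bilinear interpolation at (rows, cols) with pixel centres on
# integer coordinates.
bilinear_sample <- function(m, rows, cols) {
  r0 <- floor(rows); c0 <- floor(cols)
  r0 <- pmin(pmax(r0, 1L), nrow(m) - 1L)
  c0 <- pmin(pmax(c0, 1L), ncol(m) - 1L)
  fr <- rows - r0; fc <- cols - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  m[i00] * (1 - fr) * (1 - fc) + m[i10] * fr * (1 - fc) +
    m[i01] * (1 - fr) * fc + m[i11] * fr * fc
}

#' Score one profile for partner-stain co-localisation
#'
#' Implements the line-profile rule for aggregate co-localisation: the
#' reference peak is the maximum of the reference stain's (smoothed) series;
#' the partner peak is the local maximum of the partner series nearest to it.
#' The immediate background is the median of the partner's raw intensities
#' over the outer quartiles of the line. An aggregate is positive iff the
#' partner peak coincides with the reference peak (offset at most
#' `coincidence_tol` px) and `peak_fold = partner peak / background` meets
#' `fold_threshold` (the twofold rule; inclusive by default, set
#' `strict = TRUE` for a strict inequality).
#'
#' @param profile an `intensity_profile` from [extract_profile()].
#' @param reference reference stain name (the aggregate stain).
#' @param partner partner stain name.
#' @param fold_threshold minimum peak-over-background fold (default 2).
#' @param coincidence_tol maximum peak offset in px (default 3).
#' @param smooth moving-average window (odd; default 3) used for peak
#'   finding, suppressing single-pixel noise peaks.
#' @param strict require fold strictly above the threshold.
#' @return one-row tibble of class `coloc_call`: `aggregate_id`, `partner`,
#'   `peak_fold`, `peak_offset`, `coincident`, `positive`.
#' @export
score_profile <- function(profile, reference, partner, fold_threshold = 2,
                          coincidence_tol = 3, smooth = 3, strict = FALSE) {
  chans <- unique(profile$channel)
  if (!all(c(reference, partner) %in% chans)) {
    abort(sprintf("profile lacks stain(s): %s.",
                  paste(setdiff(c(reference, partner), chans), collapse = ", ")),
          class = "gs_missing_channel")
  }
  ref <- filter(profile, .data$channel == reference)
  par <- filter(profile, .data$channel == partner)
  ref_s <- moving_average(ref$intensity, smooth)
  par_s <- moving_average(par$intensity, smooth)
  n <- length(par_s)
  q <- floor(n / 4)
  outer_idx <- c(seq_len(q), seq(n - q + 1, n))
  if ("in_region" %in% names(par) && sum(par$in_region[outer_idx]) >= 4) {
    outer_idx <- outer_idx[par$in_region[outer_idx]]
  }
  background <- median(par$intensity[outer_idx])
  if (!is.finite(background) || background <= 0) {
    abort("partner background along the profile is zero; cannot form a fold.",
          class = "gs_degenerate_input")
  }
  ref_peak_i <- which.max(ref_s)
  loc_max <- local_maxima(par_s)
  if (length(loc_max) == 0L) loc_max <- which.max(par_s)
  par_peak_i <- loc_max[which.min(abs(ref$position[loc_max] - ref$position[ref_peak_i]))]
  offset <- abs(par$position[par_peak_i] - ref$position[ref_peak_i])
  peak_fold <- par_s[par_peak_i] / background
  coincident <- offset <= coincidence_tol
  meets <- if (strict) peak_fold > fold_threshold else peak_fold >= fold_threshold
  out <- tibble(
    aggregate_id = attr(profile, "aggregate_id") %||% NA_integer_,
    partner = partner, peak_fold = peak_fold, peak_offset = offset,
    coincident = coincident, positive = coincident && meets)
  class(out) <- c("coloc_call", class(out))
  out
}

moving_average <- function(x, window = 3) {
  if (window <= 1) return(x)
  k <- rep(1 / window, window)
  y <- stats::filter(x, k, sides = 2)
  y <- as.numeric(y)
  y[is.na(y)] <- x[is.na(y)]   # keep raw values at the edges
  y
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  cand <- i[x[i] >= x[i - 1] & x[i] >= x[i + 1] & (x[i] > x[i - 1] | x[i] > x[i + 1])]
  cand
}

#' Sampling plan for aggregate co-localisation scoring
#'
#' The assessment scheme samples a fixed number of images per replicate and a
#' fixed number of aggregates per compartment per image (default: five
#' cytoplasmic and five nuclear aggregates from five randomly selected images
#' per replicate).
#'
#' @param n_cytoplasmic,n_nuclear aggregates sampled per compartment per image.
#' @param n_images images sampled per replicate.
#' @param seed integer seed; selection is keyed to image identity so it does
#'   not depend on the order in which images are listed.
#' @return an object of class `sampling_plan`.
#' @export
sampling_plan <- function(n_cytoplasmic = 5, n_nuclear = 5, n_images = 5,
                          seed = 1L) {
  if (any(c(n_cytoplasmic, n_nuclear, n_images) < 1)) {
    abort("all sampling counts must be >= 1.", class = "gs_invalid_spec")
  }
  structure(list(n_cytoplasmic = n_cytoplasmic, n_nuclear = n_nuclear,
                 n_images = n_images, seed = as.integer(seed)),
            class = "sampling_plan")
}

#' Sample aggregates across a replicate and score co-localisation
#'
#' Selects `plan$n_images` images (deterministically keyed to image identity
#' and `plan$seed`), samples up to the requested number of aggregates per
#' compartment per image (fewer if unavailable, with a warning), extracts a
#' profile through each and scores it against the partner stain.
#'
#' @param images named list of [micrograph()]s; names are image identifiers.
#' @param aggregates tibble of aggregate records across those images, with an
#'   `image` column naming the source image plus the columns
#'   [extract_profile()] needs (`centroid_row`, `centroid_col`, `orientation`,
#'   `major_axis`, `label`) and `compartment`.
#' @param plan a [sampling_plan()].
#' @param partner partner stain to score.
#' @param reference reference stain (default `"atxn7"`).
#' @param regions optional named list of logical cell-region masks (same
#'   names as `images`), passed to [extract_profile()] so profile background
#'   is read inside the cell.
#' @param ... passed to [score_profile()].
#' @return tibble of coloc calls, one row per sampled aggregate, with
#'   `image` and `compartment` columns.
#' @export
sample_and_score <- function(images, aggregates, plan = sampling_plan(),
                             partner, reference = "atxn7", regions = NULL, ...) {
  if (is.null(names(images)) || any(names(images) == "")) {
    abort("`images` must be a named list (names are image ids).",
          class = "gs_invalid_input")
  }
  ids <- names(images)
  if (length(ids) < plan$n_images) {
    abort(sprintf("replicate has %d images but the plan needs %d.",
                  length(ids), plan$n_images),
          class = "gs_invalid_input")
  }
  if (nrow(aggregates) == 0L) {
    warn("replicate contains no aggregates; returning an empty call list.")
    return(tibble(image = character(0), compartment = character(0),
                  aggregate_id = integer(0), partner = character(0),
                  peak_fold = numeric(0), peak_offset = numeric(0),
                  coincident = logical(0), positive = logical(0)))
  }
  # image selection keyed to identity: rank by a per-id hash, independent of
  # listing order
  key <- vapply(ids, string_hash, integer(1), seed = plan$seed)
  chosen <- ids[order(key, ids)][seq_len(plan$n_images)]
  calls <- list()
  for (id in chosen) {
    agg_i <- filter(aggregates, .data$image == id)
    for (cmp in c("nuclear", "cytoplasmic")) {
      want <- if (cmp == "nuclear") plan$n_nuclear else plan$n_cytoplasmic
      pool <- filter(agg_i, .data$compartment == cmp)
      pool <- arrange(pool, .data$label)
      take <- min(want, nrow(pool))
      if (take < want) {
        warn(sprintf("image '%s' has only %d %s aggregates (wanted %d).",
                     id, nrow(pool), cmp, want))
      }
      if (take == 0L) next
      sel <- with_seed(string_hash(paste(id, cmp), seed = plan$seed),
                       sample.int(nrow(pool), take))
      for (k in sel) {
        prof <- try(extract_profile(images[[id]], pool[k, , drop = FALSE],
                                    region = regions[[id]]),
                    silent = TRUE)
        if (inherits(prof, "try-error")) next
        call <- score_profile(prof, reference = reference, partner = partner, ...)
        call$image <- id
        call$compartment <- cmp
        calls[[length(calls) + 1L]] <- call
      }
    }
  }
  if (length(calls) == 0L) {
    warn("no aggregates could be scored.")
    return(tibble(image = character(0), compartment = character(0),
                  aggregate_id = integer(0), partner = character(0),
                  peak_fold = numeric(0), peak_offset = numeric(0),
                  coincident = logical(0), positive = logical(0)))
  }
  relocate(list_rbind(calls), "image", "compartment")
}

#' Co-localisation fraction per compartment
#'
#' Fraction of scored aggregates called positive, per compartment, with the
#' binomial standard error `sqrt(p(1-p)/n)`.
#'
#' @param calls tibble of coloc calls from [sample_and_score()] (needs
#'   `compartment` and `positive` columns).
#' @return tibble: `compartment`, `n`, `positives`, `fraction`, `se`.
#' @export
coloc_fraction <- function(calls) {
  if (nrow(calls) == 0L) {
    warn("no calls; fractions undefined.")
    return(tibble(compartment = character(0), n = integer(0),
                  positives = integer(0), fraction = numeric(0),
                  se = numeric(0)))
  }
  calls %>%
    group_by(.data$compartment) %>%
    summarise(n = dplyr::n(), positives = sum(.data$positive), .groups = "drop") %>%
    mutate(fraction = .data$positives / .data$n,
           se = sqrt(.data$fraction * (1 - .data$fraction) / .data$n))
}
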