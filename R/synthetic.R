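#' Scene specification for synthetic micrographs
#'
#' Describes a synthetic multi-channel field of cells: how many cells, how
#' bright the diffuse nuclear/cytoplasmic staining is per channel, how many
#' polyQ aggregates and protein speckles to plant, how bright they are relative
#' to their immediate diffuse background, how round they are, the probability
#' that a partner stain is planted on top of an aggregate (co-localisation),
#' and the noise model. The generator realises the scene with planted 2D
#' Gaussian objects and returns the exact ground truth, so downstream
#' segmentation, co-localisation and statistics can be validated against known
#' values.
#'
#' Amplitude folds are defined as peak intensity over the local diffuse
#' background of the compartment the object sits in (peak = fold x diffuse).
#' Noise is Poisson shot noise (photon gain `noise["gain"]`) followed by
#' additive Gaussian read noise (`noise["sd"]`); intensities are then clamped
#' to [0, 65535] and rounded, matching 16-bit microscope output.
#'
#' @param image_shape integer (height, width) in pixels.
#' @param n_cells number of cells (nuclei) to plant.
#' @param nucleus_radius_range semi-axis range of the elliptical nuclei, px.
#' @param cytoplasm_width width of the cytoplasmic annulus around each
#'   nucleus, px.
#' @param aggregates_per_cell named mean counts `c(nuclear=, cytoplasmic=)` of
#'   ATXN7 aggregates per cell and compartment (Poisson).
#' @param aggregate_amplitude_fold peak-over-background fold of aggregates.
#' @param aggregate_sigma_range Gaussian sigma range of aggregates, px.
#' @param speckles_per_cell named mean speckle counts per cell, one entry per
#'   stained channel (e.g. `c(g3bp1 = 0.5, tia1 = 0.5)`).
#' @param speckle_amplitude_fold peak-over-background fold of speckles.
#' @param speckle_sigma_range Gaussian major-axis sigma range of speckles, px.
#' @param speckle_axis_ratio_range minor/major axis ratio range in (0, 1];
#'   controls planted eccentricity.
#' @param granules_per_cell mean count of stress-granule-like G3BP1 puncta per
#'   cell (cytoplasmic).
#' @param granule_partner_prob named probabilities that a planted G3BP1
#'   granule also carries a coinciding partner stain
#'   (e.g. `c(tia1 = 0.8, atxn7 = 0.5)`).
#' @param coloc_prob per-partner-channel, per-compartment probability that an
#'   aggregate carries a coinciding partner-stain peak: a named list like
#'   `list(tia1 = c(nuclear = 0.6, cytoplasmic = 0.8))`.
#' @param coloc_fold_range amplitude fold range (over the partner channel's
#'   local diffuse level) for planted co-localising peaks; kept above the
#'   twofold scoring threshold so planted positives are detectable by
#'   construction.
#' @param diffuse_levels named list, per channel, of diffuse intensities
#'   `c(nuclear =, cytoplasmic =, background =)`.
#' @param noise `c(gain =, sd =)`: Poisson gain and Gaussian read-noise sd.
#' @param seed integer seed; the same spec and seed give bit-identical output.
#'
#' @return an object of class `scene_spec`.
#' @seealso [generate_micrograph()], [scenario_preset()]
#' @export
scene_spec <- function(image_shape = c(256L, 256L),
                       n_cells = 6,
                       nucleus_radius_range = c(12, 16),
                       cytoplasm_width = 12,
                       aggregates_per_cell = c(nuclear = 0, cytoplasmic = 0),
                       aggregate_amplitude_fold = 12,
                       aggregate_sigma_range = c(3, 5),
                       speckles_per_cell = c(g3bp1 = 0, tia1 = 0),
                       speckle_amplitude_fold = 10,
                       speckle_sigma_range = c(1.3, 2),
                       speckle_axis_ratio_range = c(0.7, 1),
                       granules_per_cell = 0,
                       granule_partner_prob = c(tia1 = 0, atxn7 = 0),
                       coloc_prob = list(),
                       coloc_fold_range = c(3, 5),
                       diffuse_levels = list(
                         atxn7 = c(nuclear = 30, cytoplasmic = 15, background = 2),
                         tia1  = c(nuclear = 12, cytoplasmic = 12, background = 2),
                         g3bp1 = c(nuclear = 18, cytoplasmic = 18, background = 2),
                         dna   = c(nuclear = 60, cytoplasmic = 6,  background = 2)
                       ),
                       noise = c(gain = 1, sd = 3.5),
                       seed = 1L) {
  spec <- structure(
    list(image_shape = as.integer(image_shape), n_cells = n_cells,
         nucleus_radius_range = nucleus_radius_range,
         cytoplasm_width = cytoplasm_width,
         aggregates_per_cell = aggregates_per_cell,
         aggregate_amplitude_fold = aggregate_amplitude_fold,
         aggregate_sigma_range = aggregate_sigma_range,
         speckles_per_cell = speckles_per_cell,
         speckle_amplitude_fold = speckle_amplitude_fold,
         speckle_sigma_range = speckle_sigma_range,
         speckle_axis_ratio_range = speckle_axis_ratio_range,
         granules_per_cell = granules_per_cell,
         granule_partner_prob = granule_partner_prob,
         coloc_prob = coloc_prob, coloc_fold_range = coloc_fold_range,
         diffuse_levels = diffuse_levels, noise = noise,
         seed = as.integer(seed)),
    class = "scene_spec"
  )
  validate_scene_spec(spec)
}

#' Validate a scene specification
#'
#' Checks every invariant of a [scene_spec()] and fails naming the offending
#' field.
#' @param spec a `scene_spec`.
#' @return the spec, invisibly usable in a pipe.
#' @export
validate_scene_spec <- function(spec) {
  if (!inherits(spec, "scene_spec")) {
    abort("`spec` must be a scene_spec object.", class = "gs_invalid_spec")
  }
  if (length(spec$image_shape) != 2L || any(spec$image_shape < 32L)) {
    abort("`image_shape` must be two integers >= 32.", class = "gs_invalid_spec")
  }
  stopifnot_scalar_number(spec$n_cells, "n_cells", lower = 0)
  rng <- spec$nucleus_radius_range
  if (length(rng) != 2L || any(rng <= 0) || rng[1] > rng[2]) {
    abort("`nucleus_radius_range` must be an increasing positive pair.",
          class = "gs_invalid_spec")
  }
  stopifnot_scalar_number(spec$cytoplasm_width, "cytoplasm_width", lower = 1)
  for (cmp in names(spec$aggregates_per_cell)) {
    stopifnot_scalar_number(spec$aggregates_per_cell[[cmp]],
                            paste0("aggregates_per_cell[", cmp, "]"), lower = 0)
  }
  stopifnot_scalar_number(spec$aggregate_amplitude_fold,
                          "aggregate_amplitude_fold", lower = 0, strict_lower = TRUE)
  for (ch in names(spec$speckles_per_cell)) {
    stopifnot_scalar_number(spec$speckles_per_cell[[ch]],
                            paste0("speckles_per_cell[", ch, "]"), lower = 0)
  }
  stopifnot_scalar_number(spec$speckle_amplitude_fold, "speckle_amplitude_fold",
                          lower = 0, strict_lower = TRUE)
  arr <- spec$speckle_axis_ratio_range
  if (length(arr) != 2L || any(arr <= 0) || any(arr > 1) || arr[1] > arr[2]) {
    abort("`speckle_axis_ratio_range` must lie in (0, 1] and be increasing.",
          class = "gs_invalid_spec")
  }
  stopifnot_scalar_number(spec$granules_per_cell, "granules_per_cell", lower = 0)
  for (ch in names(spec$granule_partner_prob)) {
    stopifnot_scalar_number(spec$granule_partner_prob[[ch]],
                            paste0("granule_partner_prob[", ch, "]"),
                            lower = 0, upper = 1)
  }
  for (ch in names(spec$coloc_prob)) {
    p <- spec$coloc_prob[[ch]]
    for (cmp in names(p)) {
      stopifnot_scalar_number(p[[cmp]],
                              paste0("coloc_prob[", ch, "][", cmp, "]"),
                              lower = 0, upper = 1)
    }
    if (!ch %in% names(spec$diffuse_levels)) {
      abort(sprintf("coloc_prob names a channel '%s' absent from diffuse_levels.", ch),
            class = "gs_invalid_spec")
    }
  }
  if (spec$coloc_fold_range[1] > spec$coloc_fold_range[2] ||
      any(spec$coloc_fold_range <= 0)) {
    abort("`coloc_fold_range` must be an increasing positive pair.",
          class = "gs_invalid_spec")
  }
  for (ch in names(spec$diffuse_levels)) {
    lv <- spec$diffuse_levels[[ch]]
    if (!all(c("nuclear", "cytoplasmic", "background") %in% names(lv)) ||
        any(lv < 0)) {
      abort(sprintf("diffuse_levels[%s] needs non-negative nuclear/cytoplasmic/background entries.", ch),
            class = "gs_invalid_spec")
    }
  }
  if (!all(c("gain", "sd") %in% names(spec$noise)) ||
      spec$noise[["gain"]] <= 0 || spec$noise[["sd"]] < 0) {
    abort("`noise` must provide gain > 0 and sd >= 0.", class = "gs_invalid_spec")
  }
  stopifnot_scalar_number(spec$seed, "seed")
  invisible(spec)
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec> %dx%d px, %g cells, channels: %s (seed %d)\n",
              x$image_shape[1], x$image_shape[2], x$n_cells,
              paste(names(x$diffuse_levels), collapse = ", "), x$seed))
  invisible(x)
}

# Additive anisotropic 2D Gaussian painted into a local window of `img`.
paint_gaussian <- function(img, row, col, amplitude, sigma_a, sigma_b, theta) {
  ext <- ceiling(4 * sigma_a)
  nr <- nrow(img); nc <- ncol(img)
  r0 <- max(1L, floor(row - ext)); r1 <- min(nr, ceiling(row + ext))
  c0 <- max(1L, floor(col - ext)); c1 <- min(nc, ceiling(col + ext))
  rr <- r0:r1; cc <- c0:c1
  dr <- outer(rr - row, rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - col)
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  img[rr, cc] <- img[rr, cc] +
    amplitude * exp(-(u^2 / (2 * sigma_a^2) + v^2 / (2 * sigma_b^2)))
  img
}

# Pixels of an axis-aligned filled ellipse, clipped to the image.
ellipse_pixels <- function(shape, row, col, ra, rc) {
  r0 <- max(1L, floor(row - ra)); r1 <- min(shape[1], ceiling(row + ra))
  c0 <- max(1L, floor(col - rc)); c1 <- min(shape[2], ceiling(col + rc))
  if (r0 > r1 || c0 > c1) return(cbind(integer(0), integer(0)))
  rr <- r0:r1; cc <- c0:c1
  g <- expand.grid(row = rr, col = cc)
  keep <- ((g$row - row) / ra)^2 + ((g$col - col) / rc)^2 <= 1
  as.matrix(g[keep, , drop = FALSE])
}

# Sample up to n positions from a pixel pool with a minimum pairwise distance.
sample_positions <- function(pool, n, min_dist = 6) {
  if (n <= 0L || nrow(pool) == 0L) return(pool[integer(0), , drop = FALSE])
  chosen <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(chosen) < n && tries < 50L * n) {
    tries <- tries + 1L
    cand <- pool[sample.int(nrow(pool), 1L), , drop = FALSE]
    if (nrow(chosen) == 0L ||
        min(sqrt((chosen[, 1] - cand[1, 1])^2 + (chosen[, 2] - cand[1, 2])^2)) >= min_dist) {
      chosen <- rbind(chosen, cand)
    }
  }
  chosen
}

#' Generate one synthetic multi-channel micrograph with ground truth
#'
#' Realises a [scene_spec()]: plants elliptical nuclei (bright in the DNA
#' channel), a cytoplasmic annulus around each nucleus, per-compartment diffuse
#' staining, Gaussian-profile aggregates and speckles, co-localising partner
#' peaks, and Poisson + Gaussian noise. Deterministic given `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @return a list with elements `image` (a [micrograph()]) and `truth`
#'   (a tibble with one row per planted object: `id`, `kind`
#'   (nucleus/aggregate/speckle), `channel`, `compartment`, `cell`, `row`,
#'   `col`, `sigma_major`, `sigma_minor`, `theta`, `amplitude_fold`,
#'   `coloc_partners` as a comma-separated string).
#' @export
generate_micrograph <- function(spec) {
  validate_scene_spec(spec)
  with_seed(spec$seed, generate_micrograph_impl(spec))
}

generate_micrograph_impl <- function(spec, condition = NA_character_,
                                     replicate = NA_integer_,
                                     timepoint = NA_real_) {
  shape <- spec$image_shape
  channels <- names(spec$diffuse_levels)
  n_cells <- as.integer(round(spec$n_cells))

  nucleus_id <- matrix(0L, shape[1], shape[2])
  cyto_id <- matrix(0L, shape[1], shape[2])
  rmax <- spec$nucleus_radius_range[2]
  margin <- rmax + 3

  truth <- list()
  oid <- 0L
  new_id <- function() {
    oid <<- oid + 1L
    oid
  }
  add_truth <- function(kind, channel, compartment, cell, row, col,
                        sa, sb, theta, fold, partners = character(0)) {
    truth[[length(truth) + 1L]] <<- list(
      id = new_id(), kind = kind, channel = channel, compartment = compartment,
      cell = as.integer(cell), row = row, col = col, sigma_major = sa,
      sigma_minor = sb, theta = theta, amplitude_fold = fold,
      coloc_partners = paste(partners, collapse = ","))
  }

  # -- nuclei ----------------------------------------------------------------
  centres <- matrix(numeric(0), 0, 2)
  radii <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n_cells)) {
    ra <- runif(1, spec$nucleus_radius_range[1], spec$nucleus_radius_range[2])
    rc <- runif(1, spec$nucleus_radius_range[1], spec$nucleus_radius_range[2])
    placed <- FALSE
    for (try in 1:4000) {
      r <- runif(1, margin, shape[1] - margin)
      c <- runif(1, margin, shape[2] - margin)
      sep <- 2 * rmax + 5
      if (nrow(centres) == 0L ||
          min(sqrt((centres[, 1] - r)^2 + (centres[, 2] - c)^2)) >= sep) {
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      # dense field: accept possibly touching nuclei rather than dropping cells
      r <- runif(1, margin, shape[1] - margin)
      c <- runif(1, margin, shape[2] - margin)
    }
    centres <- rbind(centres, c(r, c))
    radii <- rbind(radii, c(ra, rc))
    px <- ellipse_pixels(shape, r, c, ra, rc)
    nucleus_id[px] <- i
    add_truth("nucleus", "dna", "nuclear", i, r, c, max(ra, rc), min(ra, rc),
              if (ra >= rc) 0 else pi / 2, 1)
  }
  for (i in seq_len(n_cells)) {
    px <- ellipse_pixels(shape, centres[i, 1], centres[i, 2],
                         radii[i, 1] + spec$cytoplasm_width,
                         radii[i, 2] + spec$cytoplasm_width)
    free <- nucleus_id[px] == 0L & cyto_id[px] == 0L
    cyto_id[px[free, , drop = FALSE]] <- i
  }

  # diffuse background per channel
  clean <- lapply(channels, function(ch) {
    lv <- spec$diffuse_levels[[ch]]
    img <- matrix(lv[["background"]], shape[1], shape[2])
    img[cyto_id > 0L] <- lv[["cytoplasmic"]]
    img[nucleus_id > 0L] <- lv[["nuclear"]]
    img
  })
  names(clean) <- channels
  level_of <- function(ch, compartment) {
    spec$diffuse_levels[[ch]][[if (compartment == "nuclear") "nuclear" else "cytoplasmic"]]
  }

  # eligible positions stay clear of the border so profiles and shape metrics
  # are well-defined for planted objects
  eligible <- function(px) {
    px[px[, 1] > 5 & px[, 1] <= shape[1] - 5 &
       px[, 2] > 5 & px[, 2] <= shape[2] - 5, , drop = FALSE]
  }
  nuc_pool <- lapply(seq_len(n_cells), function(i) {
    eligible(which(nucleus_id == i, arr.ind = TRUE))
  })
  cyt_pool <- lapply(seq_len(n_cells), function(i) {
    eligible(which(cyto_id == i, arr.ind = TRUE))
  })

  partner_channels <- names(spec$coloc_prob)

  # -- aggregates (ATXN7 channel) -------------------------------------------
  if ("atxn7" %in% channels) {
    for (i in seq_len(n_cells)) {
      for (cmp in c("nuclear", "cytoplasmic")) {
        mean_n <- spec$aggregates_per_cell[[cmp]] %||% 0
        if (is.null(mean_n) || mean_n <= 0) next
        n_agg <- rpois(1, mean_n)
        pool <- if (cmp == "nuclear") nuc_pool[[i]] else cyt_pool[[i]]
        pos <- sample_positions(pool, n_agg, min_dist = 12)
        for (k in seq_len(nrow(pos))) {
          sa <- runif(1, spec$aggregate_sigma_range[1], spec$aggregate_sigma_range[2])
          ratio <- runif(1, 0.8, 1)
          theta <- runif(1, 0, pi)
          fold <- spec$aggregate_amplitude_fold
          bg <- level_of("atxn7", cmp)
          clean[["atxn7"]] <- paint_gaussian(clean[["atxn7"]], pos[k, 1], pos[k, 2],
                                             (fold - 1) * bg, sa, sa * ratio, theta)
          partners <- character(0)
          for (pch in partner_channels) {
            p <- spec$coloc_prob[[pch]][[cmp]] %||% 0
            if (runif(1) < p) {
              pfold <- runif(1, spec$coloc_fold_range[1], spec$coloc_fold_range[2])
              pbg <- level_of(pch, cmp)
              # sequestered partner stain concentrates in the aggregate core
              clean[[pch]] <- paint_gaussian(clean[[pch]], pos[k, 1], pos[k, 2],
                                             (pfold - 1) * pbg, sa * 0.6,
                                             sa * 0.6 * ratio, theta)
              partners <- c(partners, pch)
            }
          }
          add_truth("aggregate", "atxn7", cmp, i, pos[k, 1], pos[k, 2],
                    sa, sa * ratio, theta, fold, partners)
        }
      }
    }
  }

  # -- speckles per channel (cytoplasmic) -----------------------------------
  for (ch in names(spec$speckles_per_cell)) {
    mean_n <- spec$speckles_per_cell[[ch]]
    if (mean_n <= 0 || !ch %in% channels) next
    for (i in seq_len(n_cells)) {
      n_spk <- rpois(1, mean_n)
      pos <- sample_positions(cyt_pool[[i]], n_spk, min_dist = 7)
      for (k in seq_len(nrow(pos))) {
        sa <- runif(1, spec$speckle_sigma_range[1], spec$speckle_sigma_range[2])
        ratio <- runif(1, spec$speckle_axis_ratio_range[1],
                       spec$speckle_axis_ratio_range[2])
        theta <- runif(1, 0, pi)
        bg <- level_of(ch, "cytoplasmic")
        clean[[ch]] <- paint_gaussian(clean[[ch]], pos[k, 1], pos[k, 2],
                                      (spec$speckle_amplitude_fold - 1) * bg,
                                      sa, sa * ratio, theta)
        add_truth("speckle", ch, "cytoplasmic", i, pos[k, 1], pos[k, 2],
                  sa, sa * ratio, theta, spec$speckle_amplitude_fold)
      }
    }
  }

  # -- stress-granule-like G3BP1 puncta with optional partner stains --------
  if (spec$granules_per_cell > 0 && "g3bp1" %in% channels) {
    for (i in seq_len(n_cells)) {
      n_gr <- rpois(1, spec$granules_per_cell)
      pos <- sample_positions(cyt_pool[[i]], n_gr, min_dist = 7)
      for (k in seq_len(nrow(pos))) {
        sa <- runif(1, spec$speckle_sigma_range[1], spec$speckle_sigma_range[2])
        ratio <- runif(1, spec$speckle_axis_ratio_range[1],
                       spec$speckle_axis_ratio_range[2])
        theta <- runif(1, 0, pi)
        bg <- level_of("g3bp1", "cytoplasmic")
        clean[["g3bp1"]] <- paint_gaussian(clean[["g3bp1"]], pos[k, 1], pos[k, 2],
                                           (spec$speckle_amplitude_fold - 1) * bg,
                                           sa, sa * ratio, theta)
        partners <- character(0)
        for (pch in names(spec$granule_partner_prob)) {
          if (!pch %in% channels) next
          if (runif(1) < spec$granule_partner_prob[[pch]]) {
            pbg <- level_of(pch, "cytoplasmic")
            clean[[pch]] <- paint_gaussian(clean[[pch]], pos[k, 1], pos[k, 2],
                                           (spec$speckle_amplitude_fold - 1) * pbg,
                                           sa, sa * ratio, theta)
            partners <- c(partners, pch)
          }
        }
        add_truth("speckle", "g3bp1", "cytoplasmic", i, pos[k, 1], pos[k, 2],
                  sa, sa * ratio, theta, spec$speckle_amplitude_fold, partners)
      }
    }
  }

  # -- noise and quantisation -----------------------------------------------
  gain <- spec$noise[["gain"]]
  sdr <- spec$noise[["sd"]]
  noisy <- lapply(clean, function(img) {
    n <- length(img)
    out <- rpois(n, lambda = pmax(img, 0) * gain) / gain
    if (sdr > 0) out <- out + rnorm(n, 0, sdr)
    m <- matrix(pmin(pmax(round(out), 0), 65535), nrow(img), ncol(img))
    m
  })

  truth_tbl <- if (length(truth)) {
    tibble(
      id = vapply(truth, function(x) x$id, integer(1)),
      kind = vapply(truth, function(x) x$kind, character(1)),
      channel = vapply(truth, function(x) x$channel, character(1)),
      compartment = vapply(truth, function(x) x$compartment, character(1)),
      cell = vapply(truth, function(x) x$cell, integer(1)),
      row = vapply(truth, function(x) x$row, numeric(1)),
      col = vapply(truth, function(x) x$col, numeric(1)),
      sigma_major = vapply(truth, function(x) x$sigma_major, numeric(1)),
      sigma_minor = vapply(truth, function(x) x$sigma_minor, numeric(1)),
      theta = vapply(truth, function(x) x$theta, numeric(1)),
      amplitude_fold = vapply(truth, function(x) x$amplitude_fold, numeric(1)),
      coloc_partners = vapply(truth, function(x) x$coloc_partners, character(1)))
  } else {
    tibble(
      id = integer(0), kind = character(0), channel = character(0),
      compartment = character(0), cell = integer(0), row = numeric(0),
      col = numeric(0), sigma_major = numeric(0), sigma_minor = numeric(0),
      theta = numeric(0), amplitude_fold = numeric(0), coloc_partners = character(0))
  }

  list(
    image = micrograph(noisy, condition = condition, replicate = replicate,
                       timepoint = timepoint),
    truth = truth_tbl
  )
}

#' Generate an independent-frame stress-granule recovery series
#'
#' Emulates a fixed-cell recovery time course: separate fields of cells are
#' imaged at each recovery timepoint, and the expected planted speckle/granule
#' count at time t is the t = 0 mean thinned by `2^(-t / decay_half_life)`.
#' Frames are independent (different cells at each timepoint, as in fixed-cell
#' imaging), each labelled with its timepoint.
#'
#' @param spec base [scene_spec()] describing the t = 0 field.
#' @param timepoints non-empty vector of recovery times in minutes (>= 0).
#' @param decay_half_life disassembly half-life in minutes; `Inf` means no
#'   decay.
#' @return a list with one element per timepoint, each a
#'   `list(image =, truth =)` as from [generate_micrograph()].
#' @export
generate_recovery_series <- function(spec, timepoints, decay_half_life) {
  validate_scene_spec(spec)
  if (length(timepoints) == 0L) {
    abort("`timepoints` must be a non-empty vector of minutes.",
          class = "gs_invalid_spec")
  }
  if (any(timepoints < 0)) {
    abort("`timepoints` must be non-negative.", class = "gs_invalid_spec")
  }
  if (length(decay_half_life) != 1L || is.na(decay_half_life) ||
      decay_half_life <= 0) {
    abort("`decay_half_life` must be a single positive number (Inf = no decay).",
          class = "gs_invalid_spec")
  }
  lapply(seq_along(timepoints), function(i) {
    t <- timepoints[[i]]
    factor <- if (is.finite(decay_half_life)) 2^(-t / decay_half_life) else 1
    spec_t <- spec
    spec_t$speckles_per_cell <- spec$speckles_per_cell * factor
    spec_t$granules_per_cell <- spec$granules_per_cell * factor
    spec_t$seed <- as.integer((spec$seed + i * 10007L) %% .Machine$integer.max)
    with_seed(spec_t$seed,
              generate_micrograph_impl(spec_t, timepoint = t))
  })
}

#' Preset scenes for the study's experimental conditions
#'
#' Returns a [scene_spec()] encoding one of four condition regimes:
#' \describe{
#'   \item{unstressed_control}{non-induced cells: weak diffuse staining, rare
#'     G3BP1/TIA1 speckles, no aggregates, no co-localisation.}
#'   \item{q65_speckling}{cells expressing polyQ-expanded ATXN7: nuclear and
#'     cytoplasmic aggregates with TIA1 co-localisation (0.8 cytoplasmic /
#'     0.6 nuclear) and none for G3BP1; G3BP1 speckle density six times the
#'     control and amplitude sized for a roughly fourfold texture-variance
#'     contrast.}
#'   \item{arsenite_stressed}{oxidative stress: dense cytoplasmic G3BP1
#'     granules, most co-stained for TIA1 (double-positive stress granules)
#'     and about half carrying ATXN7.}
#'   \item{recovery}{the arsenite field used as the t = 0 frame of a
#'     disassembly series (see [generate_recovery_series()]).}
#' }
#'
#' @param name one of `"unstressed_control"`, `"q65_speckling"`,
#'   `"arsenite_stressed"`, `"recovery"`.
#' @param seed integer seed stored in the returned spec.
#' @return a [scene_spec()].
#' @export
scenario_preset <- function(name, seed = 1L) {
  presets <- c("unstressed_control", "q65_speckling", "arsenite_stressed",
               "recovery")
  if (length(name) != 1L || !name %in% presets) {
    abort(sprintf("unknown preset '%s'; valid presets: %s.",
                  paste(name, collapse = ","), paste(presets, collapse = ", ")),
          class = "gs_unknown_preset")
  }
  base <- scene_spec(seed = seed)
  switch(
    name,
    unstressed_control = {
      base$speckles_per_cell <- c(g3bp1 = 0.75, tia1 = 0.5)
      base$coloc_prob <- list(tia1 = c(nuclear = 0, cytoplasmic = 0),
                              g3bp1 = c(nuclear = 0, cytoplasmic = 0))
      base
    },
    q65_speckling = {
      base$speckles_per_cell <- c(g3bp1 = 4.5, tia1 = 0.5)
      base$aggregates_per_cell <- c(nuclear = 2, cytoplasmic = 2)
      base$coloc_prob <- list(tia1 = c(nuclear = 0.6, cytoplasmic = 0.8),
                              g3bp1 = c(nuclear = 0, cytoplasmic = 0))
      base
    },
    arsenite_stressed = ,
    recovery = {
      base$speckles_per_cell <- c(g3bp1 = 0, tia1 = 0.5)
      base$granules_per_cell <- 6
      base$granule_partner_prob <- c(tia1 = 0.8, atxn7 = 0.5)
      base$aggregates_per_cell <- c(nuclear = 2, cytoplasmic = 2)
      base$coloc_prob <- list(tia1 = c(nuclear = 0.6, cytoplasmic = 0.8),
                              g3bp1 = c(nuclear = 0, cytoplasmic = 0))
      base
    }
  )
}
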