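#' Run configuration for the end-to-end pipeline
#'
#' Bundles every stage's parameters into one validated object. A run either
#' simulates its images (`simulate`: named condition -> preset name or
#' [scene_spec()]) or reads them from a [run_manifest()]. Unknown keys are
#' rejected by name, so configs cannot silently carry typos.
#'
#' @param simulate list describing simulated acquisition:
#'   `conditions` (named list: condition label -> preset name or
#'   [scene_spec()]), `n_replicates`, `images_per_replicate`, and optionally
#'   `recovery` (list with `timepoints` (minutes) and `half_life` to turn
#'   each condition into an independent-frame recovery series).
#' @param manifest optional [run_manifest()] or path to one (alternative to
#'   `simulate`).
#' @param control_condition fold-change control; defaults to the first
#'   simulated condition.
#' @param reference_condition condition whose images calibrate the
#'   per-replicate minimum threshold (defaults to the control).
#' @param segmentation list: `speckle` ([speckle_params()] arguments),
#'   `speckle_channels`, `nucleus_min_area`, `aggregate_min_area`.
#' @param coloc list: `partner`, `reference`, `fold_threshold`,
#'   `coincidence_tol`.
#' @param sampling [sampling_plan()] arguments.
#' @param stats list: `test` (`"welch"` or `"wilcoxon"`).
#' @param save_images write simulated images as TIFFs into the run directory.
#' @param seed global seed; every stochastic step derives its stream from it.
#' @return an object of class `run_config`.
#' @export
run_config <- function(simulate = list(conditions = list(
                         control = "unstressed_control",
                         q65 = "q65_speckling"),
                         n_replicates = 3, images_per_replicate = 4,
                         recovery = NULL),
                       manifest = NULL,
                       control_condition = NULL,
                       reference_condition = NULL,
                       segmentation = list(),
                       coloc = list(),
                       sampling = list(),
                       stats = list(),
                       save_images = FALSE,
                       seed = 1L) {
  seg_defaults <- list(speckle = list(), speckle_channels = c("g3bp1", "tia1"),
                       nucleus_min_area = 60, aggregate_min_area = 20)
  coloc_defaults <- list(partner = "tia1", reference = "atxn7",
                         fold_threshold = 2, coincidence_tol = 3)
  stats_defaults <- list(test = "welch")
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      abort(sprintf("unknown key(s) in %s: %s.", where,
                    paste(bad, collapse = ", ")),
            class = "gs_invalid_config")
    }
  }
  if (!is.null(simulate)) {
    check_keys(simulate, c("conditions", "n_replicates", "images_per_replicate",
                           "recovery"), "simulate")
  }
  check_keys(segmentation, names(seg_defaults), "segmentation")
  check_keys(coloc, names(coloc_defaults), "coloc")
  check_keys(sampling, c("n_cytoplasmic", "n_nuclear", "n_images", "seed"),
             "sampling")
  check_keys(stats, names(stats_defaults), "stats")
  segmentation <- utils::modifyList(seg_defaults, segmentation)
  coloc <- utils::modifyList(coloc_defaults, coloc)
  stats <- utils::modifyList(stats_defaults, stats)
  if (is.null(manifest) && is.null(simulate)) {
    abort("either `simulate` or `manifest` must be given.",
          class = "gs_invalid_config")
  }
  if (!is.null(simulate)) {
    if (is.null(control_condition)) {
      control_condition <- names(simulate$conditions)[1]
    }
    if (!control_condition %in% names(simulate$conditions)) {
      abort(sprintf("control condition '%s' is not among the simulated conditions.",
                    control_condition),
            class = "gs_invalid_config")
    }
  }
  structure(list(simulate = simulate, manifest = manifest,
                 control_condition = control_condition,
                 reference_condition = reference_condition %||% control_condition,
                 segmentation = segmentation, coloc = coloc,
                 sampling = sampling, stats = stats,
                 save_images = isTRUE(save_images), seed = as.integer(seed)),
            class = "run_config")
}

resolve_spec <- function(x, seed) {
  sp <- if (inherits(x, "scene_spec")) x else scenario_preset(x, seed = seed)
  sp$seed <- as.integer(seed)
  sp
}

#' Run the full pipeline: simulate/load, segment, co-localise, measure,
#' summarise
#'
#' Executes every stage in order and writes the run directory: per-image
#' measurements (`images.csv`), per-object records (`objects.csv`),
#' co-localisation calls and fractions (`coloc_calls.csv`,
#' `coloc_fractions.csv`), condition summaries (`summary.csv`), a recovery
#' curve (`recovery.csv`) when timepoints are present, a config echo
#' (`run_config.yaml`) and a log (`report.txt`). Every CSV carries the config
#' hash and seed, and re-running with an identical config and seed reproduces
#' identical tables.
#'
#' @param config a [run_config()].
#' @param out_dir run directory (created if missing).
#' @return an object of class `pipeline_run`: list with the output paths and
#'   the main result tibbles.
#' @export
run_pipeline <- function(config, out_dir = tempfile("gsrun")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(unclass(config))
  log_lines <- character(0)
  log_msg <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  # ---- stage: acquire -------------------------------------------------------
  images <- list()   # named list of micrographs
  truths <- list()
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    n_rep <- sim$n_replicates %||% 3
    n_img <- sim$images_per_replicate %||% 4
    for (cond in names(sim$conditions)) {
      for (rep in seq_len(n_rep)) {
        if (!is.null(sim$recovery)) {
          tps <- sim$recovery$timepoints
          for (img in seq_len(n_img)) {
            base_seed <- string_hash(sprintf("%s/r%d/i%d", cond, rep, img),
                                     seed = config$seed)
            sp <- resolve_spec(sim$conditions[[cond]], base_seed)
            series <- generate_recovery_series(sp, tps, sim$recovery$half_life)
            for (k in seq_along(tps)) {
              id <- sprintf("%s_r%d_t%03d_i%02d", cond, rep, tps[k], img)
              fr <- series[[k]]
              fr$image$condition <- cond
              fr$image$replicate <- rep
              images[[id]] <- fr$image
              truths[[id]] <- fr$truth
              log_msg("simulate: %s (%d objects planted)", id, nrow(fr$truth))
            }
          }
        } else {
          for (img in seq_len(n_img)) {
            sd_i <- string_hash(sprintf("%s/r%d/i%d", cond, rep, img),
                                seed = config$seed)
            sp <- resolve_spec(sim$conditions[[cond]], sd_i)
            out <- generate_micrograph(sp)
            out$image$condition <- cond
            out$image$replicate <- rep
            id <- sprintf("%s_r%d_i%02d", cond, rep, img)
            images[[id]] <- out$image
            truths[[id]] <- out$truth
            log_msg("simulate: %s (%d objects planted)", id, nrow(out$truth))
          }
        }
      }
    }
    if (config$save_images) {
      img_dir <- file.path(out_dir, "images")
      dir.create(img_dir, showWarnings = FALSE)
      for (id in names(images)) {
        write_micrograph(images[[id]], file.path(img_dir, paste0(id, ".tif")))
      }
    }
  } else {
    man <- config$manifest
    if (is.character(man)) man <- read_run_manifest(man)
    if (!inherits(man, "run_manifest")) {
      abort("`manifest` must be a run_manifest or a path to one.",
            class = "gs_invalid_config")
    }
    if (is.null(config$control_condition)) {
      config$control_condition <- man$control_condition
    }
    for (i in seq_len(nrow(man$entries))) {
      e <- man$entries[i, ]
      id <- sprintf("%s_r%d_i%02d", e$condition, e$replicate, i)
      images[[id]] <- read_micrograph(e$path, man$channel_map,
                                      condition = e$condition,
                                      replicate = e$replicate,
                                      timepoint = e$timepoint)
      log_msg("load: %s <- %s", id, e$path)
    }
  }

  meta <- list_rbind(imap(images, function(im, id) {
    tibble(image = id, condition = im$condition, replicate = im$replicate,
           timepoint = im$timepoint)
  }))

  # ---- stage: segment -------------------------------------------------------
  seg <- config$segmentation
  sp_par <- do.call(speckle_params, seg$speckle)
  nuclei <- list()
  obj_records <- list()
  img_rows <- list()
  agg_records <- list()
  speckle_masks <- list()

  # per-replicate minimum thresholds from the reference condition
  floors <- list()
  ref_cond <- config$reference_condition %||% config$control_condition
  for (rep in unique(meta$replicate)) {
    ids <- meta$image[meta$condition == ref_cond & meta$replicate == rep]
    if (!is.null(config$simulate) && !is.null(config$simulate$recovery)) {
      # calibrate on the t = 0 frames of the reference condition
      ids <- ids[vapply(ids, function(id) isTRUE(images[[id]]$timepoint == 0),
                        logical(1))]
    }
    floors[[as.character(rep)]] <- lapply(
      setNames(seg$speckle_channels, seg$speckle_channels),
      function(ch) {
        if (length(ids) == 0L) return(NULL)
        tryCatch(
          calibrate_min_threshold(lapply(ids, function(id) images[[id]]),
                                  stain = ch),
          error = function(e) NULL)
      })
  }

  for (id in names(images)) {
    im <- images[[id]]
    nuc <- detect_nuclei(get_channel(im, "dna"), min_area = seg$nucleus_min_area)
    nuclei[[id]] <- nuc
    n_nuc <- n_objects(nuc)
    if (n_nuc == 0L) log_msg("segment: %s excluded from per-cell measures (0 nuclei)", id)
    row <- tibble(image = id, n_nuclei = n_nuc)
    flo <- floors[[as.character(im$replicate)]] %||% list()
    for (ch in seg$speckle_channels) {
      if (!ch %in% channel_names(im)) next
      det <- tryCatch(
        detect_speckles(get_channel(im, ch), sp_par,
                        threshold_floor = flo[[ch]], stain = ch),
        error = function(e) NULL)
      n_spk <- if (is.null(det)) 0L else n_objects(det$mask)
      row[[paste0("n_speckles_", ch)]] <- n_spk
      speckle_masks[[id]][[ch]] <- if (is.null(det)) NULL else det$mask
      if (!is.null(det) && nrow(det$records)) {
        rec <- det$records
        rec$image <- id
        rec$kind <- "speckle"
        rec$stain <- ch
        obj_records[[length(obj_records) + 1L]] <- rec
      }
      log_msg("segment: %s %s -> %d speckles", id, ch, n_spk)
    }
    if ("atxn7" %in% channel_names(im)) {
      da <- detect_aggregates(get_channel(im, "atxn7"), nuc,
                              min_area = seg$aggregate_min_area)
      row$n_aggregates <- nrow(da$records)
      row$n_aggregates_nuclear <- sum(da$records$compartment == "nuclear")
      row$n_aggregates_cytoplasmic <- sum(da$records$compartment == "cytoplasmic")
      if (nrow(da$records)) {
        rec <- da$records
        rec$image <- id
        rec$kind <- "aggregate"
        rec$stain <- "atxn7"
        agg_records[[length(agg_records) + 1L]] <- rec
        obj_records[[length(obj_records) + 1L]] <- rec
      }
      log_msg("segment: %s atxn7 -> %d aggregates", id, row$n_aggregates)
    }
    # double positives
    if (!is.null(speckle_masks[[id]][["g3bp1"]]) &&
        !is.null(speckle_masks[[id]][["tia1"]])) {
      row$n_stress_granules <- call_double_positive(
        speckle_masks[[id]][["g3bp1"]], speckle_masks[[id]][["tia1"]])$n
    }
    # per-image measures on the G3BP1 channel restricted to the cell area
    if ("g3bp1" %in% channel_names(im) && n_nuc > 0) {
      region <- cell_region_mask(nuc, width = 12)
      g <- get_channel(im, "g3bp1")
      row$texture_variance_g3bp1 <- texture_variance(g, region)
      row$intensity_per_nucleus_g3bp1 <- sum(g) / n_nuc
    }
    img_rows[[id]] <- row
  }
  img_tbl <- left_join(meta, list_rbind(img_rows), by = "image")

  # ---- stage: co-localise ---------------------------------------------------
  coloc_calls <- tibble()
  coloc_frac <- tibble()
  agg_tbl <- if (length(agg_records)) list_rbind(agg_records) else tibble()
  if (nrow(agg_tbl) > 0 &&
      config$coloc$partner %in% unique(unlist(lapply(images, channel_names)))) {
    plan_args <- config$sampling
    for (cond in unique(meta$condition)) {
      for (rep in unique(meta$replicate[meta$condition == cond])) {
        ids <- meta$image[meta$condition == cond & meta$replicate == rep]
        aggs <- filter(agg_tbl, .data$image %in% ids)
        if (nrow(aggs) == 0L) next
        plan_args$n_images <- min(plan_args$n_images %||% 5, length(ids))
        plan_args$seed <- plan_args$seed %||% config$seed
        plan <- do.call(sampling_plan, plan_args)
        regions <- lapply(setNames(ids, ids), function(id) {
          cell_region_mask(nuclei[[id]], width = 12)
        })
        calls <- withCallingHandlers(
          sample_and_score(images[ids], aggs, plan,
                           partner = config$coloc$partner,
                           reference = config$coloc$reference,
                           regions = regions,
                           fold_threshold = config$coloc$fold_threshold,
                           coincidence_tol = config$coloc$coincidence_tol),
          warning = function(w) {
            log_msg("coloc: %s", conditionMessage(w))
            invokeRestart("muffleWarning")
          })
        if (nrow(calls)) {
          calls$condition <- cond
          calls$replicate <- rep
          coloc_calls <- bind_rows(coloc_calls, calls)
        }
      }
    }
    if (nrow(coloc_calls)) {
      coloc_frac <- coloc_calls %>%
        group_by(.data$condition, .data$compartment) %>%
        summarise(n = dplyr::n(), positives = sum(.data$positive),
                  .groups = "drop") %>%
        mutate(fraction = .data$positives / .data$n,
               se = sqrt(.data$fraction * (1 - .data$fraction) / .data$n))
    }
  }

  # ---- stage: quantify ------------------------------------------------------
  summaries <- list()
  ctrl <- config$control_condition
  multi_cond <- length(unique(img_tbl$condition)) > 1 && !is.null(ctrl) &&
    ctrl %in% img_tbl$condition
  if (multi_cond) {
    count_cols <- intersect(
      c("n_speckles_g3bp1", "n_speckles_tia1", "n_stress_granules",
        "n_aggregates"), names(img_tbl))
    for (cl in count_cols) {
      summaries[[cl]] <- withCallingHandlers(
        granule_counts(img_tbl, cl, control = ctrl, test = config$stats$test),
        warning = function(w) {
          log_msg("quantify: %s", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
    }
    for (cl in intersect(c("texture_variance_g3bp1",
                           "intensity_per_nucleus_g3bp1"), names(img_tbl))) {
      summaries[[cl]] <- fold_change(img_tbl, cl, control = ctrl,
                                     test = config$stats$test)
    }
  }
  summary_tbl <- if (length(summaries)) list_rbind(lapply(summaries, tidy)) else tibble()

  recovery_tbl <- tibble()
  if (!is.null(config$simulate$recovery) &&
      "n_speckles_g3bp1" %in% names(img_tbl)) {
    for (cond in unique(img_tbl$condition)) {
      d <- img_tbl %>%
        filter(.data$condition == cond, .data$n_nuclei > 0) %>%
        transmute(.data$timepoint, .data$replicate,
                  n_granules = .data$n_speckles_g3bp1, .data$n_nuclei)
      rc <- recovery_curve(d)
      rc$condition <- cond
      recovery_tbl <- bind_rows(recovery_tbl, as_tibble(unclass(rc)))
    }
  }

  # ---- stage: report --------------------------------------------------------
  stamp <- function(df) {
    if (nrow(df) == 0L) return(df)
    df$config_hash <- hash
    df$seed <- config$seed
    df
  }
  obj_tbl <- if (length(obj_records)) {
    select(list_rbind(obj_records), "image", "kind", "stain", everything())
  } else {
    tibble()
  }
  paths <- list(
    images = file.path(out_dir, "images.csv"),
    objects = file.path(out_dir, "objects.csv"),
    coloc_calls = file.path(out_dir, "coloc_calls.csv"),
    coloc_fractions = file.path(out_dir, "coloc_fractions.csv"),
    summary = file.path(out_dir, "summary.csv"),
    recovery = file.path(out_dir, "recovery.csv"),
    config = file.path(out_dir, "run_config.yaml"),
    report = file.path(out_dir, "report.txt"))
  write_table(stamp(img_tbl), paths$images)
  write_table(stamp(obj_tbl), paths$objects)
  write_table(stamp(coloc_calls), paths$coloc_calls)
  write_table(stamp(coloc_frac), paths$coloc_fractions)
  write_table(stamp(summary_tbl), paths$summary)
  if (nrow(recovery_tbl)) write_table(stamp(recovery_tbl), paths$recovery)
  cfg_echo <- unclass(config)
  cfg_echo$config_hash <- hash
  cfg_echo$simulate$conditions <- lapply(cfg_echo$simulate$conditions, function(x) {
    if (inherits(x, "scene_spec")) unclass(x) else x
  })
  yaml::write_yaml(cfg_echo, paths$config)
  writeLines(log_lines, paths$report)

  structure(list(out_dir = out_dir, config = config, config_hash = hash,
                 images = img_tbl, objects = obj_tbl,
                 coloc_calls = coloc_calls, coloc_fractions = coloc_frac,
                 summary = summary_tbl, recovery = recovery_tbl,
                 truths = if (length(truths)) truths else NULL,
                 paths = paths),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %s\n", x$out_dir))
  cat(sprintf("  %d images, %d objects, %d coloc calls\n",
              nrow(x$images), nrow(x$objects), nrow(x$coloc_calls)))
  if (nrow(x$summary)) {
    cat("  summaries:\n")
    print(as_tibble(x$summary), n = 20)
  }
  invisible(x)
}

#' @rdname run_pipeline
#' @param x a `pipeline_run`.
#' @param ... unused.
#' @export
tidy.pipeline_run <- function(x, ...) as_tibble(x$summary)

#' @rdname run_pipeline
#' @export
glance.pipeline_run <- function(x, ...) {
  tibble(n_images = nrow(x$images), n_objects = nrow(x$objects),
         n_coloc_calls = nrow(x$coloc_calls),
         n_summaries = nrow(x$summary), config_hash = x$config_hash,
         seed = x$config$seed)
}

#' Write miniature fixture scenes for every preset
#'
#' One small scene (192 x 192 px, 4 cells) per scenario preset, written as a
#' multipage TIFF with its ground truth as TSV and the spec echoed to YAML.
#' Fixed seeds give byte-identical fixtures.
#'
#' @param out_dir output directory.
#' @param seed base seed.
#' @param presets character vector of preset names.
#' @return invisibly, a tibble of written files.
#' @export
make_fixtures <- function(out_dir, seed = 1L,
                          presets = c("unstressed_control", "q65_speckling",
                                      "arsenite_stressed", "recovery")) {
  if (length(presets) == 0L) {
    warn("no presets requested; nothing written.")
    return(invisible(tibble(preset = character(0), path = character(0))))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (p in presets) {
    sp <- scenario_preset(p, seed = seed)
    sp$image_shape <- c(192L, 192L)
    sp$n_cells <- 4
    out <- generate_micrograph(sp)
    tif <- file.path(out_dir, paste0(p, ".tif"))
    write_micrograph(out$image, tif)
    readr::write_tsv(out$truth, file.path(out_dir, paste0(p, "_truth.tsv")),
                     progress = FALSE)
    yaml::write_yaml(unclass(sp), file.path(out_dir, paste0(p, "_spec.yaml")))
    rows[[p]] <- tibble(preset = p, path = tif)
  }
  invisible(list_rbind(rows))
}
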