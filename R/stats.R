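#' Significance flag from a p-value
#'
#' `"**"` for p < 0.01, `"*"` for p < 0.05, `"ns"` otherwise (`NA` stays
#' `NA`).
#' @param p numeric vector of p-values.
#' @return character vector of flags.
#' @export
signif_flag <- function(p) {
  dplyr::case_when(is.na(p) ~ NA_character_,
                   p < 0.01 ~ "**",
                   p < 0.05 ~ "*",
                   TRUE ~ "ns")
}

#' Replicate-level condition summary with fold change versus control
#'
#' Aggregates per-image measurements to per-replicate means (the biological
#' replicate is the statistical unit), then summarises each condition:
#' grand mean over replicates, SEM over replicate means, fold change versus
#' the control condition's mean, and a two-sided Welch t-test (or
#' Mann-Whitney test) of the condition's replicate means against the
#' control's. Flags follow the 0.05 / 0.01 cut-offs.
#'
#' @param data data frame with one row per image (or finer unit).
#' @param value name of the measurement column (string).
#' @param control control condition label.
#' @param condition,replicate names of the condition and replicate columns.
#' @param test `"welch"` (default) or `"wilcoxon"`.
#' @param measurement optional measurement name recorded in the output.
#' @return a tibble of class `condition_summary`: one row per condition with
#'   `measurement`, `condition`, `n_replicates`, `mean`, `sem`,
#'   `fold_change`, `p_value`, `signif`.
#' @export
fold_change <- function(data, value, control, condition = "condition",
                        replicate = "replicate", test = c("welch", "wilcoxon"),
                        measurement = value) {
  test <- match.arg(test)
  for (col in c(value, condition, replicate)) {
    if (!col %in% names(data)) {
      abort(sprintf("column '%s' not found in `data`.", col),
            class = "gs_invalid_input")
    }
  }
  if (!control %in% data[[condition]]) {
    abort(sprintf("control condition '%s' absent from the data.", control),
          class = "gs_invalid_input")
  }
  rep_means <- data %>%
    filter(!is.na(.data[[value]])) %>%
    group_by(cond = .data[[condition]], rep = .data[[replicate]]) %>%
    summarise(m = mean(.data[[value]]), .groups = "drop")
  ctrl <- filter(rep_means, .data$cond == control)$m
  ctrl_mean <- mean(ctrl)
  summarise_one <- function(ms, cond_label) {
    p <- if (cond_label == control) {
      NA_real_
    } else if (length(ms) >= 2 && length(ctrl) >= 2 &&
               (sd(ms) > 0 || sd(ctrl) > 0)) {
      if (test == "welch") {
        t.test(ms, ctrl, var.equal = FALSE)$p.value
      } else {
        stats::wilcox.test(ms, ctrl, exact = FALSE)$p.value
      }
    } else if (cond_label != control && isTRUE(all.equal(mean(ms), ctrl_mean)) &&
               sd(c(ms, ctrl)) == 0) {
      1
    } else {
      NA_real_
    }
    tibble(
      n_replicates = length(ms),
      mean = mean(ms),
      sem = if (length(ms) > 1) sd(ms) / sqrt(length(ms)) else 0,
      fold_change = if (ctrl_mean > 0) mean(ms) / ctrl_mean else NA_real_,
      p_value = p,
      signif = if (cond_label == control) NA_character_ else signif_flag(p))
  }
  out <- rep_means %>%
    group_by(condition = .data$cond) %>%
    group_modify(~ summarise_one(.x$m, .y$condition)) %>%
    ungroup() %>%
    mutate(measurement = measurement, .before = 1)
  class(out) <- c("condition_summary", class(out))
  out
}

#' Object counts per cell, summarised per condition
#'
#' Normalises an object count (speckles, granules, aggregates) by the number
#' of nuclei in each image, then summarises per condition with
#' [fold_change()]. Images without nuclei are excluded with a warning.
#'
#' @param data data frame with one row per image: columns `condition`,
#'   `replicate`, a count column and an `n_nuclei` column.
#' @param count name of the count column.
#' @param control control condition label.
#' @param ... passed to [fold_change()].
#' @return a `condition_summary` tibble for the per-cell count.
#' @export
granule_counts <- function(data, count, control, ...) {
  if (!all(c(count, "n_nuclei") %in% names(data))) {
    abort(sprintf("`data` needs columns '%s' and 'n_nuclei'.", count),
          class = "gs_invalid_input")
  }
  bad <- data$n_nuclei == 0
  if (any(bad)) {
    warn(sprintf("%d image(s) with 0 nuclei excluded from per-cell counts.",
                 sum(bad)))
    data <- data[!bad, , drop = FALSE]
  }
  data$per_cell <- data[[count]] / data$n_nuclei
  fold_change(data, "per_cell", control = control,
              measurement = paste0(count, "_per_cell"), ...)
}

#' Fraction of granules positive for a partner stain
#'
#' Either rule from the granule-scoring repertoire: with a partner label
#' mask, symmetric centroid containment ([call_double_positive()]); with a
#' partner intensity channel, a granule is positive when its mean partner
#' intensity is at least `fold_threshold` times the immediate ring background
#' of the granule in the partner channel.
#'
#' @param granules a [label_mask()] of granules.
#' @param partner_image optional partner channel matrix (ring rule).
#' @param partner_mask optional partner [label_mask()] (containment rule).
#' @param fold_threshold enrichment threshold for the ring rule (default 2).
#' @return one-row tibble: `n`, `positives`, `fraction`, `se`, `rule`.
#' @export
granule_positive_fraction <- function(granules, partner_image = NULL,
                                      partner_mask = NULL, fold_threshold = 2) {
  n <- n_objects(granules)
  if (n == 0L) {
    warn("no granules; fraction undefined.")
    return(tibble(n = 0L, positives = NA_integer_, fraction = NA_real_,
                  se = NA_real_, rule = NA_character_))
  }
  if (!is.null(partner_mask)) {
    pos <- length(unique(call_double_positive(granules, partner_mask)$pairs$label_a))
    rule <- "centroid_containment"
  } else if (!is.null(partner_image)) {
    m <- granules$mask
    pr <- region_props(m, partner_image)
    bg <- ring_background(partner_image, m)
    fold <- ifelse(bg[pr$label] > 0, pr$mean_intensity / bg[pr$label], Inf)
    pos <- sum(fold >= fold_threshold)
    rule <- "ring_enrichment"
  } else {
    abort("supply `partner_image` or `partner_mask`.", class = "gs_invalid_input")
  }
  frac <- pos / n
  tibble(n = n, positives = as.integer(pos), fraction = frac,
         se = sqrt(frac * (1 - frac) / n), rule = rule)
}

#' Aggregate counts per cell across experiment phases
#'
#' Summarises nuclear and cytoplasmic aggregate counts per cell across the
#' phases of a stress/recovery timeline (e.g. untreated, arsenite,
#' recovery), with a Welch t-test of each phase against the first on
#' replicate means, per compartment.
#'
#' @param data data frame with one row per image and compartment: columns
#'   `phase`, `replicate`, `compartment`, `n_aggregates`, `n_nuclei`.
#' @param phases optional phase ordering (default: order of appearance).
#' @return tibble: per compartment and phase, replicate-level mean per-cell
#'   count, SEM, p-value vs the first phase and significance flag.
#' @export
aggregates_per_cell_timeline <- function(data, phases = NULL) {
  needed <- c("phase", "replicate", "compartment", "n_aggregates", "n_nuclei")
  if (!all(needed %in% names(data))) {
    abort(sprintf("`data` needs columns %s.", paste(needed, collapse = ", ")),
          class = "gs_invalid_input")
  }
  phases <- phases %||% unique(data$phase)
  missing_ph <- setdiff(phases, unique(data$phase))
  if (length(missing_ph)) {
    warn(sprintf("phase(s) %s missing from the data; omitted.",
                 paste(missing_ph, collapse = ", ")))
    phases <- setdiff(phases, missing_ph)
  }
  bad <- data$n_nuclei == 0
  if (any(bad)) {
    warn(sprintf("%d image(s) with 0 nuclei excluded.", sum(bad)))
    data <- data[!bad, , drop = FALSE]
  }
  data$per_cell <- data$n_aggregates / data$n_nuclei
  out <- list()
  for (cmp in unique(data$compartment)) {
    d <- filter(data, .data$compartment == cmp)
    rep_means <- d %>%
      group_by(.data$phase, .data$replicate) %>%
      summarise(m = mean(.data$per_cell), .groups = "drop")
    base <- filter(rep_means, .data$phase == phases[1])$m
    for (ph in phases) {
      ms <- filter(rep_means, .data$phase == ph)$m
      if (length(ms) == 0L) next
      p <- if (ph == phases[1] || length(ms) < 2 || length(base) < 2 ||
               (sd(ms) == 0 && sd(base) == 0)) {
        if (ph == phases[1]) NA_real_ else if (isTRUE(all.equal(mean(ms), mean(base)))) 1 else NA_real_
      } else {
        t.test(ms, base, var.equal = FALSE)$p.value
      }
      out[[length(out) + 1L]] <- tibble(
        compartment = cmp, phase = ph, n_replicates = length(ms),
        mean_per_cell = mean(ms),
        sem = if (length(ms) > 1) sd(ms) / sqrt(length(ms)) else 0,
        p_vs_first = p, signif = if (ph == phases[1]) NA_character_ else signif_flag(p))
    }
  }
  list_rbind(out)
}

#' Stress-granule recovery curve
#'
#' Per-cell granule counts by recovery timepoint, normalised to the t = 0
#' mean (which is exactly 1 by construction). SEM is propagated over
#' replicate means on the normalised scale.
#'
#' @param data data frame with one row per image: columns `timepoint`,
#'   `replicate`, `n_granules`, `n_nuclei`.
#' @return a tibble of class `recovery_curve`: `timepoint`, `n_replicates`,
#'   `mean_per_cell`, `normalised`, `sem_normalised`.
#' @export
recovery_curve <- function(data) {
  needed <- c("timepoint", "replicate", "n_granules", "n_nuclei")
  if (!all(needed %in% names(data))) {
    abort(sprintf("`data` needs columns %s.", paste(needed, collapse = ", ")),
          class = "gs_invalid_input")
  }
  if (!0 %in% data$timepoint) {
    abort("timepoint 0 is required as the normalisation baseline.",
          class = "gs_invalid_input")
  }
  bad <- data$n_nuclei == 0
  if (any(bad)) {
    warn(sprintf("%d image(s) with 0 nuclei excluded.", sum(bad)))
    data <- data[!bad, , drop = FALSE]
  }
  data$per_cell <- data$n_granules / data$n_nuclei
  rep_means <- data %>%
    group_by(.data$timepoint, .data$replicate) %>%
    summarise(m = mean(.data$per_cell), .groups = "drop")
  t0_mean <- mean(filter(rep_means, .data$timepoint == 0)$m)
  if (!is.finite(t0_mean) || t0_mean <= 0) {
    abort("mean granule count at t = 0 is zero; curve cannot be normalised.",
          class = "gs_degenerate_input")
  }
  out <- rep_means %>%
    group_by(.data$timepoint) %>%
    summarise(n_replicates = dplyr::n(), mean_per_cell = mean(.data$m),
              sem_norm = if (dplyr::n() > 1) sd(.data$m / t0_mean) / sqrt(dplyr::n()) else 0,
              .groups = "drop") %>%
    mutate(normalised = .data$mean_per_cell / t0_mean) %>%
    select("timepoint", "n_replicates", "mean_per_cell", "normalised",
           sem_normalised = "sem_norm") %>%
    arrange(.data$timepoint)
  class(out) <- c("recovery_curve", class(out))
  out
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' @rdname fold_change
#' @param x a `condition_summary`.
#' @export
tidy.condition_summary <- function(x, ...) as_tibble(unclass(x))

#' @rdname fold_change
#' @export
glance.condition_summary <- function(x, ...) {
  tibble(measurement = x$measurement[1], n_conditions = nrow(x),
         min_p = suppressWarnings(min(x$p_value, na.rm = TRUE)),
         any_significant = any(x$signif %in% c("*", "**")))
}
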