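test_that("generation is bit-identical under a fixed spec and seed", {
  sp <- scenario_preset("q65_speckling", seed = 42)
  a <- generate_micrograph(sp)
  b <- generate_micrograph(sp)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth, b$truth)

  series_a <- generate_recovery_series(sp, c(0, 30), 30)
  series_b <- generate_recovery_series(sp, c(0, 30), 30)
  expect_identical(series_a[[2]]$image$channels, series_b[[2]]$image$channels)
})

test_that("ground truth contains exactly the planted objects", {
  sp <- scene_spec(n_cells = 12, image_shape = c(320L, 320L), seed = 42)
  out <- generate_micrograph(sp)
  expect_equal(sum(out$truth$kind == "nucleus"), 12)
  # every centroid inside bounds
  expect_true(all(out$truth$row >= 1 & out$truth$row <= 320))
  expect_true(all(out$truth$col >= 1 & out$truth$col <= 320))
})

test_that("zero co-localisation probability plants no partners", {
  sp <- scene_spec(n_cells = 8, image_shape = c(320L, 320L),
                   aggregates_per_cell = c(nuclear = 6, cytoplasmic = 6),
                   coloc_prob = list(tia1 = c(nuclear = 0, cytoplasmic = 0)),
                   seed = 7)
  out <- generate_micrograph(sp)
  agg <- out$truth[out$truth$kind == "aggregate", ]
  expect_gt(nrow(agg), 50)
  expect_true(all(agg$coloc_partners == ""))
})

test_that("aggregate compartments are consistent with the planted nuclei", {
  sp <- scene_spec(aggregates_per_cell = c(nuclear = 2, cytoplasmic = 2),
                   seed = 11)
  out <- generate_micrograph(sp)
  agg <- out$truth[out$truth$kind == "aggregate", ]
  nucs <- out$truth[out$truth$kind == "nucleus", ]
  for (i in seq_len(nrow(agg))) {
    nuc <- nucs[nucs$cell == agg$cell[i], ]
    d2 <- ((agg$row[i] - nuc$row) / nuc$sigma_major)^2 +
      ((agg$col[i] - nuc$col) / nuc$sigma_minor)^2
    # nuclear centroids lie within the (bounding circle of the) nucleus,
    # cytoplasmic ones outside the inscribed circle
    if (agg$compartment[i] == "nuclear") {
      expect_lt(sqrt((agg$row[i] - nuc$row)^2 + (agg$col[i] - nuc$col)^2),
                nuc$sigma_major + 1)
    } else {
      expect_gt(sqrt((agg$row[i] - nuc$row)^2 + (agg$col[i] - nuc$col)^2),
                nuc$sigma_minor - 1)
    }
  }
})

test_that("planted speckle masks carry the requested eccentricity", {
  sp <- scene_spec(speckles_per_cell = c(g3bp1 = 2),
                   speckle_axis_ratio_range = c(0.5, 0.5),
                   speckle_sigma_range = c(2.5, 3), speckle_amplitude_fold = 12,
                   seed = 3)
  out <- generate_micrograph(sp)
  det <- detect_speckles(get_channel(out$image, "g3bp1"),
                         speckle_params(max_area = 200), stain = "g3bp1")
  ecc <- det$records$eccentricity[det$records$retained]
  ecc <- ecc[!is.na(ecc)]
  expect_gt(length(ecc), 4)
  expect_lt(abs(median(ecc) - sqrt(1 - 0.25)), 0.05)
})

test_that("recovery series realises binomial thinning of the planted counts", {
  sp <- scene_spec(image_shape = c(512L, 512L), n_cells = 25,
                   speckles_per_cell = c(g3bp1 = 16), seed = 5)
  series <- generate_recovery_series(sp, c(0, 30, 60), decay_half_life = 30)
  counts <- vapply(series, function(fr) {
    sum(fr$truth$kind == "speckle" & fr$truth$channel == "g3bp1")
  }, numeric(1))
  expected <- c(400, 200, 100)
  for (k in 1:3) {
    expect_lt(abs(counts[k] - expected[k]), 3 * sqrt(expected[k]))
  }
  expect_equal(series[[2]]$image$timepoint, 30)
})

test_that("infinite half-life means no decay and one timepoint means one frame", {
  sp <- scene_spec(speckles_per_cell = c(g3bp1 = 20), seed = 8)
  one <- generate_recovery_series(sp, 0, decay_half_life = 30)
  expect_length(one, 1)
  n0 <- sum(one[[1]]$truth$kind == "speckle")
  expect_lt(abs(n0 - 120), 3 * sqrt(120))

  flat <- generate_recovery_series(sp, c(0, 120), decay_half_life = Inf)
  n <- vapply(flat, function(fr) sum(fr$truth$kind == "speckle"), numeric(1))
  expect_lt(abs(n[1] - n[2]), 3 * sqrt(2 * 120))
})

test_that("invalid specs fail naming the offending field", {
  expect_error(scene_spec(n_cells = -1), "n_cells", class = "gs_invalid_spec")
  expect_error(scene_spec(speckle_axis_ratio_range = c(0, 1)),
               "axis_ratio", class = "gs_invalid_spec")
  expect_error(scene_spec(coloc_prob = list(tia1 = c(nuclear = 1.4))),
               "coloc_prob", class = "gs_invalid_spec")
  expect_error(scene_spec(speckle_amplitude_fold = 0),
               "speckle_amplitude_fold", class = "gs_invalid_spec")
  expect_error(generate_recovery_series(scene_spec(), numeric(0), 30),
               "timepoints", class = "gs_invalid_spec")
  expect_error(generate_recovery_series(scene_spec(), c(0, 30), 0),
               "half_life", class = "gs_invalid_spec")
})

test_that("presets encode the study contrasts", {
  ctrl <- scenario_preset("unstressed_control")
  q65 <- scenario_preset("q65_speckling")
  expect_equal(q65$speckles_per_cell[["g3bp1"]] /
                 ctrl$speckles_per_cell[["g3bp1"]], 6)
  expect_equal(unname(ctrl$coloc_prob$g3bp1), c(0, 0))
  expect_equal(unname(q65$coloc_prob$g3bp1), c(0, 0))
  expect_gt(q65$coloc_prob$tia1[["cytoplasmic"]],
            q65$coloc_prob$tia1[["nuclear"]])
  ars <- scenario_preset("arsenite_stressed")
  expect_gt(ars$granules_per_cell, 0)
  expect_error(scenario_preset("foo"), "unstressed_control",
               class = "gs_unknown_preset")
})
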