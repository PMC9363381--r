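test_that("fold change is the ratio of condition to control replicate means", {
  d <- tibble::tibble(
    condition = rep(c("ctrl", "q65"), each = 4),
    replicate = rep(1:2, 4),
    value = c(10, 10, 10, 10, 40, 40, 40, 40))
  cs <- fold_change(d, "value", control = "ctrl")
  expect_equal(cs$fold_change[cs$condition == "q65"], 4)
  expect_equal(cs$fold_change[cs$condition == "ctrl"], 1)
})

test_that("identical arms give fold 1.0 and an ns flag", {
  d <- tibble::tibble(
    condition = rep(c("ctrl", "x"), each = 6),
    replicate = rep(rep(1:3, each = 2), 2),
    value = rep(c(5, 7, 6, 5, 7, 6), 2))
  cs <- fold_change(d, "value", control = "ctrl")
  x <- cs[cs$condition == "x", ]
  expect_equal(x$fold_change, 1)
  expect_equal(x$signif, "ns")
  # degenerate identical constant arms still report fold 1 / ns
  dc <- tibble::tibble(condition = rep(c("ctrl", "x"), each = 2),
                       replicate = rep(1:2, 2), value = rep(10, 4))
  csc <- fold_change(dc, "value", control = "ctrl")
  expect_equal(csc$fold_change[csc$condition == "x"], 1)
  expect_equal(csc$signif[csc$condition == "x"], "ns")
})

test_that("SEM follows its definition over replicate means", {
  d <- tibble::tibble(condition = "c", replicate = 1:3, value = c(2, 4, 6))
  cs <- fold_change(d, "value", control = "c")
  expect_equal(cs$mean, 4)
  expect_equal(cs$sem, 2 / sqrt(3))
})

test_that("significance flags reproduce the 0.05/0.01 cut-offs exactly", {
  expect_equal(signif_flag(c(0.049, 0.05, 0.009, 0.01, 0.9, NA)),
               c("*", "ns", "**", "*", "ns", NA))
})

test_that("granule counts are normalised per nucleus and 0-nuclei images drop", {
  d <- tibble::tibble(
    condition = rep(c("ctrl", "ars"), each = 2),
    replicate = rep(1:2, 2),
    n_granules = c(30, 30, 90, 90),
    n_nuclei = c(10, 10, 10, 10))
  cs <- granule_counts(d, "n_granules", control = "ctrl")
  expect_equal(cs$mean[cs$condition == "ctrl"], 3)
  expect_equal(cs$fold_change[cs$condition == "ars"], 3)
  d0 <- d
  d0$n_nuclei[1] <- 0
  expect_warning(granule_counts(d0, "n_granules", control = "ctrl"),
                 "0 nuclei")
})

test_that("granule positive fraction follows the ring and containment rules", {
  m <- matrix(0L, 64, 64)
  m[10:13, 10:13] <- 1L
  m[30:33, 30:33] <- 2L
  m[50:53, 50:53] <- 3L
  gran <- label_mask(m, kind = "speckle", stain = "g3bp1")
  flat <- matrix(25, 64, 64)
  fr_flat <- granule_positive_fraction(gran, partner_image = flat)
  expect_equal(fr_flat$fraction, 0)
  enriched <- flat
  enriched[m > 0] <- 80   # fold > 3 in every granule
  fr_all <- granule_positive_fraction(gran, partner_image = enriched)
  expect_equal(fr_all$fraction, 1)
  fr_mask <- granule_positive_fraction(gran, partner_mask = gran)
  expect_equal(fr_mask$fraction, 1)
  expect_equal(fr_mask$rule, "centroid_containment")
  empty <- label_mask(matrix(0L, 64, 64), kind = "speckle")
  expect_warning(fr_na <- granule_positive_fraction(empty, partner_image = flat),
                 "no granules")
  expect_true(is.na(fr_na$fraction))
})

test_that("aggregate timelines flag no difference under constant counts", {
  d <- tidyr::expand_grid(
    phase = c("untreated", "arsenite", "recovery"),
    replicate = 1:4,
    compartment = c("nuclear", "cytoplasmic"),
    img = 1:2)
  # identical counts in every phase: the null case must flag ns everywhere
  d$n_aggregates <- rep(c(10, 12, 14, 12), length.out = nrow(d))
  d$n_nuclei <- 6
  tl <- aggregates_per_cell_timeline(d, phases = c("untreated", "arsenite",
                                                   "recovery"))
  later <- tl[tl$phase != "untreated", ]
  expect_true(all(later$signif == "ns"))
  # a planted doubling is detected with enough replicates
  set.seed(5)
  d2 <- d
  boost <- d2$phase == "arsenite" & d2$compartment == "nuclear"
  d2$n_aggregates[boost] <- rpois(sum(boost), 24)
  tl2 <- aggregates_per_cell_timeline(d2, phases = c("untreated", "arsenite",
                                                     "recovery"))
  p2 <- tl2$p_vs_first[tl2$phase == "arsenite" & tl2$compartment == "nuclear"]
  expect_lt(p2, 0.05)
  expect_warning(aggregates_per_cell_timeline(d, phases = c("untreated", "gone")),
                 "gone")
})

test_that("recovery curves normalise to t = 0 exactly", {
  d <- tibble::tibble(
    timepoint = rep(c(0, 30, 60), each = 2),
    replicate = rep(1:2, 3),
    n_granules = c(20, 20, 10, 10, 5, 5),
    n_nuclei = 1)
  rc <- recovery_curve(d)
  expect_equal(rc$normalised, c(1, 0.5, 0.25))
  expect_equal(rc$normalised[rc$timepoint == 0], 1)
  single <- recovery_curve(d[d$timepoint == 0, ])
  expect_equal(single$normalised, 1)
  expect_error(recovery_curve(d[d$timepoint > 0, ]), class = "gs_invalid_input")
  zero <- d
  zero$n_granules[zero$timepoint == 0] <- 0
  expect_error(recovery_curve(zero), class = "gs_degenerate_input")
})

test_that("tidy and glance methods return flat tibbles", {
  d <- tibble::tibble(condition = rep(c("a", "b"), each = 4),
                      replicate = rep(1:2, 4), value = c(1:4, 11:14))
  cs <- fold_change(d, "value", control = "a")
  td <- tidy(cs)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "condition_summary"))
  gl <- glance(cs)
  expect_equal(gl$n_conditions, 2)
})
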