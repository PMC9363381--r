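test_that("planted non-touching nuclei are counted exactly", {
  sp <- scene_spec(n_cells = 12, image_shape = c(320L, 320L), seed = 42)
  out <- generate_micrograph(sp)
  nuc <- detect_nuclei(get_channel(out$image, "dna"))
  expect_equal(n_objects(nuc), 12)
})

test_that("a blank DNA channel yields zero nuclei with a warning", {
  expect_warning(nuc <- detect_nuclei(matrix(5, 64, 64)), "constant")
  expect_equal(n_objects(nuc), 0)
})

test_that("two overlapping nuclei with distinct centres are split", {
  img <- matrix(2, 96, 96)
  g <- expand.grid(r = 1:96, c = 1:96)
  inside <- ((g$r - 40)^2 + (g$c - 48)^2 <= 14^2) |
    ((g$r - 62)^2 + (g$c - 48)^2 <= 14^2)
  img[as.matrix(g[inside, ])] <- 60
  img <- img + matrix(with_seed(1, rnorm(96 * 96, 0, 2)), 96, 96)
  nuc <- detect_nuclei(img)
  expect_equal(n_objects(nuc), 2)
})

test_that("speckle retention follows the eightfold, area and shape rules", {
  base <- matrix(20, 96, 96)
  paint <- function(m, r0, c0, amp, sa, sb = sa, th = 0) {
    g <- expand.grid(r = 1:96, c = 1:96)
    u <- (g$r - r0) * cos(th) + (g$c - c0) * sin(th)
    v <- -(g$r - r0) * sin(th) + (g$c - c0) * cos(th)
    m + matrix(amp * exp(-(u^2 / (2 * sa^2) + v^2 / (2 * sb^2))), 96, 96)
  }
  img <- paint(base, 20, 20, 180, 2)          # fold 10 -> retained
  img <- paint(img, 60, 60, 40, 2)            # fold 3 -> intensity reject
  img <- paint(img, 30, 70, 180, 6, 0.6)      # elongated bar -> shape reject
  img <- img + matrix(with_seed(2, rnorm(96 * 96, 0, 1)), 96, 96)
  img <- pmax(img, 0)
  det <- detect_speckles(img, speckle_params(max_area = 120), stain = "g3bp1")
  rec <- det$records
  near <- function(r, c) which.min((rec$centroid_row - r)^2 +
                                     (rec$centroid_col - c)^2)
  expect_true(rec$retained[near(20, 20)])
  bar <- near(30, 70)
  expect_false(rec$retained[bar])
  expect_equal(rec$reject_reason[bar], "shape")
  # the dim spot either fails thresholding entirely or the intensity rule
  dim_candidates <- rec[abs(rec$centroid_row - 60) < 4 &
                          abs(rec$centroid_col - 60) < 4, ]
  expect_true(nrow(dim_candidates) == 0 || !any(dim_candidates$retained))
})

test_that("speckle calls are invariant to multiplying the image by a constant", {
  sp <- scenario_preset("q65_speckling", seed = 9)
  out <- generate_micrograph(sp)
  g <- get_channel(out$image, "g3bp1")
  a <- detect_speckles(g, speckle_params(), stain = "g3bp1")
  b <- detect_speckles(g * 4.2, speckle_params(), stain = "g3bp1")
  expect_equal(n_objects(a$mask), n_objects(b$mask))
  expect_equal(a$records$retained, b$records$retained)
})

test_that("sparse planted aggregates are all detected with their compartment", {
  tp <- 0L; fp <- 0L; fn <- 0L; cmp_ok <- 0L; cmp_n <- 0L
  for (seed in c(2, 4, 6)) {
    sp <- scene_spec(aggregates_per_cell = c(nuclear = 0.5, cytoplasmic = 0.5),
                     seed = seed)
    out <- generate_micrograph(sp)
    nuc <- detect_nuclei(get_channel(out$image, "dna"))
    da <- detect_aggregates(get_channel(out$image, "atxn7"), nuc)
    tr <- out$truth[out$truth$kind == "aggregate", ]
    m <- match_counts(da$records$centroid_row, da$records$centroid_col,
                      tr$row, tr$col, tol = 4)
    tp <- tp + m["tp"]; fp <- fp + m["fp"]; fn <- fn + m["fn"]
    for (i in seq_len(nrow(da$records))) {
      d <- sqrt((tr$row - da$records$centroid_row[i])^2 +
                  (tr$col - da$records$centroid_col[i])^2)
      j <- which.min(d)
      if (d[j] <= 4) {
        cmp_n <- cmp_n + 1L
        cmp_ok <- cmp_ok + (tr$compartment[j] == da$records$compartment[i])
      }
    }
  }
  expect_gte(unname(tp), 10)
  expect_gte(unname(2 * tp / (2 * tp + fp + fn)), 0.9)
  expect_gte(cmp_ok / cmp_n, 0.9)
})

test_that("double-positive calling is symmetric centroid containment", {
  m <- matrix(0L, 60, 60)
  for (k in 1:7) m[(k * 7):(k * 7 + 2), 20:22] <- k
  lm <- label_mask(m, kind = "speckle", stain = "g3bp1")
  same <- call_double_positive(lm, label_mask(m, kind = "speckle", stain = "tia1"))
  expect_equal(same$n, 7)
  shifted <- matrix(0L, 60, 60)
  shifted[, 40:42] <- m[, 20:22]
  expect_equal(call_double_positive(lm, label_mask(shifted, kind = "speckle"))$n, 0)
})

test_that("the planted double-positive fraction is recovered within binomial error", {
  n_granules <- 0L; n_pairs <- 0L
  for (seed in c(31, 32, 33, 34)) {
    sp <- scenario_preset("arsenite_stressed", seed = seed)
    sp$granule_partner_prob <- c(tia1 = 0.5, atxn7 = 0)
    sp$aggregates_per_cell <- c(nuclear = 0, cytoplasmic = 0)
    sp$speckles_per_cell <- c(g3bp1 = 0, tia1 = 0)
    out <- generate_micrograph(sp)
    g <- detect_speckles(get_channel(out$image, "g3bp1"), speckle_params(),
                         stain = "g3bp1")
    t1 <- detect_speckles(get_channel(out$image, "tia1"), speckle_params(),
                          stain = "tia1")
    n_granules <- n_granules + n_objects(g$mask)
    n_pairs <- n_pairs + call_double_positive(g$mask, t1$mask)$n
  }
  expect_gte(n_granules, 100)
  frac <- n_pairs / n_granules
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n_granules))
})

test_that("speckle detection recovers sparse bright speckles with high F1", {
  tot <- c(tp = 0, fp = 0, fn = 0)
  for (seed in 101:104) {
    sp <- scenario_preset("q65_speckling", seed = seed)
    tot <- tot + scene_speckle_f1(sp)
  }
  expect_gte(f1_score(tot), 0.9)
})
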