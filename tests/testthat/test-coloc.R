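# A hand-built profile for rule tests: reference peak centred, configurable
# partner series.
mk_profile <- function(partner_vals, ref_peak_at = 21, n = 41) {
  pos <- seq(0, n - 1)
  ref <- 100 + 300 * exp(-((pos - (ref_peak_at - 1))^2) / 18)
  out <- dplyr::bind_rows(
    tibble::tibble(position = pos, channel = "atxn7", intensity = ref),
    tibble::tibble(position = pos, channel = "tia1", intensity = partner_vals))
  class(out) <- c("intensity_profile", class(out))
  attr(out, "aggregate_id") <- 1L
  out
}

test_that("a flat image gives a constant profile in every channel", {
  mg <- micrograph(list(atxn7 = matrix(40, 64, 64), tia1 = matrix(40, 64, 64)))
  rec <- tibble::tibble(centroid_row = 32, centroid_col = 32, orientation = 0.4,
                        major_axis = 10, label = 1L)
  prof <- extract_profile(mg, rec)
  expect_true(all(prof$intensity == 40))
  expect_setequal(unique(prof$channel), c("atxn7", "tia1"))
})

test_that("the profile maximum sits at the planted aggregate centre", {
  img <- matrix(10, 96, 96)
  g <- expand.grid(r = 1:96, c = 1:96)
  img <- img + matrix(150 * exp(-((g$r - 50)^2 + (g$c - 40)^2) / (2 * 9)), 96, 96)
  mg <- micrograph(list(atxn7 = img))
  rec <- tibble::tibble(centroid_row = 50, centroid_col = 40,
                        orientation = 0.7, major_axis = 12, label = 1L)
  prof <- extract_profile(mg, rec)
  a <- prof[prof$channel == "atxn7", ]
  centre <- attr(prof, "centre_position")
  expect_lt(abs(a$position[which.max(a$intensity)] - centre), 1 + 1e-9)
})

test_that("a centroid jammed in the image corner cannot yield a profile", {
  mg <- micrograph(list(atxn7 = matrix(seq_len(64^2) %% 7, 64, 64)))
  rec <- tibble::tibble(centroid_row = 2, centroid_col = 2, orientation = pi / 4,
                        major_axis = 40, label = 1L)
  expect_error(extract_profile(mg, rec), class = "gs_profile_too_short")
})

test_that("the twofold scoring rule works on canonical profiles", {
  flat <- rep(100, 41)
  # coinciding plateau peak at 250 -> fold 2.5, positive
  peak <- flat; peak[19:23] <- 250
  call <- score_profile(mk_profile(peak), "atxn7", "tia1")
  expect_equal(call$peak_fold, 2.5)
  expect_true(call$positive)
  # coinciding peak at 150 -> fold 1.5, negative
  low <- flat; low[19:23] <- 150
  call2 <- score_profile(mk_profile(low), "atxn7", "tia1")
  expect_equal(call2$peak_fold, 1.5)
  expect_false(call2$positive)
  # strong but displaced peak -> not coincident, negative
  disp <- flat; disp[27:31] <- 300
  call3 <- score_profile(mk_profile(disp), "atxn7", "tia1")
  expect_false(call3$coincident)
  expect_false(call3$positive)
  # zero background is degenerate
  zero <- rep(0, 41); zero[19:23] <- 50
  expect_error(score_profile(mk_profile(zero), "atxn7", "tia1"),
               class = "gs_degenerate_input")
  # missing stain
  expect_error(score_profile(mk_profile(flat), "atxn7", "g3bp1"),
               class = "gs_missing_channel")
})

test_that("scoring is invariant to multiplying all channels by a constant", {
  peak <- rep(100, 41); peak[19:23] <- 260
  p1 <- mk_profile(peak)
  p2 <- p1
  p2$intensity <- p2$intensity * 11.7
  c1 <- score_profile(p1, "atxn7", "tia1")
  c2 <- score_profile(p2, "atxn7", "tia1")
  expect_equal(c1$peak_fold, c2$peak_fold, tolerance = 1e-12)
  expect_equal(c1$positive, c2$positive)
})

coloc_fixture <- function() {
  imgs <- list(); aggs <- list()
  for (i in 1:5) {
    sp <- scene_spec(aggregates_per_cell = c(nuclear = 2, cytoplasmic = 2),
                     coloc_prob = list(tia1 = c(nuclear = 0.6, cytoplasmic = 0.6)),
                     seed = 400 + i)
    out <- generate_micrograph(sp)
    id <- sprintf("img%d", i)
    nuc <- detect_nuclei(get_channel(out$image, "dna"))
    da <- detect_aggregates(get_channel(out$image, "atxn7"), nuc)
    rec <- da$records
    rec$image <- id
    imgs[[id]] <- out$image
    aggs[[i]] <- rec
  }
  list(images = imgs, aggregates = dplyr::bind_rows(aggs))
}

test_that("the 5+5 aggregates x 5 images plan yields 50 calls when available", {
  fx <- coloc_fixture()
  calls <- suppressWarnings(
    sample_and_score(fx$images, fx$aggregates, sampling_plan(seed = 7),
                     partner = "tia1"))
  expect_lte(nrow(calls), 50)
  expect_gte(nrow(calls), 45)   # occasional border profiles are skipped
  counts <- table(calls$compartment)
  expect_lte(max(counts), 25)
})

test_that("a shortfall of aggregates is scored in full and warned about", {
  fx <- coloc_fixture()
  few <- fx$aggregates[fx$aggregates$compartment == "cytoplasmic" |
                         fx$aggregates$image != "img1", ]
  few <- few[!(few$image == "img1" & few$compartment == "nuclear") |
               seq_len(nrow(few)) %in% head(which(few$image == "img1" &
                                                    few$compartment == "nuclear"), 2), ]
  expect_warning(
    calls <- sample_and_score(fx$images, few, sampling_plan(seed = 7),
                              partner = "tia1"),
    "only")
  expect_lte(sum(calls$image == "img1" & calls$compartment == "nuclear"), 2)
})

test_that("sampling is deterministic and invariant to image listing order", {
  fx <- coloc_fixture()
  c1 <- suppressWarnings(sample_and_score(fx$images, fx$aggregates,
                                          sampling_plan(seed = 5), partner = "tia1"))
  c2 <- suppressWarnings(sample_and_score(fx$images, fx$aggregates,
                                          sampling_plan(seed = 5), partner = "tia1"))
  expect_identical(c1, c2)
  perm <- rev(fx$images)
  shuffled_aggs <- fx$aggregates[rev(seq_len(nrow(fx$aggregates))), ]
  c3 <- suppressWarnings(sample_and_score(perm, shuffled_aggs,
                                          sampling_plan(seed = 5), partner = "tia1"))
  key <- function(d) sort(paste(d$image, d$compartment, d$aggregate_id))
  expect_identical(key(c1), key(c3))
})

test_that("coloc_fraction computes per-compartment fractions with binomial SE", {
  calls <- tibble::tibble(
    compartment = rep("cytoplasmic", 20),
    positive = rep(c(TRUE, FALSE), c(16, 4)))
  fr <- coloc_fraction(calls)
  expect_equal(fr$fraction, 0.8)
  expect_equal(fr$se, sqrt(0.8 * 0.2 / 20))
  none <- tibble::tibble(compartment = rep("nuclear", 20),
                         positive = rep(FALSE, 20))
  fr0 <- coloc_fraction(none)
  expect_equal(fr0$fraction, 0)
  expect_equal(fr0$se, 0)
  expect_warning(coloc_fraction(calls[0, ]), "no calls")
})
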