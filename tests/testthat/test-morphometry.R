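test_that("eccentricity matches analytic values for canonical shapes", {
  disk <- raster_disk(15)
  expect_lt(as.numeric(eccentricity(disk)), 0.05)
  ell <- raster_ellipse(20, 10)
  expect_lt(abs(as.numeric(eccentricity(ell)) - sqrt(1 - 0.25)), 0.02)
})

test_that("eccentricity equals the naive per-pixel oracle exactly", {
  set.seed(21)
  for (k in 1:12) {
    a <- sample(6:25, 1)
    b <- sample(5:a, 1)
    m <- raster_ellipse(a, b)
    # roughen the boundary so the blob is not a perfect ellipse
    idx <- which(m > 0)
    m[sample(idx, length(idx) %/% 20)] <- 0
    m <- (EBImage::bwlabel(m) == 1) * 1   # keep one component
    if (sum(m) < 5) next
    expect_equal(as.numeric(eccentricity(m)), oracle_eccentricity(m),
                 tolerance = 1e-12)
  }
})

test_that("perimeter agrees with an independent contour tracer and analytic circles", {
  set.seed(33)
  # EBImage's contour tracer walks a slightly different pixel sequence, so
  # the two corner-corrected estimates agree to a few percent, not exactly
  for (k in 1:10) {
    a <- sample(5:20, 1)
    b <- sample(4:a, 1)
    m <- raster_ellipse(a, max(b, 4))
    expect_lt(abs(object_perimeter(m) - oracle_perimeter(m)),
              0.04 * oracle_perimeter(m))
  }
  for (r in c(10, 20, 40)) {
    expect_lt(abs(object_perimeter(raster_disk(r)) - 2 * pi * r),
              0.03 * 2 * pi * r)
  }
})

test_that("form factor behaves like a circularity index", {
  expect_lt(abs(form_factor(raster_disk(20)) - 1), 0.05)
  sq <- matrix(0, 31, 31)
  sq[6:26, 6:26] <- 1
  ffsq <- form_factor(sq)
  expect_gt(ffsq, pi / 4 - 0.05)
  expect_lt(ffsq, 1)
  ell <- raster_ellipse(24, 6)
  expect_lt(form_factor(ell), ffsq)
  expect_error(form_factor(matrix(0, 5, 5)), class = "gs_degenerate_input")
})

test_that("shape metrics are invariant to translation and 90-degree rotation", {
  m <- raster_ellipse(14, 8)
  shifted <- matrix(0, nrow(m) + 10, ncol(m) + 4)
  shifted[11:(10 + nrow(m)), 3:(2 + ncol(m))] <- m
  expect_equal(as.numeric(eccentricity(m)), as.numeric(eccentricity(shifted)),
               tolerance = 1e-12)
  expect_equal(object_perimeter(m), object_perimeter(shifted))
  rotated <- t(m)
  expect_equal(as.numeric(eccentricity(m)), as.numeric(eccentricity(rotated)),
               tolerance = 1e-12)
  # arbitrary rotation: rasterise a rotated ellipse directly
  sz <- 61; cc <- 31; th <- pi / 5
  g <- expand.grid(r = 1:sz, c = 1:sz)
  u <- (g$r - cc) * cos(th) + (g$c - cc) * sin(th)
  v <- -(g$r - cc) * sin(th) + (g$c - cc) * cos(th)
  rot <- matrix(as.numeric((u / 14)^2 + (v / 8)^2 <= 1), sz, sz)
  expect_lt(abs(as.numeric(eccentricity(rot)) - as.numeric(eccentricity(m))),
            0.03)
})

test_that("region_props equals per-pixel oracles and flags border objects", {
  m <- matrix(0L, 40, 40)
  m[3:12, 3:12] <- 1L                 # interior square
  m[1:6, 30:38] <- 2L                 # touches border
  m[30, 30] <- 3L                     # single pixel
  img <- matrix(seq_len(1600) / 100, 40, 40)
  pr <- region_props(m, img)
  expect_equal(pr$area, c(100L, 54L, 1L))
  expect_true(pr$on_border[2])
  expect_true(is.na(pr$eccentricity[2]))   # clipped: shape undefined
  expect_true(is.na(pr$perimeter[3]))      # too small for shape metrics
  w1 <- which(m == 1L)
  expect_equal(pr$mean_intensity[1], mean(img[w1]))
  expect_equal(pr$total_intensity[1], sum(img[w1]))
  expect_equal(pr$centroid_row[1], mean(((w1 - 1) %% 40) + 1))
  sub <- matrix(0, 14, 14)
  sub[3:12, 3:12] <- 1
  expect_equal(pr$perimeter[1], object_perimeter(sub))
  expect_equal(pr$eccentricity[1], oracle_eccentricity(sub), tolerance = 1e-12)
})

test_that("texture variance is the population variance and scales as k^2", {
  expect_equal(texture_variance(matrix(7, 10, 10)), 0)
  set.seed(2)
  img <- matrix(rpois(400, 50), 20, 20)
  v <- texture_variance(img)
  expect_equal(v, mean((img - mean(img))^2))
  expect_equal(texture_variance(img * 3), 9 * v)
  mask <- matrix(FALSE, 20, 20)
  expect_error(texture_variance(img, mask), class = "gs_degenerate_input")
  mask[1:5, 1:5] <- TRUE
  expect_equal(texture_variance(img, mask),
               mean((img[mask] - mean(img[mask]))^2))
})

test_that("per-nucleus intensity divides total intensity by nucleus count", {
  img <- matrix(1, 20, 20)
  img[1, 1] <- 601   # total = 1000
  nuc <- label_mask(matrix(rep(c(0L, 1L, 0L, 2L, 3L, 0L, 4L, 0L), each = 50),
                           20, 20), kind = "nucleus", relabel = FALSE)
  m <- intensity_per_nucleus(img, nuc)
  expect_equal(m$intensity_per_nucleus, 250)
  m2 <- intensity_per_nucleus(img * 2, nuc)
  expect_equal(m2$intensity_per_nucleus, 500)
  empty <- label_mask(matrix(0L, 20, 20), kind = "nucleus")
  expect_warning(m3 <- intensity_per_nucleus(img, empty), "no segmented nuclei")
  expect_true(is.na(m3$intensity_per_nucleus))
  expect_equal(intensity_per_nucleus(matrix(0, 20, 20), nuc)$total_intensity, 0)
})
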