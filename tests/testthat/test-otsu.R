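test_that("a tri-modal image is partitioned with the bright mode as foreground", {
  img <- matrix(rep(c(0, 50, 200), each = 100), 30, 10)
  thr <- otsu_three_class(img)
  expect_gt(thr$t_low, 0)
  expect_lte(thr$t_low, 50)
  expect_gte(thr$t_high, 50)   # 50 itself stays in the (background) middle class
  expect_lt(thr$t_high, 200)
  fg <- img > thr$t_high
  expect_equal(sort(unique(img[fg])), 200)
  expect_equal(sum(fg), 100)
})

test_that("degenerate images are rejected", {
  expect_error(otsu_three_class(matrix(5, 10, 10)),
               class = "gs_degenerate_input")
  expect_error(otsu_three_class(matrix(c(1, 2), 10, 10)),
               class = "gs_degenerate_input")
})

test_that("the vectorised threshold search equals brute-force enumeration", {
  for (seed in 1:25) {
    img <- random_test_image(seed)
    thr <- otsu_three_class(img)
    orc <- oracle_otsu3(img)
    expect_equal(c(thr$bin_low, thr$bin_high),
                 c(orc$bin_low, orc$bin_high),
                 info = sprintf("seed %d", seed))
  }
})

test_that("minimum-threshold calibration takes the median reference t_high", {
  imgs <- lapply(c(10, 20, 90), function(peak) {
    m <- matrix(rep(c(0, peak / 2, peak), each = 200), 30, 20)
    m
  })
  t_highs <- vapply(imgs, function(m) otsu_three_class(m)$t_high, numeric(1))
  expect_equal(calibrate_min_threshold(imgs), median(t_highs))
  expect_equal(calibrate_min_threshold(imgs[1]), t_highs[1])
  expect_error(calibrate_min_threshold(list()), class = "gs_empty_reference")
})

test_that("the applied threshold is the max of t_high and the floor", {
  img <- matrix(rep(c(0, 50, 200), each = 100), 30, 10)
  thr <- otsu_three_class(img)
  low <- apply_threshold(img, thr, floor = thr$t_high - 10)
  expect_equal(low$applied, thr$t_high)
  high <- apply_threshold(img, thr, floor = thr$t_high + 30)
  expect_equal(high$applied, thr$t_high + 30)
  expect_lte(sum(high$foreground), sum(low$foreground))
})

test_that("raising the floor never increases the foreground area", {
  img <- random_test_image(99)
  thr <- otsu_three_class(img)
  areas <- vapply(seq(0, max(img), length.out = 8), function(f) {
    sum(apply_threshold(img, thr, floor = f)$foreground)
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("the threshold partition is invariant to intensity scaling", {
  img <- random_test_image(3)
  a <- otsu_three_class(img)
  b <- otsu_three_class(img * 7.3)
  expect_equal(c(a$bin_low, a$bin_high), c(b$bin_low, b$bin_high))
  expect_equal(b$t_high, a$t_high * 7.3, tolerance = 1e-10)
})
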