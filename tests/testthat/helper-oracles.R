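# Independent oracles and fixture builders used across the suite. These are
# deliberately naive re-derivations (brute force, per-pixel sums, EBImage
# contours) kept separate from the package's own code paths.

# Brute-force three-class Otsu: enumerate all (i, j) bin pairs and compute the
# between-class variance from first principles (weights and means per class,
# deviation from the global mean). Returns the bin indices of the maximiser
# with the same lexicographic tie-break the package documents.
oracle_otsu3 <- function(image, levels = 256L) {
  x <- as.numeric(image)
  lo <- min(x); hi <- max(x)
  w <- (hi - lo) / levels
  bin <- pmin(pmax(ceiling((x - lo) / w), 1L), levels)
  p <- tabulate(bin, nbins = levels) / length(x)
  mids <- lo + (seq_len(levels) - 0.5) * w
  mu_t <- sum(p * mids)
  best <- c(-Inf, NA, NA)
  for (i in 1:(levels - 2L)) {
    w1 <- sum(p[1:i])
    if (w1 == 0) next
    m1 <- sum(p[1:i] * mids[1:i]) / w1
    for (j in (i + 1L):(levels - 1L)) {
      w2 <- sum(p[(i + 1):j])
      w3 <- 1 - w1 - w2
      if (w2 == 0 || w3 <= 1e-15) next
      m2 <- sum(p[(i + 1):j] * mids[(i + 1):j]) / w2
      m3 <- sum(p[(j + 1):levels] * mids[(j + 1):levels]) / w3
      bcv <- w1 * (m1 - mu_t)^2 + w2 * (m2 - mu_t)^2 + w3 * (m3 - mu_t)^2
      if (bcv > best[1] + 1e-12) best <- c(bcv, i, j)
    }
  }
  list(bin_low = best[2], bin_high = best[3])
}

# Naive per-pixel second-moment eccentricity (explicit loops over pixels,
# closed-form eigenvalues), using the same pixel-as-unit-square convention
# the package documents.
oracle_eccentricity <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  n <- nrow(idx)
  mr <- sum(idx[, 1]) / n
  mc <- sum(idx[, 2]) / n
  c20 <- 0; c02 <- 0; c11 <- 0
  for (k in seq_len(n)) {
    c20 <- c20 + (idx[k, 1] - mr)^2
    c02 <- c02 + (idx[k, 2] - mc)^2
    c11 <- c11 + (idx[k, 1] - mr) * (idx[k, 2] - mc)
  }
  c20 <- c20 / n + 1 / 12
  c02 <- c02 / n + 1 / 12
  c11 <- c11 / n
  common <- sqrt(((c20 - c02) / 2)^2 + c11^2)
  l1 <- (c20 + c02) / 2 + common
  l2 <- (c20 + c02) / 2 - common
  unname(sqrt(1 - max(l2, 0) / l1))
}

# Perimeter oracle: EBImage's Moore contour tracing (independent code path)
# with the same corner-corrected chain-code weights.
oracle_perimeter <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  oc <- EBImage::ocontour(lab)[[1]]
  n <- nrow(oc)
  if (n < 2) return(NA_real_)
  nxt <- rbind(oc[-1, , drop = FALSE], oc[1, , drop = FALSE])
  st <- abs(nxt - oc)
  diag_step <- st[, 1] == 1 & st[, 2] == 1
  ax_step <- (st[, 1] + st[, 2]) == 1
  code <- atan2(nxt[, 2] - oc[, 2], nxt[, 1] - oc[, 1])
  corners <- sum(code != c(code[-1], code[1]))
  0.980 * sum(ax_step) + 1.406 * sum(diag_step) - 0.091 * corners
}

# Centred rasterisations on a pixel grid.
raster_ellipse <- function(a, b, pad = 6) {
  sz <- 2 * ceiling(a) + 2 * pad + 1
  cc <- (sz + 1) / 2
  g <- expand.grid(r = 1:sz, c = 1:sz)
  m <- matrix(as.numeric(((g$r - cc) / a)^2 + ((g$c - cc) / b)^2 <= 1), sz, sz)
  m
}
raster_disk <- function(r, pad = 6) raster_ellipse(r, r, pad)

# Greedy centroid matching of detections against planted ground truth.
match_counts <- function(det_rows, det_cols, truth_rows, truth_cols, tol = 3) {
  nd <- length(det_rows); nt <- length(truth_rows)
  if (nd == 0 || nt == 0) return(c(tp = 0, fp = nd, fn = nt))
  used <- rep(FALSE, nt); tp <- 0
  for (i in seq_len(nd)) {
    d <- sqrt((truth_rows - det_rows[i])^2 + (truth_cols - det_cols[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= tol) {
      used[j] <- TRUE
      tp <- tp + 1
    }
  }
  c(tp = tp, fp = nd - tp, fn = sum(!used))
}

f1_score <- function(m) as.numeric(2 * m["tp"] / (2 * m["tp"] + m["fp"] + m["fn"]))

# Random test images for the Otsu oracle property: mixtures of diffuse
# backgrounds and bright classes, quantised and continuous.
random_test_image <- function(seed, n = 64) {
  set.seed(seed)
  kind <- seed %% 4
  base <- switch(as.character(kind),
    "0" = matrix(runif(n * n, 0, 255), n, n),
    "1" = matrix(c(rnorm(n * n / 2, 40, 8), rnorm(n * n / 2, 160, 20)), n, n),
    "2" = matrix(sample(c(10, 90, 200), n * n, replace = TRUE,
                        prob = c(0.6, 0.3, 0.1)) + rnorm(n * n, 0, 4), n, n),
    "3" = matrix(round(rgamma(n * n, shape = 2, scale = 30)), n, n))
  pmax(base, 0)
}

# Planted-speckle F1 of the speckle detector on one generated scene.
scene_speckle_f1 <- function(spec, channel = "g3bp1") {
  out <- generate_micrograph(spec)
  det <- detect_speckles(get_channel(out$image, channel), speckle_params(),
                         stain = channel)
  tr <- out$truth[out$truth$kind == "speckle" & out$truth$channel == channel, ]
  rec <- det$records[det$records$retained, ]
  match_counts(rec$centroid_row, rec$centroid_col, tr$row, tr$col)
}
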