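test_that("angle sets are inclusive arithmetic sequences with validation", {
  a <- make_angle_set(-25, 25, 2.5)
  expect_length(a, 21)
  expect_equal(a[1], -25)
  expect_equal(a[21], 25)
  expect_true(all(diff(a) > 0))
  expect_length(make_angle_set(0, 180, 1), 181)
  expect_error(make_angle_set(0, 0, 1), "max_deg")
  expect_error(make_angle_set(0, 10, 3), "multiple")
  expect_error(make_angle_set(0, 10, -1), "step_deg")
})

test_that("the Radon transform is linear and vanishes on zero images", {
  z <- radon_transform(matrix(0, 64, 64))
  expect_true(all(z$data == 0))
  expect_equal(ncol(z$data), 21)
  set.seed(31)
  X <- matrix(runif(32 * 32), 32)
  Y <- matrix(runif(32 * 32), 32)
  ang <- make_angle_set(-25, 25, 5)
  lhs <- radon_transform(2.5 * X + 0.5 * Y, ang)$data
  rhs <- 2.5 * radon_transform(X, ang)$data + 0.5 * radon_transform(Y, ang)$data
  expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-6)
})

test_that("a central impulse projects to the central detector bin", {
  img <- matrix(0, 65, 65)
  img[33, 33] <- 1
  s <- radon_transform(img)
  sums <- colSums(s$data)
  expect_true(all(abs(sums - 1) < 0.1))
  center_bin <- (nrow(s$data) + 1) / 2
  expect_true(all(apply(s$data, 2, which.max) == center_bin))
})

test_that("the transform matches a brute-force line-integral oracle", {
  set.seed(11)
  img <- matrix(runif(33 * 33), 33)
  ang <- make_angle_set(-25, 25, 12.5)
  got <- radon_transform(img, ang)$data
  want <- oracle_radon(img, as.numeric(ang))
  expect_equal(dim(got), dim(want))
  expect_lt(max(abs(got - want)), 1e-8)
})

test_that("projections of rotationally symmetric objects are angle-invariant", {
  n <- 128
  cc <- (n - 1) / 2
  dist <- sqrt(outer((seq_len(n) - 1 - cc)^2, (seq_len(n) - 1 - cc)^2, "+"))
  ang <- make_angle_set(0, 175, 25)
  # smooth radial profile: invariance near machine-level interpolation error
  smooth <- radon_transform(exp(-dist^2 / (2 * 15^2)), ang)$data
  spread <- function(s) max(apply(s, 1, function(r) diff(range(r)))) / max(s)
  expect_lt(spread(smooth), 1e-3)
  # a hard-edged digital disk is itself not rotationally symmetric: the
  # attainable invariance is limited by pixelization, not the transform
  disk <- radon_transform((dist <= 30) + 0, ang)$data
  expect_lt(spread(disk), 3e-2)
})

test_that("radon rejects non-square and non-finite inputs", {
  expect_error(radon_transform(matrix(0, 32, 33)), "square")
  m <- matrix(0, 32, 32)
  m[5, 5] <- NA
  expect_error(radon_transform(m), "finite")
})

test_that("sinogram pairs are normalized, binary and co-registered", {
  smp <- make_lesion_sample(128, seed = 5)
  pair <- sinogram_pair(smp)
  expect_equal(min(pair$image_sino$data), 0)
  expect_equal(max(pair$image_sino$data), 1)
  expect_true(all(pair$mask_sino$data %in% c(0, 1)))
  expect_identical(dim(pair$image_sino$data), dim(pair$mask_sino$data))
  # empty mask is allowed (inference): mask sinogram all zero
  empty <- generate_phantom(128, "mammography", seed = 5)
  expect_true(all(sinogram_pair(empty)$mask_sino$data == 0))
  # an all-zero image has a constant sinogram and cannot be normalized
  const <- empty
  const$image[] <- 0
  expect_error(sinogram_pair(const), "constant")
})

test_that("a convex lesion traces a contiguous detector band at every angle", {
  smp <- make_lesion_sample(128, seed = 6, semi = c(9, 7), irregularity = 0)
  pair <- sinogram_pair(smp)
  for (j in seq_len(ncol(pair$mask_sino$data))) {
    nz <- which(pair$mask_sino$data[, j] == 1)
    if (length(nz) > 1) expect_equal(nz, seq(min(nz), max(nz)))
  }
})

test_that("an off-center lesion trace follows the projected center", {
  smp <- make_lesion_sample(128, seed = 6, center_off = c(-20, 14),
                            semi = c(5, 5))
  pair <- sinogram_pair(smp)
  ctr <- mask_centroid(smp$mask + 0)
  cc <- (nrow(pair$mask_sino$data) - 1) / 2
  cy <- (127) / 2
  peaks <- apply(pair$mask_sino$data, 2, function(col) mean(which(col == 1))) - 1
  pred <- vapply(as.numeric(pair$mask_sino$angles), function(th) {
    t <- (ctr$x_bar - cy) * cos(th * pi / 180) +
      (ctr$y_bar - cy) * sin(th * pi / 180)
    t + cc
  }, numeric(1))
  expect_lt(max(abs(peaks - pred)), 2.5)
  # monotone drift of the trace across the arc (small-angle regime)
  expect_true(all(diff(pred) > 0) || all(diff(pred) < 0))
  expect_true(cor(peaks, pred) > 0.99)
})

test_that("lesion-band extraction crops exactly and idempotently", {
  smp <- make_lesion_sample(128, seed = 7)
  pair <- sinogram_pair(smp)
  nz <- which(rowSums(pair$mask_sino$data) > 0)
  cropped <- extract_lesion_band(pair, margin = 10)
  expect_equal(cropped$band,
               c(max(1, min(nz) - 10), min(nrow(pair$mask_sino$data), max(nz) + 10)))
  expect_equal(nrow(cropped$image_sino$data), diff(cropped$band) + 1)
  tight <- extract_lesion_band(pair, margin = 0)
  expect_equal(tight$band, c(min(nz), max(nz)))
  again <- extract_lesion_band(tight, margin = 0)
  expect_identical(again$image_sino$data, tight$image_sino$data)
  expect_identical(again$band, tight$band)
  empty <- generate_phantom(128, "mammography", seed = 5)
  expect_error(extract_lesion_band(sinogram_pair(empty)), "full-sinogram")
})

test_that("normalize_resize maps to a unit-range square grid", {
  smp <- make_lesion_sample(128, seed = 8)
  pair <- sinogram_pair(smp)
  out <- normalize_resize(pair$image_sino, 64)
  expect_equal(dim(out), c(64, 64))
  expect_equal(range(out), c(0, 1))
  # already-normalized target-size input passes through unchanged
  expect_lt(max(abs(normalize_resize(out, 64) - out)), 1e-6)
  # constant input cannot be normalized
  expect_warning(z <- normalize_resize(matrix(1, 40, 40), 32), "constant")
  expect_true(all(z == 0))
  expect_error(normalize_resize(out, 8), "target")
})

test_that("bilinear resizing preserves monotone gradients", {
  g <- matrix(rep(seq(0, 1, length.out = 40), each = 40), 40)
  r <- normalize_resize(g, 32)
  expect_true(all(apply(r, 1, function(row) all(diff(row) >= -1e-12))))
  # spot-check the resize against the direct bilinear oracle
  m <- matrix(runif(25), 5)
  rs <- sinoseg:::bilinear_resize(m, 9, 9)
  ys <- seq(0, 4, length.out = 9)
  for (i in c(1, 4, 9)) {
    for (j in c(2, 7)) {
      expect_equal(rs[i, j], oracle_bilinear_at(m, ys[i], ys[j]),
                   tolerance = 1e-12)
    }
  }
})

test_that("sinogram mass equals image mass across seeded phantoms", {
  for (seed in 1:5) {
    smp <- generate_phantom(96, "mammography", seed)
    s <- radon_transform(smp$image)
    rel <- abs(colSums(s$data) - sum(smp$image)) / sum(smp$image)
    expect_lt(max(rel), 1e-2)
  }
})
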