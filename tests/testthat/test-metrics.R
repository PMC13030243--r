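test_that("Dice score matches counts, conventions and an oracle", {
  G <- matrix(0, 8, 8)
  G[2:4, 2:4] <- 1
  expect_equal(dice_score(G, G), 1, tolerance = 1e-4)
  P <- matrix(0, 8, 8)
  P[6:8, 6:8] <- 1
  expect_lt(dice_score(P, G), 1e-4)
  # |P| = |G| = 2, |intersection| = 1 -> 0.5
  P2 <- matrix(0, 2, 2)
  P2[1, 1] <- 1
  P2[1, 2] <- 1
  G2 <- matrix(0, 2, 2)
  G2[1, 1] <- 1
  G2[2, 1] <- 1
  expect_equal(dice_score(P2, G2), 0.5, tolerance = 1e-4)
  set.seed(1)
  for (i in 1:20) {
    A <- matrix(rbinom(64, 1, 0.3), 8)
    B <- matrix(rbinom(64, 1, 0.3), 8)
    expect_equal(dice_score(A, B), oracle_dice(A, B), tolerance = 1e-12)
    expect_equal(dice_score(A, B), dice_score(B, A))
  }
  expect_error(dice_score(matrix(0.5, 2, 2), matrix(0, 2, 2)), "binary")
})

test_that("IoU matches counting, the empty convention and an oracle", {
  G <- matrix(0, 4, 4)
  G[1:2, 1] <- 1
  G[1, 2] <- 1
  P <- matrix(0, 4, 4)
  P[1, 1] <- 1
  expect_equal(iou(P, G), 1 / 3)
  expect_equal(iou(G, G), 1)
  expect_equal(iou(matrix(0, 3, 3), matrix(0, 3, 3)), 1)
  set.seed(2)
  for (i in 1:20) {
    A <- matrix(rbinom(64, 1, 0.4), 8)
    B <- matrix(rbinom(64, 1, 0.4), 8)
    expect_equal(iou(A, B), oracle_iou(A, B), tolerance = 1e-12)
    expect_equal(iou(A, B), iou(B, A))
  }
})

test_that("the Dice-to-IoU conversion reproduces its fixed points and range", {
  expect_equal(round(iou_from_dice(0.90), 2), 0.82)
  expect_equal(round(iou_from_dice(0.70), 2), 0.54)
  expect_equal(iou_from_dice(0), 0)
  expect_equal(iou_from_dice(1), 1)
  expect_error(iou_from_dice(1.2), "0, 1")
})

test_that("mask centroids are exact pixel-coordinate means", {
  M <- matrix(0, 12, 12)
  M[6, 10] <- 1
  c1 <- mask_centroid(M)
  expect_equal(c(c1$y_bar, c1$x_bar, c1$n_pixels), c(5, 9, 1))
  B <- matrix(0, 4, 4)
  B[1:2, 1:2] <- 1
  c2 <- mask_centroid(B)
  expect_equal(c(c2$y_bar, c2$x_bar, c2$n_pixels), c(0.5, 0.5, 4))
  set.seed(3)
  R <- matrix(rbinom(100, 1, 0.3), 10)
  cr <- mask_centroid(R)
  co <- oracle_centroid(R)
  expect_equal(cr$y_bar, co$y_bar)
  expect_equal(cr$x_bar, co$x_bar)
  expect_equal(cr$n_pixels, co$n_pixels)
  expect_error(mask_centroid(matrix(0, 3, 3)), "empty")
})

test_that("centroid distance is Euclidean and symmetric", {
  a <- list(y_bar = 0, x_bar = 0)
  b <- list(y_bar = 3, x_bar = 4)
  expect_equal(centroid_distance(a, b), 5)
  expect_equal(centroid_distance(b, a), 5)
  expect_equal(centroid_distance(a, a), 0)
})

test_that("overlap percentage follows the diagonal normalization", {
  expect_equal(round(overlap_percent(5.86, 224, 224), 2), 98.15)
  expect_equal(overlap_percent(0, 224, 224), 100)
  expect_equal(overlap_percent(400, 224, 224), 0)
  d <- seq(0, sqrt(2) * 224, length.out = 50)
  v <- overlap_percent(d, 224, 224)
  expect_true(all(diff(v) < 0))
  expect_equal(overlap_percent(1000, 224, 224), 0)
})

test_that("cropped IoU excludes distant false positives", {
  G <- matrix(0, 40, 40)
  G[5:10, 5:10] <- 1
  P <- G
  expect_equal(cropped_iou(P, G, margin = 3), 1)
  P[35, 35] <- 1   # distant false positive
  expect_gt(cropped_iou(P, G, margin = 3), iou(P, G))
  expect_equal(cropped_iou(P, G, margin = 100), iou(P, G))
  expect_error(cropped_iou(P, matrix(0, 40, 40)), "empty")
})

test_that("per-lesion reports localize, match and flag correctly", {
  G <- matrix(0, 50, 50)
  G[5:10, 5:10] <- 1
  rep1 <- per_lesion_reports(G, G)
  expect_equal(nrow(rep1), 1)
  expect_equal(rep1$distance_px, 0)
  expect_equal(rep1$overlap_pct, 100)
  expect_equal(rep1$cropped_iou, 1)
  expect_true(rep1$matched)
  # second ground-truth lesion with no prediction is flagged, not zeroed
  G2 <- G
  G2[35:40, 35:40] <- 1
  rep2 <- per_lesion_reports(G, G2)
  expect_equal(nrow(rep2), 2)
  un <- rep2[!rep2$matched, ]
  expect_equal(nrow(un), 1)
  expect_true(is.na(un$centroid_pred_y))
  expect_equal(un$overlap_pct, 0)
  expect_equal(un$cropped_iou, 0)
})

test_that("multi-lesion matching minimizes total centroid distance", {
  G <- matrix(0, 60, 60)
  G[10:14, 10:14] <- 1   # lesion 1
  G[40:44, 40:44] <- 1   # lesion 2
  P <- matrix(0, 60, 60)
  P[20:24, 20:24] <- 1   # nearer lesion 1
  P[32:36, 32:36] <- 1   # nearer lesion 2
  rep <- per_lesion_reports(P, G)
  # exhaustive enumeration over both possible assignments
  cg <- list(c(11, 11), c(41, 41))
  cp <- list(c(21, 21), c(33, 33))
  d <- function(a, b) sqrt(sum((a - b)^2))
  tot1 <- d(cg[[1]], cp[[1]]) + d(cg[[2]], cp[[2]])
  tot2 <- d(cg[[1]], cp[[2]]) + d(cg[[2]], cp[[1]])
  want <- if (tot1 <= tot2) c(d(cg[[1]], cp[[1]]), d(cg[[2]], cp[[2]])) else
    c(d(cg[[1]], cp[[2]]), d(cg[[2]], cp[[1]]))
  expect_equal(sort(rep$distance_px), sort(want), tolerance = 1e-9)
  expect_true(all(rep$matched))
})

test_that("stored report fields reproduce the overlap percentage", {
  smp <- make_lesion_sample(96, seed = 12)
  pred <- smp$mask + 0
  rep <- per_lesion_reports(pred, smp$mask + 0, image_hw = c(224, 224))
  D <- sqrt(224^2 + 224^2)
  recomputed <- pmax(0, 100 * (1 - rep$distance_px / D))
  expect_equal(rep$overlap_pct, recomputed, tolerance = 1e-9)
})
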