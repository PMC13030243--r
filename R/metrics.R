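# Evaluation mathematics: Dice, IoU and their exact relationship, mask
# centroids, centroid distance, diagonal-normalized overlap percentage,
# lesion-cropped IoU, and per-lesion reports for multi-lesion images.

#' Dice score between binary masks
#'
#' \eqn{(2|P \cap G| + \epsilon) / (|P| + |G| + \epsilon)}.
#'
#' @param P,G Binary grids of identical shape.
#' @param eps Stabilizing constant (default 1e-5).
#' @return Scalar in (0, 1].
#' @export
dice_score <- function(P, G, eps = 1e-5) {
  assert_same_shape(P, G, "P and G")
  assert_binary(P, "P")
  assert_binary(G, "G")
  (2 * sum(P * G) + eps) / (sum(P) + sum(G) + eps)
}

#' Intersection over union (Jaccard index)
#'
#' \eqn{|P \cap G| / |P \cup G|}; two empty masks agree perfectly (1).
#'
#' @inheritParams dice_score
#' @return Scalar in `[0, 1]`.
#' @export
iou <- function(P, G) {
  assert_same_shape(P, G, "P and G")
  assert_binary(P, "P")
  assert_binary(G, "G")
  un <- sum(P + G > 0)
  if (un == 0) return(1)
  sum(P * G) / un
}

#' Convert a Dice score to IoU
#'
#' The exact set-theoretic relationship `IoU = Dice / (2 - Dice)`, which
#' holds whenever both are computed from the same overlap counts.
#'
#' @param dice Dice value(s) in `[0, 1]`.
#' @return IoU value(s) in `[0, 1]`.
#' @export
iou_from_dice <- function(dice) {
  if (any(dice < 0 | dice > 1)) stop("dice must lie in [0, 1]", call. = FALSE)
  dice / (2 - dice)
}

#' Centroid of a binary mask
#'
#' Mean 0-based (row, col) coordinate of the nonzero pixels.
#'
#' @param M Binary grid with at least one nonzero pixel.
#' @return A `mask_centroid`: `list(y_bar, x_bar, n_pixels)`.
#' @export
mask_centroid <- function(M) {
  assert_binary(M, "M")
  idx <- which(M == 1, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    stop("mask is empty: centroid undefined", call. = FALSE)
  }
  structure(list(y_bar = mean(idx[, 1]) - 1, x_bar = mean(idx[, 2]) - 1,
                 n_pixels = nrow(idx)),
            class = "mask_centroid")
}

#' @export
print.mask_centroid <- function(x, ...) {
  cat(sprintf("<mask_centroid> (%.2f, %.2f), N = %d\n", x$y_bar, x$x_bar,
              x$n_pixels))
  invisible(x)
}

#' Euclidean distance between two centroids
#'
#' @param c_ref,c_seg `mask_centroid` objects (or lists with `y_bar`,
#'   `x_bar`).
#' @return Distance in pixels.
#' @export
centroid_distance <- function(c_ref, c_seg) {
  sqrt((c_ref$y_bar - c_seg$y_bar)^2 + (c_ref$x_bar - c_seg$x_bar)^2)
}

#' Diagonal-normalized spatial overlap percentage
#'
#' `max(0, 100 * (1 - d / D))` with `D = sqrt(height^2 + width^2)` the
#' image diagonal. 100 means coincident centroids; 0 means a discrepancy
#' of at least one diagonal.
#'
#' @param d Centroid distance in pixels (>= 0).
#' @param height,width Evaluation image dimensions in pixels.
#' @return Percentage in `[0, 100]`.
#' @export
overlap_percent <- function(d, height, width) {
  stopifnot(all(d >= 0), height >= 1, width >= 1)
  pmax(0, 100 * (1 - d / sqrt(height^2 + width^2)))
}

gt_crop_box <- function(G, margin) {
  idx <- which(G == 1, arr.ind = TRUE)
  list(r = c(max(1, min(idx[, 1]) - margin), min(nrow(G), max(idx[, 1]) + margin)),
       c = c(max(1, min(idx[, 2]) - margin), min(ncol(G), max(idx[, 2]) + margin)))
}

#' IoU restricted to the lesion region
#'
#' IoU computed only inside the bounding box of the ground-truth mask,
#' expanded by `margin` pixels and clipped to the frame, so distant false
#' positives in a large background do not dominate the score.
#'
#' @inheritParams dice_score
#' @param margin Box expansion in pixels.
#' @return Scalar in `[0, 1]`.
#' @export
cropped_iou <- function(P, G, margin = 10) {
  assert_same_shape(P, G, "P and G")
  assert_binary(P, "P")
  assert_binary(G, "G")
  if (sum(G) == 0) stop("ground-truth mask is empty", call. = FALSE)
  b <- gt_crop_box(G, margin)
  iou(P[b$r[1]:b$r[2], b$c[1]:b$c[2], drop = FALSE],
      G[b$r[1]:b$r[2], b$c[1]:b$c[2], drop = FALSE])
}

# minimal-total-distance injective assignment of rows (GT) to columns
# (prediction); exhaustive for small problems, greedy otherwise
best_assignment <- function(cost) {
  nr <- nrow(cost)
  nc <- ncol(cost)
  k <- min(nr, nc)
  if (nr <= 6 && nc <= 6) {
    best <- NULL
    best_tot <- Inf
    rec <- function(row, used, acc, tot) {
      if (tot >= best_tot) return()
      if (row > nr || length(used) == nc) {
        if (tot < best_tot) {
          best_tot <<- tot
          best <<- acc
        }
        return()
      }
      for (j in setdiff(seq_len(nc), used)) {
        rec(row + 1, c(used, j), c(acc, stats::setNames(j, row)), tot + cost[row, j])
      }
      if (nr - row >= nc - length(used)) {
        rec(row + 1, used, c(acc, stats::setNames(NA_integer_, row)), tot)
      }
      invisible()
    }
    rec(1, integer(), integer(), 0)
    out <- rep(NA_integer_, nr)
    out[as.integer(names(best))] <- best
    return(out)
  }
  out <- rep(NA_integer_, nr)
  free_r <- seq_len(nr)
  free_c <- seq_len(nc)
  for (i in seq_len(k)) {
    sub <- cost[free_r, free_c, drop = FALSE]
    ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    out[free_r[ij[1]]] <- free_c[ij[2]]
    free_r <- free_r[-ij[1]]
    free_c <- free_c[-ij[2]]
  }
  out
}

#' Per-lesion localization reports
#'
#' Ground-truth lesions are the 8-connected components of `G`. Each is
#' matched one-to-one to the predicted component minimizing total centroid
#' distance (exhaustive for up to 6 lesions, greedy beyond). Unmatched
#' lesions are flagged with zero overlap percentage and cropped IoU and an
#' undefined predicted centroid.
#'
#' @inheritParams dice_score
#' @param image_hw (height, width) used for the diagonal normalization;
#'   defaults to the mask dimensions.
#' @param margin Crop margin for the per-lesion cropped IoU.
#' @param connectivity 4 or 8 (default) for component labeling.
#' @return A `localization_report` tibble, one row per ground-truth lesion:
#'   `lesion_id`, `centroid_gt_y/x`, `centroid_pred_y/x`, `distance_px`,
#'   `overlap_pct`, `cropped_iou`, `matched`, `image_h`, `image_w`.
#' @export
per_lesion_reports <- function(P, G, image_hw = dim(G), margin = 10,
                               connectivity = 8) {
  assert_same_shape(P, G, "P and G")
  assert_binary(P, "P")
  assert_binary(G, "G")
  if (sum(G) == 0) stop("ground-truth mask is empty", call. = FALSE)
  labG <- cpp_label_components(matrix(as.integer(G), nrow(G)), connectivity)
  labP <- cpp_label_components(matrix(as.integer(P), nrow(P)), connectivity)
  nG <- max(labG)
  nP <- max(labP)
  cg <- map(seq_len(nG), ~ mask_centroid((labG == .x) + 0))
  cp <- if (nP > 0) map(seq_len(nP), ~ mask_centroid((labP == .x) + 0)) else list()
  match_idx <- rep(NA_integer_, nG)
  if (nP > 0) {
    cost <- matrix(0, nG, nP)
    for (i in seq_len(nG)) {
      for (j in seq_len(nP)) cost[i, j] <- centroid_distance(cg[[i]], cp[[j]])
    }
    match_idx <- best_assignment(cost)
  }
  rows <- map(seq_len(nG), function(i) {
    Gi <- (labG == i) + 0
    j <- match_idx[i]
    if (is.na(j)) {
      tibble(lesion_id = i, centroid_gt_y = cg[[i]]$y_bar,
             centroid_gt_x = cg[[i]]$x_bar, centroid_pred_y = NA_real_,
             centroid_pred_x = NA_real_, distance_px = NA_real_,
             overlap_pct = 0, cropped_iou = 0, matched = FALSE)
    } else {
      d <- centroid_distance(cg[[i]], cp[[j]])
      b <- gt_crop_box(Gi, margin)
      ci <- iou(P[b$r[1]:b$r[2], b$c[1]:b$c[2], drop = FALSE],
                Gi[b$r[1]:b$r[2], b$c[1]:b$c[2], drop = FALSE])
      tibble(lesion_id = i, centroid_gt_y = cg[[i]]$y_bar,
             centroid_gt_x = cg[[i]]$x_bar, centroid_pred_y = cp[[j]]$y_bar,
             centroid_pred_x = cp[[j]]$x_bar, distance_px = d,
             overlap_pct = overlap_percent(d, image_hw[1], image_hw[2]),
             cropped_iou = ci, matched = TRUE)
    }
  })
  out <- bind_rows(rows)
  out$image_h <- image_hw[1]
  out$image_w <- image_hw[2]
  class(out) <- c("localization_report", class(out))
  out
}
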