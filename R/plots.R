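# ggplot2 views of the package's result types.

raster_df <- function(m) {
  tibble(y = rep(seq_len(nrow(m)) - 1, times = ncol(m)),
         x = rep(seq_len(ncol(m)) - 1, each = nrow(m)),
         value = as.vector(m))
}

#' Plot an image sample with its lesion contours
#'
#' @param object An `image_sample`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.image_sample <- function(object, ...) {
  df <- raster_df(object$image)
  p <- ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    scale_y_reverse() +
    coord_fixed() +
    labs(title = sprintf("%s / %s", object$patient_id %||% "sample",
                         object$modality), fill = "I") +
    theme_minimal()
  ct <- mask_contours(object$mask)
  if (nrow(ct) > 0) {
    p <- p + geom_path(data = ct,
                       aes(x = .data$x, y = .data$y, group = .data$component),
                       inherit.aes = FALSE, color = "red", linewidth = 0.4)
  }
  p
}

#' Plot a sinogram
#'
#' @param object A `sinogram`.
#' @param ... Unused.
#' @return A ggplot object (detector position on the vertical axis, angle
#'   on the horizontal, matching the package's sinogram convention).
#' @export
autoplot.sinogram <- function(object, ...) {
  df <- raster_df(object$data)
  df$angle <- as.numeric(object$angles)[df$x + 1]
  ggplot(df, aes(x = .data$angle, y = .data$y, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c() +
    scale_y_reverse() +
    labs(x = "projection angle (deg)", y = "detector position (px)",
         fill = "R f") +
    theme_minimal()
}

#' Plot training history
#'
#' Train/validation Dice per epoch with the selected epoch marked.
#'
#' @param object A `unet_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.unet_fit <- function(object, ...) {
  h <- object$history
  if (nrow(h) == 0) stop("empty training history", call. = FALSE)
  long <- bind_rows(
    tibble(epoch = h$epoch, metric = "train dice", value = h$train_dice),
    tibble(epoch = h$epoch, metric = "val dice", value = h$val_dice))
  ggplot(long, aes(x = .data$epoch, y = .data$value,
                   color = .data$metric)) +
    geom_line() +
    geom_vline(xintercept = object$best_epoch, linetype = "dashed",
               color = "grey40") +
    labs(y = "Dice", title = sprintf("best val Dice %.3f (epoch %d)",
                                     object$best_val_dice,
                                     object$best_epoch)) +
    theme_minimal()
}

#' Plot a localization report
#'
#' Centroid distance against lesion-cropped IoU, one point per lesion,
#' unmatched lesions shown at the top margin.
#'
#' @param object A `localization_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.localization_report <- function(object, ...) {
  df <- as_tibble(object)
  df$distance_plot <- ifelse(df$matched, df$distance_px,
                             max(df$distance_px, na.rm = TRUE) * 1.1)
  ggplot(df, aes(x = .data$distance_plot, y = .data$cropped_iou,
                 shape = .data$matched)) +
    geom_point(size = 2, alpha = 0.8) +
    labs(x = "centroid distance (px)", y = "cropped IoU",
         shape = "matched") +
    theme_minimal()
}
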