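# Training recipe: patient-level splits, on-the-fly augmentation, Adam with
# the fixed learning rate, and best-validation-Dice model selection.

#' Configure training
#'
#' Defaults follow the fixed optimization recipe used throughout: Adam at
#' learning rate 1e-4 with L2 weight decay 1e-6, batch size 16, 100 epochs
#' with no schedule or early stopping, and augmentation by random rotation
#' (within +/- 15 degrees), horizontal flipping and additive Gaussian noise,
#' each applied independently with probability `aug_prob`.
#'
#' @param lr Learning rate (> 0).
#' @param weight_decay L2 regularization strength.
#' @param batch_size Mini-batch size (>= 1).
#' @param epochs Number of epochs (0 returns the initial weights).
#' @param aug_rotation_deg Rotation half-range in degrees.
#' @param aug_hflip Enable horizontal flips.
#' @param aug_noise_sigma Additive noise standard deviation (image only).
#' @param aug_prob Per-transform application probability.
#' @param split_fractions Patient-level (train, val, test) fractions,
#'   positive and summing to 1.
#' @param seed Master seed for shuffling, augmentation and dropout.
#' @param input_config Which modality to train on: `"mammography"`,
#'   `"dbt"`, or `"combined"` (both sets pooled as independent
#'   single-channel examples).
#' @return A `train_config` object.
#' @export
train_config <- function(lr = 1e-4, weight_decay = 1e-6, batch_size = 16,
                         epochs = 100, aug_rotation_deg = 15,
                         aug_hflip = TRUE, aug_noise_sigma = 0.02,
                         aug_prob = 0.5,
                         split_fractions = c(0.7, 0.15, 0.15), seed = 1,
                         input_config = c("combined", "mammography", "dbt")) {
  input_config <- match.arg(input_config)
  if (lr <= 0) stop("lr must be > 0", call. = FALSE)
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  if (epochs < 0) stop("epochs must be >= 0", call. = FALSE)
  stopifnot(length(split_fractions) == 3)
  if (any(split_fractions <= 0) || abs(sum(split_fractions) - 1) > 1e-9) {
    stop("split_fractions must be positive and sum to 1", call. = FALSE)
  }
  structure(
    list(lr = lr, weight_decay = weight_decay,
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         aug_rotation_deg = aug_rotation_deg, aug_hflip = aug_hflip,
         aug_noise_sigma = aug_noise_sigma, aug_prob = aug_prob,
         split_fractions = split_fractions, seed = as.integer(seed),
         input_config = input_config),
    class = "train_config")
}

#' Split samples at the patient level
#'
#' Patients (never individual images) are shuffled by `seed` and
#' partitioned by `fractions`, so no patient contributes images to more
#' than one subset and all of a patient's modalities stay together. Every
#' subset receives at least one patient.
#'
#' @param samples List of `image_sample` objects (>= 3 distinct patients).
#' @param fractions (train, val, test) fractions.
#' @param seed Shuffle seed.
#' @return `list(train, val, test)` of sample lists; the patient assignment
#'   is attached as attribute `"patients"`.
#' @export
patient_level_split <- function(samples, fractions = c(0.7, 0.15, 0.15),
                                seed = 1) {
  pids <- map_chr(samples, "patient_id")
  up <- unique(pids)
  if (length(up) < 3) {
    stop("need >= 3 distinct patients for a three-way split", call. = FALSE)
  }
  perm <- withr::with_seed(as.integer(seed), sample(up))
  P <- length(up)
  n_tr <- max(1L, round(fractions[1] * P))
  n_va <- max(1L, round(fractions[2] * P))
  while (n_tr + n_va >= P) {
    if (n_tr >= n_va && n_tr > 1) n_tr <- n_tr - 1L
    else if (n_va > 1) n_va <- n_va - 1L
    else break
  }
  assign <- list(train = perm[seq_len(n_tr)],
                 val = perm[n_tr + seq_len(n_va)],
                 test = perm[(n_tr + n_va + 1):P])
  out <- map(assign, function(ids) samples[pids %in% ids])
  attr(out, "patients") <- assign
  out
}

#' Augment a training pair
#'
#' With independent probability `prob` each: rotate image and mask jointly
#' by a uniform angle in `[-rotation_deg, +rotation_deg]` (mask re-binarized
#' after interpolation), flip both horizontally, and add Gaussian noise to
#' the image only. The image is clipped back to `[0, 1]`. Uses the current
#' RNG state; wrap in a seeded context for reproducibility.
#'
#' @param image,mask Grids of identical shape, image in `[0, 1]`.
#' @param rotation_deg Rotation half-range.
#' @param hflip Allow horizontal flips.
#' @param noise_sigma Additive noise standard deviation.
#' @param prob Per-transform probability.
#' @return `list(image, mask)`.
#' @export
augment_pair <- function(image, mask, rotation_deg = 15, hflip = TRUE,
                         noise_sigma = 0.02, prob = 0.5) {
  assert_same_shape(image, mask, "image and mask")
  if (rotation_deg > 0 && runif(1) < prob) {
    th <- runif(1, -rotation_deg, rotation_deg)
    image <- clamp01(rotate_image(image, th))
    mask <- (rotate_image(mask, th) >= 0.5) + 0
  }
  if (hflip && runif(1) < prob) {
    image <- image[, rev(seq_len(ncol(image))), drop = FALSE]
    mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  }
  if (noise_sigma > 0 && runif(1) < prob) {
    image <- clamp01(image + rnorm(length(image), 0, noise_sigma))
  }
  list(image = image, mask = mask)
}

stack_pairs <- function(pairs, size) {
  n <- length(pairs)
  X <- array(0, dim = c(size, size, n))
  Y <- array(0, dim = c(size, size, n))
  for (i in seq_len(n)) {
    X[, , i] <- pairs[[i]]$image
    Y[, , i] <- pairs[[i]]$mask
  }
  list(X = X, Y = Y)
}

empty_history <- function() {
  tibble(epoch = integer(), train_loss = numeric(), train_dice = numeric(),
         val_dice = numeric())
}

#' Train the U-Net on sinogram pairs
#'
#' Minimizes the hybrid BCE + Dice loss with Adam over shuffled mini-batches.
#' After every epoch the validation Dice is computed on the predicted
#' probabilities (soft Dice, running batch-norm statistics, dropout off);
#' the weights with the highest validation Dice are retained, and the
#' final-epoch weights are kept alongside. Soft rather than thresholded
#' Dice is used for selection because it is the lower-variance estimator of
#' the same overlap: with validation sets of ten-odd images the thresholded
#' score swings by tens of points between epochs and can hand selection to
#' an immature early epoch. The run is reproducible from `config$seed`.
#'
#' @param model A freshly built [build_unet()] model.
#' @param train_pairs,val_pairs Lists of `list(x = input grid, y = binary
#'   target grid)` at the model's input size.
#' @param config A [train_config()].
#' @return A `unet_fit`: best model, per-epoch `history` tibble
#'   (`epoch`, `train_loss`, `train_dice`, `val_dice`), `best_epoch`,
#'   `best_val_dice`, and the training config.
#' @export
train_unet <- function(model, train_pairs, val_pairs, config = train_config()) {
  model <- as_unet_model(model)
  stopifnot(inherits(config, "train_config"))
  if (length(train_pairs) == 0 || length(val_pairs) == 0) {
    stop("train and validation sets must be non-empty", call. = FALSE)
  }
  size <- model$config$input_size
  for (p in c(train_pairs, val_pairs)) {
    if (!all(dim(p$x) == c(size, size))) {
      stop("pair grids must match the model input size", call. = FALSE)
    }
  }
  params <- model$params
  zeros <- map(params, function(a) {
    z <- a
    z[] <- 0
    z
  })
  m <- zeros
  v <- zeros
  history <- empty_history()
  best_params <- params
  best_val <- -Inf
  best_epoch <- NA_integer_
  step <- 0L
  n <- length(train_pairs)
  val_x <- stack_pairs(map(val_pairs, ~ list(image = .x$x, mask = .x$y)), size)

  for (epoch in seq_len(config$epochs)) {
    ep <- withr::with_seed(derive_seed(config$seed, paste0("epoch", epoch)), {
      ord <- sample(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      tot_loss <- 0
      tot_dice <- 0
      for (bi in batches) {
        aug <- map(train_pairs[bi], function(p) {
          augment_pair(p$x, p$y, config$aug_rotation_deg, config$aug_hflip,
                       config$aug_noise_sigma, config$aug_prob)
        })
        batch <- stack_pairs(aug, size)
        step <- step + 1L
        res <- cpp_unet_train_batch(
          params, m, v, step, model$config, batch$X, batch$Y,
          config$lr, config$weight_decay,
          sample.int(2147483646L, 1))
        params <- res$params
        m <- res$m
        v <- res$v
        tot_loss <- tot_loss + res$loss * length(bi)
        tot_dice <- tot_dice + res$dice_hard * length(bi)
      }
      list(loss = tot_loss / n, dice = tot_dice / n)
    })
    cur <- structure(list(config = model$config, params = params),
                     class = "unet_model")
    pv <- unet_forward(cur, val_x$X)
    # soft Dice on the probabilities: at small validation sizes the
    # thresholded score is too noisy to rank epochs reliably
    vd <- mean(map_dbl(seq_along(val_pairs), function(i) {
      dice_soft(pv[, , i], val_x$Y[, , i])
    }))
    history <- bind_rows(history, tibble(
      epoch = epoch, train_loss = ep$loss, train_dice = ep$dice,
      val_dice = vd))
    if (vd > best_val) {
      best_val <- vd
      best_epoch <- epoch
      best_params <- params
    }
  }
  if (config$epochs == 0) {
    best_params <- params
    best_val <- NA_real_
  }
  structure(
    list(model = structure(list(config = model$config, params = best_params),
                           class = "unet_model"),
         final_model = structure(list(config = model$config, params = params),
                                 class = "unet_model"),
         history = history, best_epoch = best_epoch, best_val_dice = best_val,
         train_config = config),
    class = "unet_fit")
}

#' @export
print.unet_fit <- function(x, ...) {
  cat(sprintf("<unet_fit> %d epoch(s); best val Dice %.4f at epoch %s\n",
              nrow(x$history), x$best_val_dice,
              ifelse(is.na(x$best_epoch), "<none>", x$best_epoch)))
  invisible(x)
}

#' @rdname train_unet
#' @param x A `unet_fit`.
#' @param ... Unused.
#' @export
tidy.unet_fit <- function(x, ...) x$history

#' @rdname train_unet
#' @export
glance.unet_fit <- function(x, ...) {
  tibble(epochs = nrow(x$history), best_epoch = x$best_epoch,
         best_val_dice = x$best_val_dice,
         n_parameters = n_parameters(x$model))
}

#' Evaluate a model on test pairs
#'
#' Thresholded predictions are scored against the ground-truth mask
#' sinograms with Dice and IoU.
#'
#' @param object A `unet_fit` or `unet_model`.
#' @param test_pairs Non-empty list of `list(x, y)` pairs.
#' @param threshold Prediction threshold.
#' @return A tibble with one row per pair (`sample`, `dice`, `iou`) and the
#'   means in attribute `"means"`.
#' @export
evaluate_model <- function(object, test_pairs, threshold = 0.5) {
  model <- as_unet_model(object)
  if (length(test_pairs) == 0) stop("test set is empty", call. = FALSE)
  rows <- imap(test_pairs, function(p, i) {
    pred <- predict_mask(model, p$x, threshold)
    tibble(sample = i, dice = dice_score(pred, p$y), iou = iou(pred, p$y))
  })
  out <- bind_rows(rows)
  attr(out, "means") <- c(dice = mean(out$dice), iou = mean(out$iou))
  out
}
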