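# U-Net surface: configuration, parameter initialization, forward pass and
# the hybrid BCE + Dice objective. The compiled engine (src/unet.cpp) does
# the heavy lifting; parameters live in an R list of named arrays so models
# are plain serializable data.

#' Configure the segmentation U-Net
#'
#' A symmetric encoder-decoder: `depth` encoder blocks of two 3x3
#' convolutions (each batch-norm + ReLU) with dropout and 2x2 max-pooling,
#' a two-convolution bottleneck, and `depth` decoder blocks of upsampling,
#' a 3x3 convolution, skip concatenation and a merging 3x3 convolution,
#' finished by a 1x1 convolution with sigmoid. Channel widths double per
#' level from `base_channels`.
#'
#' @param in_channels Input channels (sinograms are single-channel).
#' @param depth Number of encoder levels.
#' @param base_channels Channels at the first level.
#' @param dropout_p Dropout probability in `[0, 1)`, applied at the end of
#'   every encoder, bottleneck and decoder block.
#' @param upsample_mode `"nearest"` (upsample then convolution) or
#'   `"bilinear"`.
#' @param input_size Square input side; must be divisible by `2^depth`.
#' @return A `unet_config` object.
#' @export
unet_config <- function(in_channels = 1, depth = 4, base_channels = 32,
                        dropout_p = 0.2,
                        upsample_mode = c("nearest", "bilinear"),
                        input_size = 128) {
  upsample_mode <- match.arg(upsample_mode)
  if (input_size %% 2^depth != 0) {
    stop(sprintf("input_size must be divisible by 2^depth = %d", 2^depth),
         call. = FALSE)
  }
  if (dropout_p < 0 || dropout_p >= 1) {
    stop("dropout_p must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(in_channels = as.integer(in_channels), depth = as.integer(depth),
         base_channels = as.integer(base_channels), dropout_p = dropout_p,
         upsample_mode = upsample_mode, input_size = as.integer(input_size)),
    class = "unet_config")
}

# named list of parameter array dims, in a fixed order
unet_param_shapes <- function(config) {
  d <- config$depth
  base <- config$base_channels
  shapes <- list()
  bn <- function(stem, c) {
    s <- list()
    s[[paste0(stem, "_gamma")]] <- c
    s[[paste0(stem, "_beta")]] <- c
    s[[paste0(stem, "_rm")]] <- c
    s[[paste0(stem, "_rv")]] <- c
    s
  }
  for (k in seq_len(d)) {
    cin <- if (k == 1) config$in_channels else base * 2^(k - 2)
    cout <- base * 2^(k - 1)
    s <- paste0("enc", k)
    shapes[[paste0(s, "_conv1_W")]] <- c(3, 3, cin, cout)
    shapes[[paste0(s, "_conv1_b")]] <- cout
    shapes <- c(shapes, bn(paste0(s, "_bn1"), cout))
    shapes[[paste0(s, "_conv2_W")]] <- c(3, 3, cout, cout)
    shapes[[paste0(s, "_conv2_b")]] <- cout
    shapes <- c(shapes, bn(paste0(s, "_bn2"), cout))
  }
  cb <- base * 2^(d - 1)
  shapes[["bot_conv1_W"]] <- c(3, 3, cb, cb)
  shapes[["bot_conv1_b"]] <- cb
  shapes <- c(shapes, bn("bot_bn1", cb))
  shapes[["bot_conv2_W"]] <- c(3, 3, cb, cb)
  shapes[["bot_conv2_b"]] <- cb
  shapes <- c(shapes, bn("bot_bn2", cb))
  for (k in rev(seq_len(d))) {
    cout <- base * 2^(k - 1)
    prev <- if (k == d) cb else base * 2^k
    s <- paste0("dec", k)
    shapes[[paste0(s, "_upconv_W")]] <- c(3, 3, prev, cout)
    shapes[[paste0(s, "_upconv_b")]] <- cout
    shapes <- c(shapes, bn(paste0(s, "_bnu"), cout))
    shapes[[paste0(s, "_mergeconv_W")]] <- c(3, 3, 2 * cout, cout)
    shapes[[paste0(s, "_mergeconv_b")]] <- cout
    shapes <- c(shapes, bn(paste0(s, "_bnm"), cout))
  }
  shapes[["head_W"]] <- c(1, 1, base, 1)
  shapes[["head_b"]] <- 1
  shapes
}

#' Build a U-Net with freshly initialized weights
#'
#' He-normal initialization for convolution kernels, unit batch-norm scale,
#' zero shifts and biases. The parameter count is a pure function of the
#' configuration.
#'
#' @param config A [unet_config()].
#' @param seed Integer seed for the weight draw.
#' @return A `unet_model`: `list(config, params)`.
#' @export
build_unet <- function(config = unet_config(), seed = 1) {
  stopifnot(inherits(config, "unet_config"))
  shapes <- unet_param_shapes(config)
  params <- withr::with_seed(as.integer(seed), {
    imap(shapes, function(dm, nm) {
      n <- prod(dm)
      v <- if (grepl("_W$", nm)) {
        fan_in <- if (length(dm) == 4) prod(dm[1:3]) else n
        rnorm(n, 0, sqrt(2 / fan_in))
      } else if (grepl("_gamma$|_rv$", nm)) {
        rep(1, n)
      } else {
        rep(0, n)
      }
      if (length(dm) > 1) array(v, dim = dm) else v
    })
  })
  structure(list(config = config, params = params), class = "unet_model")
}

#' Count trainable parameters
#'
#' @param model A `unet_model` or `unet_fit`.
#' @return Number of trainable parameters (batch-norm running statistics
#'   excluded).
#' @export
n_parameters <- function(model) {
  model <- as_unet_model(model)
  nm <- names(model$params)
  sum(map_int(model$params[!grepl("_rm$|_rv$", nm)], length))
}

as_unet_model <- function(object) {
  if (inherits(object, "unet_fit")) return(object$model)
  stopifnot(inherits(object, "unet_model"))
  object
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf(
    "<unet_model> depth %d, base %d, input %dx%d, dropout %.2f, %s upsampling, %s parameters\n",
    x$config$depth, x$config$base_channels, x$config$input_size,
    x$config$input_size, x$config$dropout_p, x$config$upsample_mode,
    format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

check_input_dims <- function(model, x) {
  s <- model$config$input_size
  d <- dim(x)
  if (is.null(d) || d[1] != s || d[2] != s) {
    stop(sprintf("input must be %dx%d (got %s)", s, s,
                 paste(d, collapse = "x")), call. = FALSE)
  }
}

#' Forward pass through the network
#'
#' @param model A `unet_model` or `unet_fit`.
#' @param x Input grid (`input_size x input_size` matrix) or an
#'   `input_size x input_size x B` array, values in `[0, 1]`.
#' @param training Use batch statistics and dropout (TRUE) or running
#'   statistics with dropout off (FALSE).
#' @param dropout_seed Seed for the dropout mask when `training`.
#' @return Sigmoid probabilities with the shape of `x`, all in (0, 1).
#' @export
unet_forward <- function(model, x, training = FALSE, dropout_seed = 0) {
  model <- as_unet_model(model)
  check_input_dims(model, x)
  cpp_unet_forward(model$params, model$config, x, training,
                   as.integer(dropout_seed))
}

#' Predict a binary mask
#'
#' @inheritParams unet_forward
#' @param threshold Probability threshold (default 0.5).
#' @return Binary grid of the input shape.
#' @export
predict_mask <- function(model, x, threshold = 0.5) {
  p <- unet_forward(model, x, training = FALSE)
  (p > threshold) + 0
}

#' Binary cross-entropy over pixels
#'
#' Mean over pixels of \eqn{-[G \log P + (1 - G)\log(1 - P)]}, with
#' predictions clamped to `[eps, 1 - eps]`.
#'
#' @param pred Probability grid.
#' @param target Binary grid of the same shape.
#' @param eps Clamping constant.
#' @return Nonnegative scalar.
#' @export
bce_loss <- function(pred, target, eps = 1e-7) {
  assert_same_shape(pred, target, "pred and target")
  p <- pmin(pmax(pred, eps), 1 - eps)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

#' Soft Dice coefficient
#'
#' \eqn{(2\sum P_i G_i + \epsilon) / (\sum P_i + \sum G_i + \epsilon)};
#' two empty grids agree perfectly (value 1) through the stabilizing
#' constant.
#'
#' @inheritParams bce_loss
#' @param eps Stabilizing constant (default 1e-5).
#' @return Scalar in (0, 1].
#' @export
dice_soft <- function(pred, target, eps = 1e-5) {
  assert_same_shape(pred, target, "pred and target")
  (2 * sum(pred * target) + eps) / (sum(pred) + sum(target) + eps)
}

#' Hybrid BCE + Dice objective
#'
#' `total = bce + (1 - dice_term)`, balancing pixel-wise fidelity against
#' global region overlap.
#'
#' @inheritParams bce_loss
#' @return A `loss_value` with fields `bce`, `dice_term`, `total`.
#' @export
combined_loss <- function(pred, target) {
  b <- bce_loss(pred, target)
  d <- dice_soft(pred, target)
  structure(list(bce = b, dice_term = d, total = b + (1 - d)),
            class = "loss_value")
}

#' @export
print.loss_value <- function(x, ...) {
  cat(sprintf("<loss_value> total %.4f = bce %.4f + (1 - dice %.4f)\n",
              x$total, x$bce, x$dice_term))
  invisible(x)
}
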