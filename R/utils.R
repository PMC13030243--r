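# Shared numeric helpers. Coordinates are 0-based (row, col) with pixel
# centers at integer positions throughout the package.

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Derive a stage seed from a master seed
#'
#' Deterministically maps a master seed and a stage label to a new 32-bit
#' seed, so pipeline stages can be rerun in isolation with independent
#' randomness.
#'
#' @param seed Integer master seed.
#' @param label Character stage label.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  h <- as.double(seed) %% 2147483647
  for (c in utf8ToInt(label)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

# Bilinear sampling of `img` at fractional 0-based coordinates (y, x).
# Points outside the image contribute zero.
bilinear_sample <- function(img, y, x) {
  h <- nrow(img)
  w <- ncol(img)
  y0 <- floor(y)
  x0 <- floor(x)
  fy <- y - y0
  fx <- x - x0
  acc <- numeric(length(y))
  for (dy in 0:1) {
    for (dx in 0:1) {
      yy <- y0 + dy
      xx <- x0 + dx
      wgt <- (if (dy == 1) fy else 1 - fy) * (if (dx == 1) fx else 1 - fx)
      ok <- yy >= 0 & yy < h & xx >= 0 & xx < w & wgt > 0
      if (any(ok)) {
        v <- numeric(length(y))
        v[ok] <- img[cbind(yy[ok] + 1, xx[ok] + 1)] * wgt[ok]
        acc <- acc + v
      }
    }
  }
  dim(acc) <- dim(y)
  acc
}

# Corner-aligned bilinear resize; an identity when sizes already match.
bilinear_resize <- function(m, out_h, out_w) {
  if (nrow(m) == out_h && ncol(m) == out_w) return(m)
  yg <- if (out_h == 1) (nrow(m) - 1) / 2 else seq(0, nrow(m) - 1, length.out = out_h)
  xg <- if (out_w == 1) (ncol(m) - 1) / 2 else seq(0, ncol(m) - 1, length.out = out_w)
  Y <- matrix(yg, out_h, out_w)
  X <- matrix(xg, out_h, out_w, byrow = TRUE)
  bilinear_sample(m, Y, X)
}

# Rotate an image by `angle_deg` (counter-clockwise in (row, col) space)
# about its center, sampling bilinearly; out-of-frame pixels become zero.
rotate_image <- function(m, angle_deg) {
  if (angle_deg == 0) return(m)
  h <- nrow(m)
  w <- ncol(m)
  cy <- (h - 1) / 2
  cx <- (w - 1) / 2
  th <- angle_deg * pi / 180
  dy <- matrix(seq_len(h) - 1 - cy, h, w)
  dx <- matrix(seq_len(w) - 1 - cx, h, w, byrow = TRUE)
  sy <- cy + cos(th) * dy + sin(th) * dx
  sx <- cx - sin(th) * dy + cos(th) * dx
  bilinear_sample(m, sy, sx)
}

smoothstep <- function(t) {
  t <- clamp01(t)
  t * t * (3 - 2 * t)
}

# Otsu's threshold on values in [0, 1]
otsu_threshold <- function(x, nbins = 256) {
  x <- as.vector(x)
  h <- tabulate(pmin(pmax(floor(x * nbins) + 1, 1), nbins), nbins)
  p <- h / sum(h)
  mids <- (seq_len(nbins) - 0.5) / nbins
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[nbins]
  between <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

assert_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s must have identical shapes (%s vs %s)", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
         call. = FALSE)
  }
}

assert_binary <- function(m, name = "mask") {
  if (!all(m %in% c(0, 1))) {
    stop(sprintf("%s must be strictly binary {0, 1}", name), call. = FALSE)
  }
}
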