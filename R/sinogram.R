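# Sinogram construction under the limited-angle tomosynthesis geometry.
# Convention (fixed package-wide): sinogram rows index detector position t,
# columns index projection angle theta; the detector axis spans the image
# diagonal with unit-spaced bins and t = 0 at the central bin.

#' Build an ordered set of projection angles
#'
#' Inclusive arithmetic sequence of angles in degrees. The default geometry
#' is the limited tomosynthesis arc: -25 to +25 degrees in steps of 2.5,
#' giving 21 projections.
#'
#' @param min_deg,max_deg Arc limits in degrees, `max_deg > min_deg`.
#' @param step_deg Positive increment; the span must be an integer multiple
#'   of it (tolerance 1e-9).
#' @return An `angle_set`: a strictly increasing numeric vector of degrees.
#' @export
make_angle_set <- function(min_deg = -25, max_deg = 25, step_deg = 2.5) {
  if (step_deg <= 0) stop("step_deg must be > 0", call. = FALSE)
  if (max_deg <= min_deg) stop("max_deg must be > min_deg", call. = FALSE)
  k <- (max_deg - min_deg) / step_deg
  if (abs(k - round(k)) > 1e-9 * max(1, abs(k))) {
    stop("(max_deg - min_deg) must be an integer multiple of step_deg",
         call. = FALSE)
  }
  structure(min_deg + step_deg * (0:round(k)), class = "angle_set")
}

#' @export
print.angle_set <- function(x, ...) {
  cat(sprintf("<angle_set> %d angles: %g .. %g deg\n", length(x), x[1],
              x[length(x)]))
  invisible(x)
}

new_sinogram <- function(data, angles, source_shape, normalized = FALSE) {
  structure(list(data = data, angles = angles,
                 source_shape = as.integer(source_shape),
                 normalized = normalized),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d detector bins x %d angles (source %dx%d%s)\n",
              nrow(x$data), ncol(x$data), x$source_shape[1], x$source_shape[2],
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' @export
dim.sinogram <- function(x) dim(x$data)

#' Parallel-beam Radon transform
#'
#' Computes line-integral projections of a square image for each angle in
#' `angles`. For angle \eqn{\theta} and detector position \eqn{t} the
#' integral runs along \eqn{(x, y) = (t\cos\theta - s\sin\theta,\;
#' t\sin\theta + s\cos\theta)}, sampled bilinearly at sub-pixel steps.
#' Projections outside the inscribed circle are retained (no circular
#' masking), so the sum of every column equals the total image mass up to
#' interpolation error.
#'
#' @param image Square numeric matrix with finite entries.
#' @param angles An [make_angle_set()] result (degrees).
#' @param s_substeps Integration substeps per pixel along the ray
#'   (accuracy/cost trade-off; 2 keeps mass conservation well under 1%).
#' @return A `sinogram` (rows = detector bins spanning the image diagonal,
#'   columns = angles).
#' @export
radon_transform <- function(image, angles = make_angle_set(), s_substeps = 2) {
  if (!is.matrix(image)) stop("image must be a matrix", call. = FALSE)
  if (nrow(image) != ncol(image)) {
    stop("image must be square; pad non-square inputs first", call. = FALSE)
  }
  if (!all(is.finite(image))) stop("image contains non-finite values", call. = FALSE)
  data <- cpp_radon(image, as.numeric(angles), as.integer(s_substeps))
  new_sinogram(data, angles, dim(image))
}

#' Build a co-registered image/mask sinogram pair
#'
#' The image sinogram is min-max normalized to `[0, 1]`; the mask sinogram
#' is the Radon transform of the binary mask binarized at `mask_threshold`
#' times its own maximum (a relative threshold: any ray whose intersection
#' with the lesion is at least that fraction of the longest intersection
#' counts as lesion-bearing).
#'
#' @param sample An `image_sample`.
#' @param angles Projection angles.
#' @param mask_threshold Relative binarization threshold in (0, 1).
#' @return A `sinogram_pair`.
#' @export
sinogram_pair <- function(sample, angles = make_angle_set(),
                          mask_threshold = 0.05) {
  stopifnot(inherits(sample, "image_sample"))
  img_sino <- radon_transform(sample$image, angles)
  rng <- range(img_sino$data)
  if (diff(rng) == 0) {
    stop("constant image: sinogram cannot be min-max normalized", call. = FALSE)
  }
  img_sino$data <- (img_sino$data - rng[1]) / diff(rng)
  img_sino$normalized <- TRUE
  mask_sino <- radon_transform(sample$mask + 0, angles)
  mx <- max(mask_sino$data)
  mask_sino$data <- if (mx > 0) (mask_sino$data >= mask_threshold * mx) + 0 else
    mask_sino$data
  structure(
    list(image_sino = img_sino, mask_sino = mask_sino,
         sample_ref = list(patient_id = sample$patient_id,
                           modality = sample$modality),
         band = NULL, full_rows = nrow(img_sino$data)),
    class = "sinogram_pair")
}

#' @export
print.sinogram_pair <- function(x, ...) {
  cat(sprintf("<sinogram_pair> %dx%d, patient %s (%s)%s\n",
              nrow(x$image_sino$data), ncol(x$image_sino$data),
              x$sample_ref$patient_id %||% "<none>", x$sample_ref$modality,
              if (!is.null(x$band)) sprintf(", band rows %d..%d of %d",
                                            x$band[1], x$band[2], x$full_rows)
              else ""))
  invisible(x)
}

#' Crop a sinogram pair to its lesion band
#'
#' Restricts both sinograms to the minimal detector-row interval containing
#' every nonzero mask-sinogram row, expanded by `margin` rows and clipped to
#' the detector range. The angle dimension is untouched. The crop window is
#' recorded in `$band` (1-based row interval) so predictions can be mapped
#' back to full detector coordinates.
#'
#' @param pair A [sinogram_pair()].
#' @param margin Extra detector rows on each side.
#' @return The cropped pair.
#' @export
extract_lesion_band <- function(pair, margin = 10) {
  stopifnot(inherits(pair, "sinogram_pair"), margin >= 0)
  nz <- which(rowSums(pair$mask_sino$data) > 0)
  if (length(nz) == 0) {
    stop("mask sinogram is empty; run in full-sinogram mode instead",
         call. = FALSE)
  }
  r0 <- max(1, min(nz) - margin)
  r1 <- min(nrow(pair$mask_sino$data), max(nz) + margin)
  prior <- if (is.null(pair$band)) c(1L, pair$full_rows) else pair$band
  pair$image_sino$data <- pair$image_sino$data[r0:r1, , drop = FALSE]
  pair$mask_sino$data <- pair$mask_sino$data[r0:r1, , drop = FALSE]
  pair$band <- c(prior[1] + r0 - 1L, prior[1] + r1 - 1L)
  pair
}

#' Resize a sinogram to a square model input
#'
#' Bilinear resize to `target x target` followed by min-max normalization to
#' `[0, 1]`. A constant input cannot be normalized and maps to all zeros
#' with a warning.
#'
#' @param sino A `sinogram` or plain matrix.
#' @param target Output side in pixels (>= 16).
#' @return A `target x target` matrix in `[0, 1]`.
#' @export
normalize_resize <- function(sino, target = 128) {
  if (target < 16) stop("target must be >= 16", call. = FALSE)
  m <- if (inherits(sino, "sinogram")) sino$data else sino
  out <- bilinear_resize(m, target, target)
  rng <- range(out)
  # relative tolerance: interpolating a constant grid leaves ~1e-16 ripple
  if (diff(rng) <= 1e-12 * max(1, abs(rng[2]))) {
    warning("constant input: returning all-zero grid")
    return(matrix(0, target, target))
  }
  (out - rng[1]) / diff(rng)
}
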