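# Synthetic breast phantoms: an elliptical support region with smooth
# low-frequency tissue texture and one or more hyperintense (mass-like)
# lesions. A "dbt" mode lowers global contrast and adds detector noise so the
# two modalities differ the way single DBT slices differ from mammograms.

#' Specify a synthetic lesion
#'
#' Describes one elliptical, optionally boundary-perturbed, hyperintense
#' lesion. The perturbation is a fixed low-order harmonic of the boundary
#' angle, so a spec fully determines its rasterization.
#'
#' @param center_yx Numeric length-2, 0-based (row, col) center in pixels.
#' @param semi_axes Numeric length-2 semi-axes (a, b) in pixels, both >= 2.
#' @param rotation_deg Rotation of the ellipse axes in degrees.
#' @param contrast Additive intensity in (0, 1]; lesions are hyperintense.
#' @param boundary_irregularity Amplitude (>= 0) of the radial boundary
#'   perturbation; 0 gives an exact ellipse.
#' @return A `lesion_spec` object.
#' @export
lesion_spec <- function(center_yx, semi_axes, rotation_deg = 0,
                        contrast = 0.4, boundary_irregularity = 0) {
  stopifnot(length(center_yx) == 2, length(semi_axes) == 2)
  if (any(semi_axes < 2)) stop("semi_axes must both be >= 2 px", call. = FALSE)
  if (contrast <= 0 || contrast > 1) {
    stop("contrast must lie in (0, 1]: lesions are hyperintense", call. = FALSE)
  }
  if (boundary_irregularity < 0) stop("boundary_irregularity must be >= 0", call. = FALSE)
  structure(
    list(center_yx = as.numeric(center_yx), semi_axes = as.numeric(semi_axes),
         rotation_deg = as.numeric(rotation_deg), contrast = as.numeric(contrast),
         boundary_irregularity = as.numeric(boundary_irregularity)),
    class = "lesion_spec")
}

new_image_sample <- function(image, mask, patient_id, modality,
                             lesions = list(), support = NULL) {
  structure(
    list(image = image, mask = mask, patient_id = patient_id,
         modality = modality, lesions = lesions, support = support),
    class = "image_sample")
}

#' @export
print.image_sample <- function(x, ...) {
  cat(sprintf("<image_sample> %dx%d %s, patient %s, %d lesion(s), %d mask px\n",
              nrow(x$image), ncol(x$image), x$modality,
              x$patient_id %||% "<none>", length(x$lesions), sum(x$mask)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Generate a lesion-free breast phantom
#'
#' Builds a square image in `[0, 1]` with an elliptical breast support
#' region (covering well over 30% of the frame) filled with smooth
#' low-frequency tissue texture that fades towards the support boundary.
#' In `"dbt"` mode the in-support contrast is compressed by
#' `dbt_contrast_scale` and additive Gaussian detector noise of standard
#' deviation `dbt_noise_sigma` is applied, emulating the noisier, lower
#' contrast appearance of single tomosynthesis slices.
#'
#' @param size Image side in pixels (>= 64).
#' @param modality `"mammography"` or `"dbt"`.
#' @param seed Integer seed; output is a pure function of the arguments.
#' @param dbt_noise_sigma Noise standard deviation for `"dbt"` mode.
#' @param dbt_contrast_scale Contrast multiplier in (0, 1] for `"dbt"` mode.
#' @return An [image_sample][lesion_spec] with an all-zero mask.
#' @export
generate_phantom <- function(size = 256, modality = c("mammography", "dbt"),
                             seed = 1, dbt_noise_sigma = 0.03,
                             dbt_contrast_scale = 0.6) {
  if (!is.numeric(size) || length(size) != 1 || size < 64) {
    stop("size must be a single number >= 64", call. = FALSE)
  }
  size <- as.integer(size)
  modality <- match.arg(modality)
  withr::with_seed(as.integer(seed), {
    cy <- (size - 1) / 2 + runif(1, -0.02, 0.02) * size
    cx <- (size - 1) / 2 + runif(1, -0.02, 0.02) * size
    a <- 0.40 * size * (1 + runif(1, -0.05, 0.05))
    b <- 0.33 * size * (1 + runif(1, -0.05, 0.05))
    n <- ceiling(size / 16)
    tex <- matrix(rnorm(n * n), n, n)
    tex <- bilinear_resize(tex, size, size)
    tex <- (tex - mean(tex)) / max(sd(tex), 1e-12)

    dy <- matrix(seq_len(size) - 1 - cy, size, size)
    dx <- matrix(seq_len(size) - 1 - cx, size, size, byrow = TRUE)
    ell <- sqrt((dy / a)^2 + (dx / b)^2)
    support <- ell <= 1
    wnd <- smoothstep((1 - ell) / 0.12)
    img <- (0.45 + 0.10 * tex) * wnd
    img[!support] <- 0
    img <- clamp01(img)
    if (modality == "dbt") {
      mu <- mean(img[support])
      img[support] <- mu + dbt_contrast_scale * (img[support] - mu)
      img <- clamp01(img + rnorm(size * size, 0, dbt_noise_sigma))
    }
    new_image_sample(img, matrix(0L, size, size), patient_id = NA_character_,
                     modality = modality,
                     support = list(cy = cy, cx = cx, a = a, b = b))
  })
}

in_support <- function(sample, y, x) {
  s <- sample$support
  if (is.null(s)) {
    return(y >= 0 & y < nrow(sample$image) & x >= 0 & x < ncol(sample$image))
  }
  ((y - s$cy) / s$a)^2 + ((x - s$cx) / s$b)^2 <= 1
}

#' Add a lesion to a phantom
#'
#' Raises intensities inside the (possibly boundary-perturbed) ellipse by
#' `spec$contrast` with a raised-cosine falloff towards the boundary, clips
#' to `[0, 1]`, and marks the interior in the mask.
#'
#' @param sample An [image_sample][lesion_spec].
#' @param spec A [lesion_spec()].
#' @return The modified sample, with `spec` appended to `sample$lesions`.
#' @export
add_lesion <- function(sample, spec) {
  stopifnot(inherits(sample, "image_sample"), inherits(spec, "lesion_spec"))
  y0 <- spec$center_yx[1]
  x0 <- spec$center_yx[2]
  if (!in_support(sample, y0, x0)) {
    stop("lesion center lies outside the breast support region", call. = FALSE)
  }
  h <- nrow(sample$image)
  w <- ncol(sample$image)
  a <- spec$semi_axes[1]
  b <- spec$semi_axes[2]
  irr <- spec$boundary_irregularity
  rmax <- max(a, b) * (1 + irr) + 2
  ry <- max(1, floor(y0 - rmax) + 1):min(h, ceiling(y0 + rmax) + 1)
  rx <- max(1, floor(x0 - rmax) + 1):min(w, ceiling(x0 + rmax) + 1)
  ddy <- matrix(ry - 1 - y0, length(ry), length(rx))
  ddx <- matrix(rx - 1 - x0, length(ry), length(rx), byrow = TRUE)
  r <- spec$rotation_deg * pi / 180
  u <- cos(r) * ddy + sin(r) * ddx
  v <- -sin(r) * ddy + cos(r) * ddx
  rho <- sqrt((u / a)^2 + (v / b)^2)
  phi <- atan2(v, u)
  pert <- 1 + irr * (0.6 * sin(3 * phi + 3 * r + 1.7) +
                     0.4 * sin(5 * phi + 5 * r + 0.4))
  inside <- rho <= pert
  if (!any(inside)) stop("lesion rasterized to zero pixels", call. = FALSE)
  fall <- 0.5 * (1 + cos(pi * pmin(rho / pert, 1)))
  patch <- sample$image[ry, rx]
  patch[inside] <- patch[inside] + spec$contrast * fall[inside]
  sample$image[ry, rx] <- clamp01(patch)
  mpatch <- sample$mask[ry, rx]
  mpatch[inside] <- 1L
  sample$mask[ry, rx] <- mpatch
  sample$lesions <- c(sample$lesions, list(spec))
  sample
}

#' Configure a synthetic phantom dataset
#'
#' Defaults describe the study conditions used throughout: 60 patients with
#' two annotated views each (the standard craniocaudal/mediolateral pair of
#' a screening study) at 256 px, a DBT fraction of 0.2 (the roughly 1:4
#' ratio of annotated DBT to mammography images in public archives), one or
#' two masses per image, and the DBT degradation defaults.
#'
#' @param n_patients Number of synthetic patients (>= 3 so that three-way
#'   patient-level splits exist).
#' @param images_per_patient Images per patient.
#' @param image_size Square image side in pixels.
#' @param modality_mix Fraction of DBT samples in `[0, 1]`.
#' @param lesion_count_range Integer (min, max) lesions per image.
#' @param dbt_noise_sigma,dbt_contrast_scale DBT degradation parameters;
#'   the contrast scale must not exceed 1 (DBT lesions are never more
#'   conspicuous than mammography lesions).
#' @param seed Master seed for the dataset.
#' @return A `phantom_config` object.
#' @export
phantom_config <- function(n_patients = 60, images_per_patient = 2,
                           image_size = 256, modality_mix = 0.2,
                           lesion_count_range = c(1, 2),
                           dbt_noise_sigma = 0.03, dbt_contrast_scale = 0.6,
                           seed = 1) {
  if (n_patients < 3) stop("n_patients must be >= 3", call. = FALSE)
  if (images_per_patient < 1) stop("images_per_patient must be >= 1", call. = FALSE)
  if (image_size < 64) stop("image_size must be >= 64", call. = FALSE)
  if (modality_mix < 0 || modality_mix > 1) {
    stop("modality_mix must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(length(lesion_count_range) == 2)
  if (lesion_count_range[1] < 0 || diff(lesion_count_range) < 0) {
    stop("lesion_count_range must be nonnegative and nondecreasing", call. = FALSE)
  }
  if (dbt_contrast_scale <= 0 || dbt_contrast_scale > 1) {
    stop("dbt_contrast_scale must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(n_patients = as.integer(n_patients),
         images_per_patient = as.integer(images_per_patient),
         image_size = as.integer(image_size), modality_mix = modality_mix,
         lesion_count_range = as.integer(lesion_count_range),
         dbt_noise_sigma = dbt_noise_sigma,
         dbt_contrast_scale = dbt_contrast_scale, seed = as.integer(seed)),
    class = "phantom_config")
}

# seed for sample (p, j): decoupled per sample so datasets are stable when
# patients or images are added or reordered
sample_seed <- function(seed, p, j) {
  as.integer((as.double(seed) + p * 100003 + j * 1009) %% 2147483647)
}

#' Generate a seeded synthetic dataset
#'
#' Produces `n_patients * images_per_patient` annotated samples. Modalities
#' are assigned deterministically by global sample index so that a fraction
#' `modality_mix` of samples is DBT; each sample draws its own RNG stream
#' from `(seed, patient, image)`.
#'
#' @param config A [phantom_config()].
#' @return A `phantom_dataset`: a list of samples with the config attached.
#' @export
generate_dataset <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  samples <- vector("list", config$n_patients * config$images_per_patient)
  s <- 0L
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%03d", p)
    for (j in seq_len(config$images_per_patient)) {
      dbt <- floor((s + 1) * config$modality_mix) - floor(s * config$modality_mix) >= 1
      modality <- if (dbt) "dbt" else "mammography"
      sseed <- sample_seed(config$seed, p, j)
      smp <- generate_phantom(config$image_size, modality, sseed,
                              config$dbt_noise_sigma, config$dbt_contrast_scale)
      smp$patient_id <- pid
      smp <- withr::with_seed(sample_seed(config$seed, p, j + 7919L), {
        lo <- config$lesion_count_range[1]
        hi <- config$lesion_count_range[2]
        nles <- if (lo == hi) lo else sample(lo:hi, 1)
        for (k in seq_len(nles)) {
          ang <- runif(1, 0, 2 * pi)
          rr <- sqrt(runif(1)) * 0.75
          ctr <- c(smp$support$cy + rr * smp$support$a * cos(ang),
                   smp$support$cx + rr * smp$support$b * sin(ang))
          ax <- pmax(2, runif(2, 5, 14) * config$image_size / 256)
          ctr_contrast <- runif(1, 0.25, 0.55) *
            (if (dbt) config$dbt_contrast_scale else 1)
          smp <- add_lesion(smp, lesion_spec(
            center_yx = ctr, semi_axes = ax, rotation_deg = runif(1, 0, 180),
            contrast = ctr_contrast, boundary_irregularity = runif(1, 0, 0.2)))
        }
        smp
      })
      s <- s + 1L
      samples[[s]] <- smp
    }
  }
  structure(samples, class = "phantom_dataset", config = config)
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<phantom_dataset> %d samples, %d patients, %d px, %.0f%% dbt\n",
              length(x), cfg$n_patients, cfg$image_size,
              100 * mean(map_chr(x, "modality") == "dbt")))
  invisible(x)
}

#' Summarize a phantom dataset as a tibble
#'
#' @param x A `phantom_dataset`.
#' @param ... Unused.
#' @return One row per sample: patient, modality, lesion count, mask area.
#' @export
as_tibble.phantom_dataset <- function(x, ...) {
  tibble(
    sample = seq_along(x),
    patient_id = map_chr(x, "patient_id"),
    modality = map_chr(x, "modality"),
    n_lesions = map_int(x, ~ length(.x$lesions)),
    mask_px = map_int(x, ~ as.integer(sum(.x$mask))))
}
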