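# Interchange formats, all plain files: PNG (8/16-bit) or TSV images and
# masks with a JSONL metadata file per dataset; sinograms as TSV matrices
# with a JSON sidecar sharing the file stem; reports as CSV plus a JSON
# mirror; model checkpoints as RDS with a config hash.

#' Write a phantom dataset to disk
#'
#' Creates `images/<stem>.png`, `masks/<stem>.png` and a `metadata.jsonl`
#' with one JSON record per sample (stem, patient, modality, lesion specs).
#'
#' @param dataset A `phantom_dataset` or list of `image_sample`s.
#' @param dir Output directory.
#' @param overwrite Allow writing into an existing directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, overwrite = FALSE) {
  if (dir.exists(dir) && !overwrite) {
    stop(sprintf("'%s' exists; pass overwrite = TRUE to replace it", dir),
         call. = FALSE)
  }
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  meta_path <- file.path(dir, "metadata.jsonl")
  con <- file(meta_path, "w")
  on.exit(close(con))
  for (i in seq_along(dataset)) {
    smp <- dataset[[i]]
    stem <- sprintf("s%04d", i)
    png::writePNG(clamp01(smp$image), file.path(dir, "images", paste0(stem, ".png")))
    png::writePNG(smp$mask + 0, file.path(dir, "masks", paste0(stem, ".png")))
    rec <- list(stem = stem, patient_id = smp$patient_id,
                modality = smp$modality,
                lesions = map(smp$lesions, unclass))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return List of `image_sample` objects.
#' @export
read_dataset <- function(dir) {
  meta_path <- file.path(dir, "metadata.jsonl")
  if (!file.exists(meta_path)) {
    stop(sprintf("no metadata.jsonl under '%s'", dir), call. = FALSE)
  }
  map(readLines(meta_path), function(line) {
    rec <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    smp <- read_image_mask_pair(file.path(dir, "images", paste0(rec$stem, ".png")),
                                file.path(dir, "masks", paste0(rec$stem, ".png")))
    smp$patient_id <- rec$patient_id
    smp$modality <- rec$modality
    smp$lesions <- map(rec$lesions, function(l) {
      lesion_spec(unlist(l$center_yx), unlist(l$semi_axes), l$rotation_deg,
                  l$contrast, l$boundary_irregularity)
    })
    smp
  })
}

read_gray <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    tsv = as.matrix(read.delim(path, header = FALSE)),
    stop(sprintf("unreadable format '.%s' (supported: png, tiff, tsv)", ext),
         call. = FALSE))
  if (length(dim(img)) == 3) img <- img[, , 1]
  unname(img)
}

#' Read an image/mask pair as an `image_sample`
#'
#' PNG and TIFF intensities arrive already scaled to `[0, 1]` by bit depth;
#' TSV matrices are taken as-is. Masks are binarized at strictly positive
#' values. Image and mask shapes must agree.
#'
#' @param image_path,mask_path File paths (`.png`, `.tif(f)` or `.tsv`).
#' @return An `image_sample` (no patient/lesion metadata).
#' @export
read_image_mask_pair <- function(image_path, mask_path) {
  img <- read_gray(image_path)
  msk <- (read_gray(mask_path) > 0) + 0L
  if (!identical(dim(img), dim(msk))) {
    stop(sprintf("image/mask shape mismatch: %s vs %s",
                 paste(dim(img), collapse = "x"),
                 paste(dim(msk), collapse = "x")), call. = FALSE)
  }
  new_image_sample(img, msk, patient_id = NA_character_,
                   modality = "mammography")
}

#' Write a sinogram as TSV + JSON sidecar
#'
#' Produces `<stem>.sino.tsv` (rows = detector bins, columns = angles) and
#' `<stem>.sino.json` recording the angle list, source shape and
#' normalization flag.
#'
#' @param sino A `sinogram`.
#' @param stem Path stem (no extension).
#' @return The stem, invisibly.
#' @export
write_sinogram <- function(sino, stem) {
  stopifnot(inherits(sino, "sinogram"))
  utils::write.table(sino$data, paste0(stem, ".sino.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(angles_deg = as.numeric(sino$angles),
         source_shape = sino$source_shape, normalized = sino$normalized),
    paste0(stem, ".sino.json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Read a sinogram written by [write_sinogram()]
#'
#' @param stem Path stem used at write time.
#' @return A `sinogram`.
#' @export
read_sinogram <- function(stem) {
  tsv <- paste0(stem, ".sino.tsv")
  side <- paste0(stem, ".sino.json")
  if (!file.exists(tsv) || !file.exists(side)) {
    stop(sprintf("missing sinogram files for stem '%s'", stem), call. = FALSE)
  }
  meta <- jsonlite::fromJSON(side)
  new_sinogram(unname(as.matrix(read.delim(tsv, header = FALSE))),
               structure(meta$angles_deg, class = "angle_set"),
               meta$source_shape, isTRUE(meta$normalized))
}

#' Write a localization report as CSV + JSON
#'
#' Numeric columns are rounded to 2 decimal places (the reporting
#' precision); unmatched lesions keep explicit NA/null predicted-centroid
#' fields. Refuses an empty report.
#'
#' @param report A `localization_report` (or any tibble of per-lesion rows).
#' @param stem Path stem; writes `<stem>.csv` and `<stem>.json`.
#' @return The stem, invisibly.
#' @export
write_report <- function(report, stem) {
  if (nrow(report) == 0) stop("refusing to write an empty report", call. = FALSE)
  rep2 <- as.data.frame(report)
  num <- vapply(rep2, is.numeric, logical(1))
  rep2[num] <- lapply(rep2[num], function(v) round(v, 2))
  utils::write.csv(rep2, paste0(stem, ".csv"), row.names = FALSE, na = "")
  jsonlite::write_json(rep2, paste0(stem, ".json"), dataframe = "rows",
                       na = "null", digits = NA)
  invisible(stem)
}

#' Read a report written by [write_report()]
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_report <- function(path) {
  as_tibble(read.csv(path))
}

unet_config_hash <- function(config) {
  paste(unlist(config), collapse = "|")
}

#' Save / load a U-Net checkpoint
#'
#' A single RDS archive of weights plus configuration; loading validates
#' the stored config hash so a checkpoint cannot silently be attached to a
#' different architecture.
#'
#' @param object A `unet_model` or `unet_fit` (its best model is saved).
#' @param path Checkpoint path (`.rds`).
#' @return `path` (save) or a `unet_model` (load).
#' @export
save_unet <- function(object, path) {
  model <- as_unet_model(object)
  saveRDS(list(config = model$config, params = model$params,
               hash = unet_config_hash(model$config)), path)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$hash, unet_config_hash(ck$config))) {
    stop("checkpoint config hash mismatch: file is corrupt or altered",
         call. = FALSE)
  }
  structure(list(config = ck$config, params = ck$params),
            class = "unet_model")
}
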