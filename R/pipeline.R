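# End-to-end orchestration: phantoms -> sinogram pairs -> patient split ->
# training -> prediction -> FBP localization -> reports. One master seed
# fans out to per-stage seeds so stages can be rerun in isolation.

#' Configure the full pipeline
#'
#' Aggregates every stage's settings. Three sizes matter: `radon_input`
#' (spatial standardization before the Radon transform, default 256),
#' `model_input` (network input, default 128) and `eval_image` (frame for
#' the localization metrics' diagonal, default 224).
#'
#' @param phantom A [phantom_config()]; its `image_size` is forced to
#'   `sizes$radon_input`.
#' @param angles Numeric `c(min, max, step)` in degrees.
#' @param sizes List with `radon_input`, `model_input`, `eval_image`.
#' @param unet A [unet_config()]; its `input_size` is forced to
#'   `sizes$model_input`.
#' @param train A [train_config()].
#' @param recon List with `filter`, `binarize`, `rel`.
#' @param metrics List with `crop_margin`, `connectivity`.
#' @param band_margin Detector rows kept around the lesion band.
#' @param mask_threshold Relative mask-sinogram binarization threshold.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_config(),
                            angles = c(-25, 25, 2.5),
                            sizes = list(radon_input = 256, model_input = 128,
                                         eval_image = 224),
                            unet = unet_config(),
                            train = train_config(),
                            recon = list(filter = "ramp",
                                         binarize = "rel_threshold", rel = 0.2),
                            metrics = list(crop_margin = 10, connectivity = 8),
                            band_margin = 10, mask_threshold = 0.05) {
  if (sizes$model_input %% 2^unet$depth != 0) {
    stop("model_input must be divisible by 2^depth", call. = FALSE)
  }
  phantom$image_size <- as.integer(sizes$radon_input)
  unet$input_size <- as.integer(sizes$model_input)
  structure(
    list(phantom = phantom, angles = angles, sizes = sizes, unet = unet,
         train = train, recon = recon, metrics = metrics,
         band_margin = band_margin, mask_threshold = mask_threshold),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; omitted keys
#' keep their defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$phantom)) args$phantom <- do.call(phantom_config, y$phantom)
  if (!is.null(y$angles)) args$angles <- as.numeric(unlist(y$angles))
  if (!is.null(y$sizes)) args$sizes <- utils::modifyList(
    list(radon_input = 256, model_input = 128, eval_image = 224), y$sizes)
  if (!is.null(y$unet)) args$unet <- do.call(unet_config, y$unet)
  if (!is.null(y$train)) args$train <- do.call(train_config, y$train)
  if (!is.null(y$recon)) args$recon <- utils::modifyList(
    list(filter = "ramp", binarize = "rel_threshold", rel = 0.2), y$recon)
  if (!is.null(y$metrics)) args$metrics <- utils::modifyList(
    list(crop_margin = 10, connectivity = 8), y$metrics)
  if (!is.null(y$band_margin)) args$band_margin <- y$band_margin
  if (!is.null(y$mask_threshold)) args$mask_threshold <- y$mask_threshold
  do.call(pipeline_config, args)
}

#' Build model-ready sinogram pairs from samples
#'
#' For each sample: sinogram pair, lesion-band crop, bilinear resize of
#' both grids to the model input size (mask re-binarized at 0.5). The band
#' window, detector size and source shape are kept so predictions can be
#' mapped back to full detector coordinates.
#'
#' @param samples List of `image_sample`s (non-empty masks).
#' @param angles An [make_angle_set()] result.
#' @param band_margin Detector rows around the lesion band.
#' @param model_input Network input size.
#' @param mask_threshold Relative mask-sinogram threshold.
#' @return A list of records: `x`, `y`, `band`, `full_rows`,
#'   `source_shape`, `patient_id`, `modality`, `sample_index`.
#' @export
build_sinogram_set <- function(samples, angles = make_angle_set(),
                               band_margin = 10, model_input = 128,
                               mask_threshold = 0.05) {
  imap(samples, function(smp, i) {
    pair <- sinogram_pair(smp, angles, mask_threshold)
    pair <- extract_lesion_band(pair, band_margin)
    x <- normalize_resize(pair$image_sino, model_input)
    y <- (bilinear_resize(pair$mask_sino$data, model_input, model_input) >= 0.5) + 0
    list(x = x, y = y, band = pair$band, full_rows = pair$full_rows,
         source_shape = pair$image_sino$source_shape,
         patient_id = smp$patient_id, modality = smp$modality,
         sample_index = i)
  })
}

#' Map a model-space prediction back to a full-detector mask sinogram
#'
#' Resizes the prediction to the band window, re-binarizes at 0.5 and
#' embeds it into an all-zero full-height sinogram.
#'
#' @param pred Binary (or probability) grid at model input size.
#' @param record A [build_sinogram_set()] record.
#' @param angles Projection angles.
#' @return A binary `sinogram` of full detector height.
#' @export
embed_band_prediction <- function(pred, record, angles = make_angle_set()) {
  bh <- record$band[2] - record$band[1] + 1
  band <- (bilinear_resize(pred, bh, length(angles)) >= 0.5) + 0
  full <- matrix(0, record$full_rows, length(angles))
  full[record$band[1]:record$band[2], ] <- band
  new_sinogram(full, angles, record$source_shape)
}

resize_binary <- function(mask, h, w) {
  (bilinear_resize(mask + 0, h, w) >= 0.5) + 0
}

#' Localize predicted lesions for a test set
#'
#' For every test record: predict the sinogram mask, map it back to full
#' detector coordinates, reconstruct a spatial mask by filtered
#' backprojection, then compare against the ground-truth spatial mask with
#' per-lesion centroid metrics at the evaluation frame size.
#'
#' @param object A `unet_fit` or `unet_model`.
#' @param records Test records from [build_sinogram_set()].
#' @param samples The sample list the records index into.
#' @param angles Projection angles.
#' @param eval_hw (height, width) evaluation frame, default `c(224, 224)`.
#' @param recon `list(binarize, rel)` reconstruction settings.
#' @param crop_margin,connectivity Metric settings.
#' @return A `localization_report` tibble with sample/patient/modality
#'   columns prepended.
#' @export
localize_test_set <- function(object, records, samples,
                              angles = make_angle_set(),
                              eval_hw = c(224, 224),
                              recon = list(binarize = "rel_threshold", rel = 0.2),
                              crop_margin = 10, connectivity = 8) {
  model <- as_unet_model(object)
  rows <- map(records, function(rec) {
    pred <- predict_mask(model, rec$x)
    sino <- embed_band_prediction(pred, rec, angles)
    pmask <- reconstruct_mask(sino, recon$binarize, recon$rel)
    G <- samples[[rec$sample_index]]$mask
    P224 <- resize_binary(pmask, eval_hw[1], eval_hw[2])
    G224 <- resize_binary(G, eval_hw[1], eval_hw[2])
    rep <- per_lesion_reports(P224, G224, image_hw = eval_hw,
                              margin = crop_margin,
                              connectivity = connectivity)
    rep$sample_index <- rec$sample_index
    rep$patient_id <- rec$patient_id
    rep$modality <- rec$modality
    rep
  })
  out <- bind_rows(rows)
  class(out) <- c("localization_report", class(out))
  out
}

filter_modality <- function(samples, input_config) {
  if (input_config == "combined") return(samples)
  samples[map_chr(samples, "modality") == input_config]
}

log_line <- function(con, stage, msg) {
  writeLines(sprintf("%s\t%s\t%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                     stage, msg), con)
  flush(con)
}

run_stage <- function(con, stage, expr) {
  log_line(con, stage, "start")
  res <- tryCatch(expr, error = function(e) {
    log_line(con, stage, paste0("error: ", conditionMessage(e)))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  log_line(con, stage, "done")
  res
}

#' Run the full pipeline
#'
#' Executes phantoms, sinogram pairs, patient-level split, training,
#' test-set prediction, FBP localization and report writing, persisting
#' every artifact (resolved config, history, checkpoint, evaluation table,
#' per-lesion report, structured log) under `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory; must not exist unless `force = TRUE`.
#' @param force Overwrite an existing run directory.
#' @return Invisibly, `list(out_dir, fit, evaluation, report)`.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (dir.exists(out_dir) && !force) {
    stop(sprintf("run directory '%s' exists; use force = TRUE", out_dir),
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(con))
  log_line(con, "env", sprintf("%s; sinoseg %s", R.version.string,
                               utils::packageVersion("sinoseg")))
  seed0 <- config$phantom$seed
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  angles <- make_angle_set(config$angles[1], config$angles[2], config$angles[3])
  ds <- run_stage(con, "phantoms", generate_dataset(config$phantom))
  used <- run_stage(con, "modality_filter",
                    filter_modality(ds, config$train$input_config))
  split <- run_stage(con, "split", patient_level_split(
    used, config$train$split_fractions, derive_seed(seed0, "split")))
  sets <- run_stage(con, "sinograms", map(split, function(ss) {
    build_sinogram_set(ss, angles, config$band_margin,
                       config$sizes$model_input, config$mask_threshold)
  }))
  to_pairs <- function(recs) map(recs, ~ list(x = .x$x, y = .x$y))
  fit <- run_stage(con, "train", {
    model <- build_unet(config$unet, derive_seed(seed0, "init"))
    tc <- config$train
    tc$seed <- derive_seed(seed0, "train")
    train_unet(model, to_pairs(sets$train), to_pairs(sets$val), tc)
  })
  utils::write.csv(fit$history, file.path(out_dir, "history.csv"),
                   row.names = FALSE)
  save_unet(fit, file.path(out_dir, "checkpoint.rds"))
  evaluation <- run_stage(con, "evaluate",
                          evaluate_model(fit, to_pairs(sets$test)))
  utils::write.csv(evaluation, file.path(out_dir, "evaluation.csv"),
                   row.names = FALSE)
  report <- run_stage(con, "localize", localize_test_set(
    fit, sets$test, split$test, angles,
    eval_hw = c(config$sizes$eval_image, config$sizes$eval_image),
    recon = config$recon, crop_margin = config$metrics$crop_margin,
    connectivity = config$metrics$connectivity))
  run_stage(con, "report", write_report(report, file.path(out_dir, "report")))
  log_line(con, "pipeline", "complete")
  invisible(list(out_dir = out_dir, fit = fit, evaluation = evaluation,
                 report = report))
}
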