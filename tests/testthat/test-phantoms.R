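test_that("phantom generation is a pure function of its arguments", {
  a <- generate_phantom(128, "mammography", seed = 7)
  b <- generate_phantom(128, "mammography", seed = 7)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  c <- generate_phantom(128, "mammography", seed = 8)
  expect_false(identical(a$image, c$image))
})

test_that("phantoms are correctly bounded and lesion-free", {
  s <- generate_phantom(128, "mammography", seed = 7)
  expect_true(all(s$image >= 0 & s$image <= 1))
  expect_true(all(s$mask == 0))
  expect_length(s$lesions, 0)
  # elliptical support covers at least 30% of the frame
  expect_gte(mean(s$image > 0), 0.30)
  expect_error(generate_phantom(32), "size")
})

test_that("dbt mode has strictly more high-frequency energy than mammography", {
  m <- generate_phantom(128, "mammography", seed = 7)
  d <- generate_phantom(128, "dbt", seed = 7)
  expect_gt(oracle_laplacian_energy(d$image), oracle_laplacian_energy(m$image))
})

test_that("a circular lesion rasterizes like a brute-force disk", {
  s <- generate_phantom(128, "mammography", seed = 3)
  ctr <- c(round(s$support$cy), round(s$support$cx))
  s <- add_lesion(s, lesion_spec(ctr, c(6, 6), contrast = 0.4,
                                 boundary_irregularity = 0))
  n <- sum(s$mask)
  expect_lt(abs(n - pi * 36) / (pi * 36), 0.15)
  expect_equal(n, oracle_disk_count(ctr[1], ctr[2], 6, 128, 128))
})

test_that("lesion contrast is additive up to clipping", {
  s <- generate_phantom(128, "mammography", seed = 3)
  s$image[] <- 0   # zero background, integer-centered lesion
  ctr <- c(round(s$support$cy), round(s$support$cx))
  s <- add_lesion(s, lesion_spec(ctr, c(6, 6), contrast = 0.3))
  expect_gte(max(s$image), 0.3 - 1e-9)
})

test_that("disjoint lesions give two mask components; bad centers error", {
  s <- generate_phantom(128, "mammography", seed = 3)
  cy <- s$support$cy
  cx <- s$support$cx
  s <- add_lesion(s, lesion_spec(c(cy - 15, cx), c(5, 5)))
  s <- add_lesion(s, lesion_spec(c(cy + 15, cx), c(5, 5)))
  lab <- sinoseg:::cpp_label_components(matrix(as.integer(s$mask), 128), 8L)
  expect_equal(max(lab), 2)
  expect_error(add_lesion(s, lesion_spec(c(1, 1), c(5, 5))), "support")
})

test_that("dataset generation is seeded, counted and patient-structured", {
  cfg <- phantom_config(n_patients = 10, images_per_patient = 2,
                        image_size = 64, modality_mix = 0.5, seed = 1)
  ds <- generate_dataset(cfg)
  expect_length(ds, 20)
  tab <- table(purrr::map_chr(ds, "patient_id"))
  expect_length(tab, 10)
  expect_true(all(tab == 2))
  expect_equal(sum(purrr::map_chr(ds, "modality") == "dbt"), 10)
  ds2 <- generate_dataset(cfg)
  expect_identical(lapply(ds, `[[`, "image"), lapply(ds2, `[[`, "image"))
  cfg3 <- phantom_config(n_patients = 10, images_per_patient = 2,
                         image_size = 64, modality_mix = 0.5, seed = 2)
  ds3 <- generate_dataset(cfg3)
  expect_false(identical(ds[[1]]$image, ds3[[1]]$image))
})

test_that("mask components sit on their generating lesion centers", {
  cfg <- phantom_config(n_patients = 6, images_per_patient = 1,
                        image_size = 128, modality_mix = 0.2,
                        lesion_count_range = c(1, 1), seed = 9)
  for (smp in generate_dataset(cfg)) {
    ctr <- mask_centroid(smp$mask + 0)
    spec <- smp$lesions[[1]]
    d <- sqrt((ctr$y_bar - spec$center_yx[1])^2 +
              (ctr$x_bar - spec$center_yx[2])^2)
    expect_lt(d, 2)
  }
})

test_that("mammography lesions are more conspicuous than dbt lesions", {
  local_contrast <- function(smp) {
    idx <- which(smp$mask == 1, arr.ind = TRUE)
    box <- cbind(pmax(1, range(idx[, 1]) + c(-8, 8)),
                 pmax(1, range(idx[, 2]) + c(-8, 8)))
    box[box > nrow(smp$image)] <- nrow(smp$image)
    sub_i <- smp$image[box[1, 1]:box[2, 1], box[1, 2]:box[2, 2]]
    sub_m <- smp$mask[box[1, 1]:box[2, 1], box[1, 2]:box[2, 2]]
    mean(sub_i[sub_m == 1]) - mean(sub_i[sub_m == 0])
  }
  per_mod <- function(modality, seeds) {
    mean(vapply(seeds, function(s) {
      cfg <- phantom_config(n_patients = 3, images_per_patient = 1,
                            image_size = 128, lesion_count_range = c(1, 1),
                            modality_mix = if (modality == "dbt") 1 else 0,
                            seed = s)
      mean(vapply(generate_dataset(cfg), local_contrast, numeric(1)))
    }, numeric(1)))
  }
  seeds <- 1:7   # 21 samples per modality
  expect_gt(per_mod("mammography", seeds), per_mod("dbt", seeds))
})

test_that("dataset config validation catches impossible settings", {
  expect_error(phantom_config(n_patients = 2), "n_patients")
  expect_error(phantom_config(modality_mix = 1.5), "modality_mix")
  expect_error(phantom_config(dbt_contrast_scale = 1.2), "contrast_scale")
  expect_error(lesion_spec(c(10, 10), c(1, 5)), "semi_axes")
  expect_error(lesion_spec(c(10, 10), c(5, 5), contrast = 0), "contrast")
})

test_that("a dataset summarizes to a tidy tibble", {
  ds <- generate_dataset(phantom_config(n_patients = 3, images_per_patient = 2,
                                        image_size = 64, seed = 4))
  tb <- tibble::as_tibble(ds)
  expect_equal(nrow(tb), 6)
  expect_named(tb, c("sample", "patient_id", "modality", "n_lesions",
                     "mask_px"))
  expect_true(all(tb$mask_px > 0))
})
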