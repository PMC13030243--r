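fake_sample <- function(pid, modality = "mammography") {
  sinoseg:::new_image_sample(matrix(0.5, 8, 8), matrix(0L, 8, 8), pid, modality)
}

test_that("patient-level splits never leak a patient across subsets", {
  samples <- unlist(lapply(sprintf("P%02d", 1:10), function(p) {
    list(fake_sample(p, "mammography"), fake_sample(p, "dbt"))
  }), recursive = FALSE)
  sp <- patient_level_split(samples, c(0.7, 0.15, 0.15), seed = 1)
  pids <- lapply(sp, function(ss) unique(purrr::map_chr(ss, "patient_id")))
  expect_equal(length(pids$train), 7)
  expect_true(length(pids$val) %in% 1:2)
  expect_true(length(pids$test) %in% 1:2)
  expect_equal(sum(lengths(pids)), 10)
  expect_length(intersect(pids$train, pids$val), 0)
  expect_length(intersect(pids$train, pids$test), 0)
  expect_length(intersect(pids$val, pids$test), 0)
  # both modalities of one patient land in the same subset
  for (ss in sp) {
    tab <- table(purrr::map_chr(ss, "patient_id"))
    expect_true(all(tab == 2))
  }
})

test_that("splits are seed-deterministic and seed-sensitive", {
  samples <- lapply(sprintf("P%02d", 1:12), fake_sample)
  s1 <- patient_level_split(samples, seed = 3)
  s2 <- patient_level_split(samples, seed = 3)
  expect_identical(attr(s1, "patients"), attr(s2, "patients"))
  diffs <- vapply(1:10, function(k) {
    !identical(attr(patient_level_split(samples, seed = 100 + k), "patients"),
               attr(s1, "patients"))
  }, logical(1))
  expect_true(any(diffs))
  expect_error(patient_level_split(samples[1:2]), "3 distinct")
})

test_that("augmentation has an identity path and involutive flips", {
  set.seed(1)
  img <- matrix(runif(64 * 64), 64)
  msk <- matrix(0, 64, 64)
  msk[20:30, 25:40] <- 1
  id <- augment_pair(img, msk, prob = 0)
  expect_identical(id$image, img)
  expect_identical(id$mask, msk)
  flip <- img[, 64:1]
  expect_lt(max(abs(flip[, 64:1] - img)), 1e-6)
})

test_that("rotation moves image and mask jointly", {
  msk <- matrix(0, 64, 64)
  msk[14:22, 40:48] <- 1
  img <- msk * 0.8
  out <- withr::with_seed(7, augment_pair(img, msk, rotation_deg = 15,
                                          hflip = FALSE, noise_sigma = 0,
                                          prob = 1))
  expect_false(identical(out$mask, msk))
  cm <- mask_centroid(out$mask)
  ci <- mask_centroid((out$image > 0.4) + 0)
  expect_lt(centroid_distance(cm, ci), 1.5)
  # mask centroid stays on the circle around the frame center
  c0 <- mask_centroid(msk)
  ctr <- 63 / 2
  r0 <- sqrt((c0$y_bar - ctr)^2 + (c0$x_bar - ctr)^2)
  r1 <- sqrt((cm$y_bar - ctr)^2 + (cm$x_bar - ctr)^2)
  expect_lt(abs(r1 - r0), 1.5)
})

tiny_pairs <- function(n, size = 32, seed = 1) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    y <- matrix(0, size, size)
    y0 <- sample(5:(size - 12), 1)
    y[y0:(y0 + 6), 10:(size - 10)] <- 1
    x <- sinoseg:::clamp01(y * 0.7 + matrix(runif(size^2, 0, 0.25), size))
    list(x = x, y = y)
  }))
}

test_that("zero-epoch training returns initial weights and empty history", {
  model <- build_unet(unet_config(base_channels = 4, input_size = 32), seed = 1)
  fit <- train_unet(model, tiny_pairs(2), tiny_pairs(2, seed = 2),
                    train_config(epochs = 0, batch_size = 2))
  expect_identical(fit$model$params, model$params)
  expect_equal(nrow(fit$history), 0)
  expect_true(is.na(fit$best_val_dice))
})

test_that("training runs, improves the loss, and keeps its books", {
  model <- build_unet(unet_config(base_channels = 4, input_size = 32,
                                  dropout_p = 0.1), seed = 1)
  tc <- train_config(epochs = 4, batch_size = 4, lr = 3e-4, seed = 5,
                     aug_prob = 0.25)
  fit <- train_unet(model, tiny_pairs(8), tiny_pairs(4, seed = 2), tc)
  h <- fit$history
  expect_equal(nrow(h), 4)
  expect_true(all(is.finite(h$train_loss)))
  expect_equal(fit$best_val_dice, max(h$val_dice))
  expect_equal(fit$best_epoch, which.max(h$val_dice))
  expect_lt(h$train_loss[4], h$train_loss[1])
  # tidy()/glance() expose the history and the summary
  expect_identical(tidy(fit), h)
  g <- glance(fit)
  expect_equal(g$best_epoch, fit$best_epoch)
  expect_equal(g$n_parameters, n_parameters(fit$model))
})

test_that("identical configs reproduce identical training runs", {
  run <- function() {
    model <- build_unet(unet_config(base_channels = 4, input_size = 32), seed = 1)
    train_unet(model, tiny_pairs(4), tiny_pairs(2, seed = 2),
               train_config(epochs = 2, batch_size = 2, seed = 11))
  }
  expect_identical(run()$history, run()$history)
})

test_that("training validates inputs and set sizes", {
  model <- build_unet(unet_config(base_channels = 4, input_size = 32), seed = 1)
  expect_error(train_unet(model, list(), tiny_pairs(2)), "non-empty")
  bad <- tiny_pairs(2)
  bad[[1]]$x <- matrix(0, 16, 16)
  expect_error(train_unet(model, bad, tiny_pairs(2)), "input size")
  expect_error(train_config(split_fractions = c(0.5, 0.5, 0)), "positive")
  expect_error(train_config(lr = 0), "lr")
})

test_that("evaluation scores predictions against targets", {
  model <- build_unet(unet_config(base_channels = 4, input_size = 32), seed = 1)
  pairs <- tiny_pairs(3)
  ev <- evaluate_model(model, pairs)
  expect_equal(nrow(ev), 3)
  expect_named(ev, c("sample", "dice", "iou"))
  expect_true(all(ev$dice >= 0 & ev$dice <= 1))
  # forcing empty predictions drives Dice to ~0 on nonempty targets
  ev0 <- evaluate_model(model, pairs, threshold = 1.0)
  expect_true(all(ev0$dice < 0.01))
  expect_error(evaluate_model(model, list()), "empty")
})

test_that("reported IoU and Dice satisfy their algebraic relationship", {
  # at eps = 0 the identity IoU = Dice/(2 - Dice) is exact for every mask
  # pair; the eps-stabilized scores deviate only at O(eps)
  set.seed(8)
  for (i in 1:100) {
    P <- matrix(rbinom(16, 1, 0.4), 4)
    G <- matrix(rbinom(16, 1, 0.4), 4)
    inter <- sum(P * G)
    if (sum(P) + sum(G) > 0) {
      d0 <- 2 * inter / (sum(P) + sum(G))
      expect_equal(oracle_iou(P, G), d0 / (2 - d0), tolerance = 1e-12)
    }
    expect_equal(iou(P, G), iou_from_dice(dice_score(P, G)),
                 tolerance = 1e-3)
  }
})
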