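test_that("boundary ground truth marks edges, softened by sigma", {
  m <- array(0, c(16, 16, 2))
  m[8, 8, 1] <- 1; m[8, 8, 2] <- 1
  hard <- boundary_ground_truth(m, sigma = 0)
  expect_equal(hard[8, 8, 1], 1)
  expect_equal(sum(hard[, , 1]), 1)
  # a full-frame mask has its only edge at the image border
  full <- array(1, c(16, 16, 2))
  hb <- boundary_ground_truth(full, sigma = 0)
  interior <- hb[3:14, 3:14, 1]
  expect_equal(sum(interior), 0)
  expect_gt(sum(hb[1, , 1]), 0)
  # smoothing keeps the max at 1 and spreads mass
  soft <- boundary_ground_truth(m, sigma = 2)
  expect_equal(max(soft[, , 1]), 1)
  expect_gt(sum(soft[, , 1] > 0.01), sum(hard[, , 1] > 0.01))
  w <- capture_warnings(boundary_ground_truth(array(0, c(8, 8, 2)), 1))
  expect_length(w, 2L)
  expect_match(w, "empty", all = TRUE)
})

test_that("boundary ridge follows the rasterized ellipse contour", {
  p <- eye_params(image_size = 64L, disc_center = c(32, 32),
                  disc_axes = c(20, 10), cup_axes = c(8, 4),
                  vessel_count = 0L, noise_sd = 0)
  e <- generate_eye(p, seed = 1)
  soft <- boundary_ground_truth(e$mask, sigma = 3)
  # contour oracle: mask minus its erosion
  edge <- e$mask[, , 1] - fa$erode1(e$mask[, , 1])
  ridge <- which(soft[, , 1] > 0.999, arr.ind = TRUE)
  edge_px <- which(edge == 1, arr.ind = TRUE)
  expect_gt(nrow(ridge), 0)
  for (i in seq_len(nrow(ridge))) {
    d2 <- (edge_px[, 1] - ridge[i, 1])^2 + (edge_px[, 2] - ridge[i, 2])^2
    expect_lte(sqrt(min(d2)), 1.5)
  }
})

test_that("augmentations are seeded, geometric ones move mask and image
           together", {
  d <- tiny_domain(1, seed = 41)[[1]]
  idn <- apply_augmentations(d$image, d$mask, list(), seed = 1)
  expect_identical(idn$image, d$image)
  expect_identical(idn$mask, d$mask)
  cfg <- list(rotation = 15, gaussian_noise = 0.02, contrast = 0.1,
              random_erasure = 0.2, elastic = list(alpha = 1.5, sigma = 6))
  a1 <- apply_augmentations(d$image, d$mask, cfg, seed = 7)
  a2 <- apply_augmentations(d$image, d$mask, cfg, seed = 7)
  expect_identical(a1, a2)
  expect_false(identical(a1$image, d$image))
  expect_true(all(a1$mask %in% c(0, 1)))
  expect_true(all(a1$mask[, , 2] <= a1$mask[, , 1]))
})

test_that("an exact quarter-turn permutes the mask without loss", {
  m <- array(0, c(32, 32, 2))
  m[11:22, 15:18, 1] <- 1; m[13:20, 16:17, 2] <- 1
  src_r <- matrix(rep(seq_len(32) - 0.5, 32), 32, 32)
  src_c <- matrix(rep(seq_len(32) - 0.5, each = 32), 32, 32)
  th <- pi / 2
  u <- src_r - 16; v <- src_c - 16
  rr <- cos(th) * u - sin(th) * v + 16
  cc <- sin(th) * u + cos(th) * v + 16
  plane <- fa$warp_nearest(m[, , 1], rr, cc, fill = 0)
  expect_equal(sum(plane), sum(m[, , 1]))
  expect_equal(plane, t(m[, , 1])[, 32:1])
})

test_that("toggle validation enforces the CAE prerequisite", {
  expect_error(train_config(use_cae = FALSE, use_db_plus = TRUE),
               "use_db_plus requires use_cae")
  expect_error(train_config(seg_lr = 0), "seg_lr")
  cfg <- train_config(use_cae = FALSE, use_bmal = TRUE,
                      use_db_plus = FALSE)
  expect_error(train_segmentation(cfg, tiny_domain(2, 1), list()),
               "target domain required")
})

test_that("supervised training reduces the mask loss on the source", {
  src <- tiny_domain(4, seed = 51)
  cfg <- train_config(seg_lr = 1e-3, epochs = 4L, seed = 1,
                      use_cae = FALSE, use_bmal = FALSE,
                      use_db_plus = FALSE)
  fit <- train_segmentation(cfg, src)
  first <- mean(fit$log$L_m[fit$log$epoch == 1])
  last <- mean(fit$log$L_m[fit$log$epoch == max(fit$log$epoch)])
  expect_lt(last, first)
  expect_false(fit$checkpoint$diverged)
})

test_that("training is deterministic given the seed", {
  src <- tiny_domain(3, seed = 52)
  tgt <- tiny_domain(3, seed = 53, shift = target_shift())
  cae <- build_cae(latent_channels = 8L, widths = c(8L, 12L, 16L), seed = 1)
  cae <- pretrain_cae(cae, lapply(src, `[[`, "image"), epochs = 3L,
                      seed = 1)$cae
  cfg <- train_config(seg_lr = 1e-3, epochs = 2L, seed = 9)
  f1 <- train_segmentation(cfg, src, tgt, cae = cae)
  f2 <- train_segmentation(cfg, src, tgt, cae = cae)
  expect_identical(f1$log, f2$log)
})

test_that("lambda 0 reproduces the supervised generator trajectory", {
  src <- tiny_domain(3, seed = 54)
  tgt <- tiny_domain(3, seed = 55, shift = target_shift())
  cae <- build_cae(latent_channels = 8L, widths = c(8L, 12L, 16L), seed = 2)
  cae <- pretrain_cae(cae, lapply(src, `[[`, "image"), epochs = 3L,
                      seed = 2)$cae
  adv0 <- train_config(seg_lr = 1e-3, epochs = 2L, seed = 11,
                       lambda_adv = 0)
  sup <- train_config(seg_lr = 1e-3, epochs = 2L, seed = 11,
                      use_bmal = FALSE, use_db_plus = FALSE)
  fa_ <- train_segmentation(adv0, src, tgt, cae = cae)
  fs <- train_segmentation(sup, src, tgt, cae = cae)
  wa <- fa_$checkpoint$segnet$heads$m2$W
  ws <- fs$checkpoint$segnet$heads$m2$W
  expect_equal(wa, ws, tolerance = 1e-12)
  # but the adversarial run did train its discriminators
  expect_false(is.null(fa_$checkpoint$disc_b))
  expect_true(all(is.finite(fa_$log$L_D_b)))
})

test_that("generator and discriminators update disjoint parameter sets", {
  src <- tiny_domain(2, seed = 56)
  tgt <- tiny_domain(2, seed = 57, shift = target_shift())
  cae <- build_cae(latent_channels = 8L, widths = c(8L, 12L, 16L), seed = 3)
  cae <- pretrain_cae(cae, lapply(src, `[[`, "image"), epochs = 2L,
                      seed = 3)$cae
  cfg <- train_config(seg_lr = 1e-3, epochs = 1L, seed = 12)
  fit <- train_segmentation(cfg, src, tgt, cae = cae)
  # discriminators moved away from their seeded initialization
  d0 <- build_discriminator(2L, cfg$disc_base_channels,
                            seed = fa$derive_seed(12L, "db-init"))
  expect_false(identical(fit$checkpoint$disc_b$layers[[1]]$W,
                         d0$layers[[1]]$W))
  # the frozen autoencoder is untouched by adversarial training
  expect_identical(fit$checkpoint$cae$encoder[[1]]$W, cae$encoder[[1]]$W)
})
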