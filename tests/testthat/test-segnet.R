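test_that("forward pass yields aligned sigmoid outputs for both branches", {
  net <- build_segnet("tiny", seed = 1)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  f <- segnet_forward(net, x)
  expect_equal(dim(f$mask_prob), c(64L, 64L, 2L))
  expect_equal(dim(f$boundary_pred), c(64L, 64L, 2L))
  expect_true(all(f$mask_prob >= 0 & f$mask_prob <= 1))
  expect_true(all(f$boundary_pred >= 0 & f$boundary_pred <= 1))
  expect_error(segnet_forward(net, array(0, c(30, 30, 3))), "divisible")
  # deterministic in evaluation mode
  expect_identical(f$mask_prob, segnet_forward(net, x)$mask_prob)
})

test_that("the boundary prediction feeds the mask branch (live concat)", {
  net <- build_segnet("tiny", seed = 2)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  base <- segnet_forward(net, x)
  ablated <- net
  # silence the boundary heads: large negative bias drives the boundary
  # probability to ~0, which must change the mask prediction downstream
  ablated$heads$bhead_disc$W[] <- 0
  ablated$heads$bhead_cup$W[] <- 0
  ablated$heads$bhead_disc$b[] <- -20
  ablated$heads$bhead_cup$b[] <- -20
  out <- segnet_forward(ablated, x)
  expect_gt(max(abs(out$mask_prob - base$mask_prob)), 1e-6)
})

test_that("backbone registry validates names and builds ASPP variants", {
  expect_error(build_backbone("resnet"), "registry")
  bb <- build_backbone("tiny", aspp_rates = c(1L))
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  r <- backbone_forward(bb, x)
  expect_equal(dim(r$high), c(4L, 4L, bb$widths$w3))
  expect_equal(dim(r$low), c(8L, 8L, bb$widths$w2))
  bb4 <- build_backbone("tiny", aspp_rates = c(1L, 6L, 12L, 18L))
  r4 <- backbone_forward(bb4, x)
  expect_equal(dim(r4$high), dim(r$high))
  # deeplab_like widths follow the published branch widths
  reg <- fa$segnet_registry()
  expect_equal(reg$deeplab_like$wb, 256L)
})

test_that("tiny forward on a 128px image is subsecond on one CPU", {
  net <- build_segnet("tiny", seed = 3)
  x <- array(runif(128 * 128 * 3), c(128, 128, 3))
  elapsed <- system.time(segnet_forward(net, x))[["elapsed"]]
  expect_lt(elapsed, 1)
})

test_that("boundary branch can be duplicated per structure by config", {
  shared <- build_segnet("tiny", shared_boundary_trunk = TRUE, seed = 4)
  dup <- build_segnet("tiny", shared_boundary_trunk = FALSE, seed = 4)
  expect_true(all(c("btrunk1", "btrunk2") %in% names(shared$heads)))
  expect_true(all(c("btrunk1_disc", "btrunk1_cup", "btrunk2_cup") %in%
                    names(dup$heads)))
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_equal(dim(segnet_forward(dup, x)$boundary_pred), c(32L, 32L, 2L))
})

test_that("segnet backward matches finite differences through the graph", {
  net <- build_segnet("tiny", seed = 5)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  tgt_m <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
  tgt_b <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
  f <- segnet_forward(net, x, keep = TRUE)
  grads <- fa$segnet_backward(net, f$caches, tgt_m, tgt_b)
  # loss = sum(up(m_logit) * tgt_m) + sum(up(b_logit) * tgt_b); probe a few
  # parameters in layers on every path (backbone, decoder, both branches)
  loss_at <- function(n2) {
    f2 <- segnet_forward(n2, x, keep = TRUE)
    lm <- log(f2$mask_prob / (1 - f2$mask_prob))
    lb <- log(f2$boundary_pred / (1 - f2$boundary_pred))
    sum(lm * tgt_m) + sum(lb * tgt_b)
  }
  eps <- 1e-5
  probe <- function(where, layer_name, idx) {
    n_p <- net; n_m <- net
    if (where == "backbone") {
      n_p$backbone$layers[[layer_name]]$W[idx] <-
        n_p$backbone$layers[[layer_name]]$W[idx] + eps
      n_m$backbone$layers[[layer_name]]$W[idx] <-
        n_m$backbone$layers[[layer_name]]$W[idx] - eps
    } else {
      n_p$heads[[layer_name]]$W[idx] <- n_p$heads[[layer_name]]$W[idx] + eps
      n_m$heads[[layer_name]]$W[idx] <- n_m$heads[[layer_name]]$W[idx] - eps
    }
    (loss_at(n_p) - loss_at(n_m)) / (2 * eps)
  }
  for (case in list(list("backbone", "stem1", 5L),
                    list("backbone", "aspp_2", 11L),
                    list("backbone", "aspp_fuse", 3L),
                    list("heads", "dec", 17L),
                    list("heads", "btrunk1", 9L),
                    list("heads", "bhead_cup", 2L),
                    list("heads", "m1", 21L),
                    list("heads", "m2", 4L))) {
    got <- grads[[case[[2]]]]$gW[case[[3]]]
    want <- probe(case[[1]], case[[2]], case[[3]])
    expect_equal(got, want, tolerance = 1e-4,
                 label = paste("grad of", case[[2]]))
  }
})

test_that("checkpoints round-trip through save and load", {
  net <- build_segnet("tiny", seed = 6)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(net, path)
  net2 <- load_checkpoint(path)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(segnet_forward(net, x)$mask_prob,
                   segnet_forward(net2, x)$mask_prob)
  unlink(path)
})
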