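# Closed-form binary cross-entropy values: a discriminator that outputs 0.5
# everywhere scores ln 2 against either label; a discriminating one scores
# ~0 on its own objective.  Every adversarial operation must also equal the
# manual composition of bce over its batches.

test_that("bce matches closed forms and clamps saturated probabilities", {
  p <- matrix(0.5, 4, 4)
  expect_equal(bce(p, 1), log(2))
  expect_equal(bce(p, 0), log(2))
  expect_equal(bce(matrix(0.9, 2, 2), 1), -log(0.9))
  expect_true(is.finite(bce(matrix(1, 2, 2), 1)))
  expect_true(is.finite(bce(matrix(0, 2, 2), 0)))
})

test_that("mask loss is mean multi-label cross-entropy", {
  y <- array(c(1, 0, 0, 1, 1, 1, 0, 0), c(2, 2, 2))
  expect_lt(mask_loss(y, y), 1e-5)
  expect_equal(mask_loss(array(0.5, c(2, 2, 2)), y), log(2))
  p <- array(c(0.8, 0.2, 0.4, 0.9, 0.7, 0.6, 0.1, 0.3), c(2, 2, 2))
  hand <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(mask_loss(p, y), hand, tolerance = 1e-6)
  expect_error(mask_loss(p, array(0, c(2, 2, 1))), "shape")
})

test_that("boundary loss is mean squared error", {
  y <- array(runif(8), c(2, 2, 2))
  expect_equal(boundary_loss(y, y), 0)
  expect_equal(boundary_loss(y + 0.5, y), 0.25)
  p <- array(c(0.1, 0.9, 0.3, 0.5, 0.2, 0.8, 0.6, 0.4), c(2, 2, 2))
  y2 <- array(c(1, 0, 0, 1, 0, 1, 1, 0), c(2, 2, 2))
  expect_equal(boundary_loss(p, y2), mean((y2 - p)^2))
})

test_that("adversarial objectives hit their closed-form anchors", {
  half <- const_half_disc(2L)
  maps <- replicate(3, array(runif(64 * 64 * 2), c(64, 64, 2)),
                    simplify = FALSE)
  expect_equal(disc_loss_b_plus(half, maps, maps), 2 * log(2))
  expect_equal(adv_loss_b_plus(half, maps), log(2))
  expect_equal(disc_loss_b(half, maps, maps[1:2]), 2 * log(2))
  expect_equal(adv_loss_b(half, maps), log(2))
  expect_equal(disc_loss_m(half, maps, maps), 2 * log(2))
  expect_equal(adv_loss_m(half, maps), log(2))
})

test_that("a discriminating patch classifier drives its objective to ~0", {
  # 32-px maps give a single-patch grid, so one affine recalibration of the
  # last layer separates the two maps cleanly
  hi <- array(0.9, c(32, 32, 2))
  lo <- array(0.1, c(32, 32, 2))
  d <- calibrated_disc(hi, lo)
  expect_gt(mean(discriminator_forward(d, hi)$probs), 0.99)
  expect_lt(mean(discriminator_forward(d, lo)$probs), 0.01)
  expect_lt(disc_loss_b_plus(d, list(hi), list(lo)), 0.05)
  expect_lt(disc_loss_m(d, list(hi), list(lo)), 0.05)
  # and the generator objective on fooled maps is ~0 as well
  expect_lt(adv_loss_b_plus(d, list(hi)), 0.02)
})

test_that("each adversarial operation equals its manual bce composition", {
  set.seed(7)
  d <- build_discriminator(2L, base_channels = 2L, seed = 7)
  src <- replicate(3, array(runif(32 * 32 * 2), c(32, 32, 2)),
                   simplify = FALSE)
  enh <- replicate(3, array(runif(32 * 32 * 2), c(32, 32, 2)),
                   simplify = FALSE)
  tgt <- replicate(2, array(runif(32 * 32 * 2), c(32, 32, 2)),
                   simplify = FALSE)
  D <- function(x) discriminator_forward(d, x)$probs
  manual_bp <- (sum(vapply(src, function(x) bce(D(x), 1), numeric(1))) +
                sum(vapply(enh, function(x) bce(D(x), 0), numeric(1)))) / 3
  expect_equal(disc_loss_b_plus(d, src, enh), manual_bp, tolerance = 1e-6)
  new_src <- c(src, enh)
  manual_b <- mean(vapply(new_src, function(x) bce(D(x), 1), numeric(1))) +
    mean(vapply(tgt, function(x) bce(D(x), 0), numeric(1)))
  expect_equal(disc_loss_b(d, new_src, tgt), manual_b, tolerance = 1e-6)
  expect_equal(disc_loss_m(d, new_src, tgt), manual_b, tolerance = 1e-6)
  expect_equal(adv_loss_b(d, tgt),
               mean(vapply(tgt, function(x) bce(D(x), 1), numeric(1))),
               tolerance = 1e-6)
  expect_equal(adv_loss_m(d, tgt), adv_loss_b(d, tgt))
  expect_error(disc_loss_b(d, list(), tgt))
})

test_that("total loss satisfies the additive identities", {
  r <- total_loss(1, 2, 0.5, 0.25, 0.25, lambda_adv = 0.01)
  expect_equal(r$L_adv, 1.0)
  expect_equal(r$L_total, 3.01)
  r0 <- total_loss(0.7, 0.2)
  expect_equal(r0$L_total, 0.9)
  rz <- total_loss(1, 1, 5, 5, 5, lambda_adv = 0)
  expect_equal(rz$L_total, 2)
  expect_error(total_loss(NaN, 1), "L_m")
  expect_error(total_loss(1, Inf), "L_b")
})

test_that("a gradient step on the mask loss moves p toward y", {
  # single-logit toy problem: d(bce)/d(logit) = p - y
  y <- 1
  logit <- -0.3
  for (i in 1:20) {
    p <- 1 / (1 + exp(-logit))
    logit <- logit - 1.0 * (p - y)
  }
  expect_gt(1 / (1 + exp(-logit)), 0.9)
  # finite-difference agreement of the analytic logit gradient
  p0 <- 0.37
  l0 <- log(p0 / (1 - p0))
  f <- function(l) {
    pp <- 1 / (1 + exp(-l))
    -(y * log(pp) + (1 - y) * log(1 - pp))
  }
  eps <- 1e-6
  expect_equal((f(l0 + eps) - f(l0 - eps)) / (2 * eps), p0 - y,
               tolerance = 1e-5)
})
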