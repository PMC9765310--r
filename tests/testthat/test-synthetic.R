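test_that("vessel-free noiseless eye rasterizes exact ellipses", {
  p <- eye_params(image_size = 64L, disc_center = c(32, 32),
                  disc_axes = c(20, 20), cup_axes = c(8, 8),
                  cup_offset = c(0, 0), vessel_count = 0L, noise_sd = 0)
  e <- generate_eye(p, seed = 1)
  # disc area equals the center-inclusion rasterized circle of radius 20
  cc <- seq_len(64) - 0.5
  circle <- outer((cc - 32)^2, (cc - 32)^2, `+`) <= 400
  expect_equal(e$mask[, , 1], circle * 1)
  expect_lt(sum(e$mask[, , 2]), sum(e$mask[, , 1]))
})

test_that("generation is a pure function of (params, seed)", {
  p <- eye_params(image_size = 64L, disc_center = c(30, 34))
  a <- generate_eye(p, seed = 7)
  b <- generate_eye(p, seed = 7)
  expect_identical(a, b)
  c <- generate_eye(p, seed = 8)
  expect_false(identical(a$image, c$image))
})

test_that("vertical disc diameter equals twice the row semi-axis", {
  p <- eye_params(image_size = 64L, disc_center = c(32, 32),
                  disc_axes = c(20, 10), cup_axes = c(8, 4),
                  vessel_count = 0L, noise_sd = 0)
  e <- generate_eye(p, seed = 1)
  rows <- sum(apply(e$mask[, , 1] == 1, 1, any))
  expect_equal(rows, 40L)
  cols <- sum(apply(e$mask[, , 1] == 1, 2, any))
  expect_equal(cols, 20L)
})

test_that("invalid geometry is rejected", {
  expect_error(eye_params(disc_axes = c(10, 10), cup_axes = c(12, 8)),
               "cup axes")
  expect_error(eye_params(image_size = 64L, disc_center = c(5, 32),
                          disc_axes = c(20, 20), cup_axes = c(8, 8)),
               "bounds")
  expect_error(eye_params(image_size = 64L, disc_center = c(32, 32),
                          disc_axes = c(20, 20), cup_axes = c(18, 18),
                          cup_offset = c(10, 0)),
               "not contained")
})

test_that("cup is a pixelwise subset of disc across sampled eyes", {
  dom <- generate_domain(domain_spec(8, seed = 42, image_size = 64L))
  for (d in dom) {
    expect_true(all(d$mask[, , 2] <= d$mask[, , 1]))
    expect_true(all(d$image >= 0 & d$image <= 1))
  }
})

test_that("brightness shift moves mean intensity by the stated offset", {
  base <- domain_spec(10, seed = 5, image_size = 64L)
  shifted <- domain_spec(10, shift = list(brightness = 0.2), seed = 5,
                         image_size = 64L)
  m0 <- mean(vapply(generate_domain(base), function(d) mean(d$image),
                    numeric(1)))
  m1 <- mean(vapply(generate_domain(shifted), function(d) mean(d$image),
                    numeric(1)))
  expect_lt(abs((m1 - m0) - 0.2), 0.05)
})

test_that("domain generation is deterministic and sized as requested", {
  expect_length(generate_domain(domain_spec(1, seed = 3, image_size = 32L)),
                1L)
  a <- generate_domain(domain_spec(4, seed = 9, image_size = 32L))
  b <- generate_domain(domain_spec(4, seed = 9, image_size = 32L))
  expect_identical(a, b)
  expect_error(domain_spec(3, param_ranges = list(cup_ratio = c(0.6, 0.2))),
               "range")
})

test_that("generated CDR matches the requested ratio up to rasterization", {
  for (cdr in c(0.35, 0.5, 0.65)) {
    p <- eye_params(image_size = 96L, disc_center = c(48, 48),
                    disc_axes = c(22, 20), cup_axes = cdr * c(22, 20),
                    vessel_count = 3L)
    e <- generate_eye(p, seed = 2)
    d_od <- 2 * 22
    expect_lt(abs(vertical_cdr(e$mask) - cdr), 1 / d_od + 1e-9)
  }
})

test_that("glaucoma cohort separates classes and respects prevalence", {
  coh <- glaucoma_cohort(50, prevalence = 0.5, cdr_normal = c(0.3, 0.4),
                         cdr_glaucoma = c(0.7, 0.8), seed = 4,
                         image_size = 64L)
  labels <- vapply(coh, `[[`, numeric(1), "label")
  scores <- vapply(coh, function(x) vertical_cdr(x$mask), numeric(1))
  expect_equal(roc_auc(scores, labels)$auc, 1.0)
  expect_true(all(vapply(coh, function(x)
    x$cdr_true >= 0.3 && x$cdr_true <= 0.8, logical(1))))

  none <- glaucoma_cohort(10, prevalence = 0, seed = 1, image_size = 32L)
  expect_true(all(vapply(none, `[[`, numeric(1), "label") == 0))

  big <- glaucoma_cohort(100, prevalence = 0.3, seed = 6, image_size = 32L)
  k <- sum(vapply(big, `[[`, numeric(1), "label"))
  # binomial 99% interval for n = 100, p = 0.3
  expect_gte(k, qbinom(0.005, 100, 0.3))
  expect_lte(k, qbinom(0.995, 100, 0.3))
})

test_that("overlapping cohort intervals warn, inverted ones error", {
  expect_warning(glaucoma_cohort(4, cdr_normal = c(0.3, 0.6),
                                 cdr_glaucoma = c(0.5, 0.8), seed = 1,
                                 image_size = 32L),
                 "overlap")
  expect_error(glaucoma_cohort(4, cdr_normal = c(0.5, 0.6),
                               cdr_glaucoma = c(0.4, 0.8), seed = 1),
               "above")
})
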