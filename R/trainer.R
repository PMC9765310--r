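# Alternating adversarial optimization: each iteration first updates the
# segmentation network on the total objective (supervised mask/boundary
# terms plus lambda-weighted adversarial terms, discriminators frozen), then
# updates each discriminator on its own objective with the generator frozen,
# reusing the iteration's detached prediction maps.  Generator and
# discriminators are never updated from the same computation graph.

#' Training configuration
#'
#' Defaults follow the published recipe: Adam for the segmentation network
#' (learning rate 2.5e-5), plain SGD for all three discriminators (learning
#' rate 1e-3).  Note that 2.5e-5 presumes fine-tuning from a pretrained
#' backbone; the desk-scale experiment preset (see
#' [run_adaptation_experiment()]) trains tiny networks from random
#' initialization and overrides `seg_lr` accordingly.
#'
#' Ablation toggles: `use_cae` enables source enhancement (and supervision
#' on the enhanced images), `use_bmal` enables the boundary and mask
#' discriminators against the target domain, `use_db_plus` additionally
#' enables the source-vs-enhanced boundary discriminator and requires
#' `use_cae` (without an enhanced domain there is nothing for it to
#' discriminate).
#'
#' @param seg_lr,disc_lr learning rates (> 0).
#' @param lambda_adv weight of the adversarial sum in the total loss.
#' @param epochs training epochs (one epoch = one pass over the source set).
#' @param seed master seed; weight init, data order and latent jitter draw
#'   from disjoint derived streams.
#' @param use_cae,use_bmal,use_db_plus ablation toggles.
#' @param boundary_sigma Gaussian width (pixels) of the soft boundary
#'   ground truth.
#' @param jitter_sd latent jitter for the enhanced domain.
#' @param backbone backbone name for [build_segnet()].
#' @param disc_base_channels width of the discriminators' first layer.
#' @param cae_epochs,cae_lr autoencoder pretraining budget (used when no
#'   pretrained autoencoder is supplied).
#' @param augmentations list of data-augmentation settings, see
#'   [apply_augmentations()]; empty list disables augmentation.
#' @param aspp_rates,shared_boundary_trunk forwarded to [build_segnet()].
#' @param disc_input what the mask discriminator consumes: the mask
#'   probability maps (`"prob"`, default) or their pixelwise Shannon
#'   entropy maps (`"entropy"`), which align prediction *confidence*
#'   instead of prediction shape.
#' @param lr_decay_power `NULL` for a constant segmentation learning rate
#'   (default), or a positive exponent `p` for polynomial decay
#'   `lr * (1 - iter/total_iters)^p`.
#' @return object of class `train_config`.
#' @export
train_config <- function(seg_lr = 2.5e-5, disc_lr = 1e-3, lambda_adv = 0.01,
                         epochs = 30L, seed = 1L, use_cae = TRUE,
                         use_bmal = TRUE, use_db_plus = TRUE,
                         boundary_sigma = 3, jitter_sd = 0.1,
                         backbone = "tiny", disc_base_channels = 8L,
                         cae_epochs = 30L, cae_lr = 1e-3,
                         augmentations = list(),
                         aspp_rates = c(1L, 6L, 12L, 18L),
                         shared_boundary_trunk = TRUE,
                         disc_input = c("prob", "entropy"),
                         lr_decay_power = NULL) {
  disc_input <- match.arg(disc_input)
  stopifnot(seg_lr > 0, disc_lr > 0, lambda_adv >= 0, epochs >= 1,
            boundary_sigma >= 0,
            is.null(lr_decay_power) || lr_decay_power > 0)
  if (use_db_plus && !use_cae) {
    stop("train_config: use_db_plus requires use_cae (the source-vs-",
         "enhanced discriminator needs an enhanced domain)", call. = FALSE)
  }
  structure(list(seg_lr = seg_lr, disc_lr = disc_lr,
                 lambda_adv = lambda_adv, epochs = as.integer(epochs),
                 seed = as.integer(seed), use_cae = use_cae,
                 use_bmal = use_bmal, use_db_plus = use_db_plus,
                 boundary_sigma = boundary_sigma, jitter_sd = jitter_sd,
                 backbone = backbone,
                 disc_base_channels = as.integer(disc_base_channels),
                 cae_epochs = as.integer(cae_epochs), cae_lr = cae_lr,
                 augmentations = augmentations,
                 aspp_rates = as.integer(aspp_rates),
                 shared_boundary_trunk = shared_boundary_trunk,
                 disc_input = disc_input,
                 lr_decay_power = lr_decay_power),
            class = "train_config")
}

erode1 <- function(m) {
  # 8-neighbour erosion with zero padding (foreground shrinks at borders)
  n <- nrow(m); p <- ncol(m)
  z <- matrix(0, n + 2, p + 2)
  z[2:(n + 1), 2:(p + 1)] <- m
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    out <- out & z[(2 + dr):(n + 1 + dr), (2 + dc):(p + 1 + dc)]
  }
  out * 1
}

#' Soft boundary ground truth from a binary mask
#'
#' Per channel: the morphological gradient (mask XOR its 1-pixel erosion,
#' with the outside of the image treated as background so a structure
#' touching the border has its edge at the border), optionally smoothed by a
#' Gaussian of width `sigma` and renormalized to maximum 1.  `sigma = 0`
#' returns the hard edge.
#'
#' @param mask `H x W x 2` binary array.
#' @param sigma Gaussian width in pixels.
#' @return `H x W x 2` real array in `[0, 1]`.
#' @export
boundary_ground_truth <- function(mask, sigma = 3) {
  stopifnot(sigma >= 0)
  d <- dim(mask)
  out <- array(0, d)
  for (ch in seq_len(d[3])) {
    m <- binarize(mask[, , ch])
    if (sum(m) == 0) {
      warning("boundary_ground_truth: empty mask channel ", ch,
              ", returning zero boundary")
      next
    }
    edge <- (m - erode1(m)) * 1
    if (sigma > 0) {
      edge <- gblur_capped(edge, sigma)
      mx <- max(edge)
      if (mx > 0) edge <- edge / mx
    }
    out[, , ch] <- edge
  }
  out
}

# ---- data augmentation ------------------------------------------------------

warp_nearest <- function(plane, src_r, src_c, fill) {
  n <- nrow(plane); p <- ncol(plane)
  ri <- floor(src_r) + 1L
  ci <- floor(src_c) + 1L
  ok <- ri >= 1 & ri <= n & ci >= 1 & ci <= p
  out <- matrix(fill, n, p)
  out[ok] <- plane[cbind(ri[ok], ci[ok])]
  out
}

#' Apply seeded data augmentation to an image/mask pair
#'
#' Geometric transforms (rotation, elastic warp) are applied identically to
#' image and mask with nearest-neighbour sampling for the mask, so the mask
#' stays binary and the cup remains inside the disc; photometric transforms
#' (Gaussian noise, contrast, random erasure) touch the image only.  An
#' empty `config` is the identity.
#'
#' @param image `H x W x 3` array.
#' @param mask `H x W x 2` binary array.
#' @param config list with optional entries `rotation` (max |degrees|),
#'   `elastic` (`list(alpha, sigma)` in pixels), `gaussian_noise` (sd),
#'   `contrast` (max relative change), `random_erasure` (max side fraction).
#' @param seed integer seed; equal seeds give identical outputs.
#' @return `list(image, mask)`.
#' @export
apply_augmentations <- function(image, mask, config = list(), seed = 1L) {
  if (length(config) == 0) return(list(image = image, mask = mask))
  with_seed(seed, {
    n <- dim(image)[1]; p <- dim(image)[2]
    grid_r <- matrix(rep(seq_len(n) - 0.5, p), n, p)
    grid_c <- matrix(rep(seq_len(p) - 0.5, each = n), n, p)
    src_r <- grid_r; src_c <- grid_c
    warped <- FALSE
    if (!is.null(config$rotation) && config$rotation != 0) {
      th <- runif(1, -config$rotation, config$rotation) * pi / 180
      cr <- n / 2; cc <- p / 2
      u <- grid_r - cr; v <- grid_c - cc
      src_r <- cos(th) * u - sin(th) * v + cr
      src_c <- sin(th) * u + cos(th) * v + cc
      warped <- TRUE
    }
    if (!is.null(config$elastic)) {
      al <- config$elastic$alpha %||% 2
      sg <- config$elastic$sigma %||% 8
      dr <- gblur_capped(matrix(rnorm(n * p), n, p), sg)
      dc <- gblur_capped(matrix(rnorm(n * p), n, p), sg)
      dr <- dr / max(abs(dr)) * al
      dc <- dc / max(abs(dc)) * al
      src_r <- src_r + dr; src_c <- src_c + dc
      warped <- TRUE
    }
    if (warped) {
      for (ch in 1:3) {
        image[, , ch] <- warp_nearest(image[, , ch], src_r, src_c,
                                      fill = stats::median(image[, , ch]))
      }
      for (ch in 1:2) {
        mask[, , ch] <- warp_nearest(mask[, , ch], src_r, src_c, fill = 0)
      }
    }
    if (!is.null(config$contrast) && config$contrast != 0) {
      f <- 1 + runif(1, -config$contrast, config$contrast)
      image <- 0.5 + (image - 0.5) * f
    }
    if (!is.null(config$gaussian_noise) && config$gaussian_noise > 0) {
      image <- image + rnorm(length(image), sd = config$gaussian_noise)
    }
    if (!is.null(config$random_erasure) && config$random_erasure > 0) {
      side <- max(2L, round(runif(1, 0.05, config$random_erasure) * n))
      r0 <- sample.int(n - side, 1); c0 <- sample.int(p - side, 1)
      image[r0:(r0 + side - 1), c0:(c0 + side - 1), ] <- mean(image)
    }
    image <- pmin(pmax(image, 0), 1)
    list(image = image, mask = mask)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gaussian blur with the brush capped to the image extent (EBImage's
# default radius 2*ceil(3*sigma)+1 errors on images smaller than the brush)
gblur_capped <- function(x, sigma) {
  m <- min(dim(x))
  r <- min(2L * ceiling(3 * sigma) + 1L, if (m %% 2L == 1L) m else m - 1L)
  as.matrix(EBImage::gblur(x, sigma = sigma, radius = r))
}

# ---- adversarial training ---------------------------------------------------

# gradient of mean BCE w.r.t. the discriminator's probability grid
bce_grad_probs <- function(probs, label) {
  p <- clamp01(probs)
  if (label == 1) -1 / (p * length(p)) else 1 / ((1 - p) * length(p))
}

# pixelwise Shannon entropy of a probability map and its derivative
entropy_map <- function(p) {
  p <- clamp01(p)
  -(p * log(p) + (1 - p) * log(1 - p))
}

entropy_grad <- function(p) {
  p <- clamp01(p)
  log((1 - p) / p)
}

#' Train the segmentation network with adversarial domain adaptation
#'
#' Runs the full alternating procedure: (optional) autoencoder enhancement
#' of the source domain, supervised mask/boundary training on the labeled
#' (new) source domain, and adversarial alignment of target-domain boundary
#' and mask predictions via the patch discriminators.  With all toggles off
#' this reduces to supervised training on the source domain.
#'
#' @param config a [train_config()].
#' @param source list of `list(image, mask)` labeled pairs.
#' @param target list of `list(image, ...)` unlabeled items; may be empty
#'   only when `use_bmal = FALSE`.
#' @param cae optional pretrained [build_cae()] autoencoder; when `NULL` and
#'   `use_cae = TRUE` one is pretrained on the source images first.
#' @param init optional checkpoint from a previous [train_segmentation()]
#'   call; its networks (and autoencoder) resume training instead of fresh
#'   initializations.
#' @param verbose print per-epoch means.
#' @return `list(checkpoint, log)`: the checkpoint holds the trained
#'   networks (and frozen autoencoder), the log one row per iteration with
#'   every loss component.
#' @export
train_segmentation <- function(config, source, target = list(), cae = NULL,
                               init = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "train_config"), length(source) >= 1)
  if (config$use_bmal && length(target) == 0) {
    stop("train_segmentation: target domain required when use_bmal = TRUE",
         call. = FALSE)
  }
  seed <- config$seed
  net <- if (!is.null(init)) init$segnet else {
    build_segnet(config$backbone, aspp_rates = config$aspp_rates,
                 shared_boundary_trunk = config$shared_boundary_trunk,
                 seed = derive_seed(seed, "seg-init"))
  }
  if (is.null(cae) && !is.null(init)) cae <- init$cae
  if (config$use_cae && is.null(cae)) {
    cae <- build_cae(seed = derive_seed(seed, "cae-init"))
    cae <- pretrain_cae(cae, lapply(source, `[[`, "image"),
                        epochs = config$cae_epochs, lr = config$cae_lr,
                        seed = derive_seed(seed, "cae-pretrain"))$cae
  }
  dbp <- db <- dm <- NULL
  opt_dbp <- opt_db <- opt_dm <- NULL
  if (config$use_db_plus) {
    dbp <- init$disc_b_plus %||%
      build_discriminator(2L, config$disc_base_channels,
                          seed = derive_seed(seed, "dbp-init"))
    opt_dbp <- opt_sgd(config$disc_lr)
  }
  if (config$use_bmal) {
    db <- init$disc_b %||%
      build_discriminator(2L, config$disc_base_channels,
                          seed = derive_seed(seed, "db-init"))
    dm <- init$disc_m %||%
      build_discriminator(2L, config$disc_base_channels,
                          seed = derive_seed(seed, "dm-init"))
    opt_db <- opt_sgd(config$disc_lr)
    opt_dm <- opt_sgd(config$disc_lr)
  }
  opt_seg <- opt_adam(config$seg_lr)
  yb_cache <- lapply(source, function(s)
    boundary_ground_truth(s$mask, config$boundary_sigma))
  # the CAE is frozen during training, so source latents never change;
  # encode once and only re-decode (with fresh jitter) each epoch
  z_cache <- if (config$use_cae) {
    lapply(source, function(s) cae_encode(cae, s$image))
  }
  aug_on <- length(config$augmentations) > 0
  log_rows <- vector("list", config$epochs * length(source))
  iter <- 0L
  last_good <- NULL
  diverged <- FALSE
  lam <- config$lambda_adv
  for (ep in seq_len(config$epochs)) {
    enhanced <- NULL
    if (config$use_cae) {
      jit_seed <- derive_seed(seed, paste0("jit", ep))
      enhanced <- lapply(seq_along(source), function(i) {
        z <- z_cache[[i]]
        if (config$jitter_sd > 0) {
          z <- z + with_seed(derive_seed(jit_seed, paste0("jitter", i)),
                             array(rnorm(length(z), sd = config$jitter_sd),
                                   dim(z)))
        }
        list(image = cae_decode(cae, z), mask = source[[i]]$mask,
             source_index = i)
      })
    }
    ord <- with_seed(derive_seed(seed, paste0("order", ep)),
                     sample.int(length(source)))
    t_ord <- if (length(target)) {
      with_seed(derive_seed(seed, paste0("t-order", ep)),
                sample(rep_len(seq_along(target), length(source))))
    } else NULL
    for (step in seq_along(ord)) {
      iter <- iter + 1L
      i <- ord[step]
      xs <- source[[i]]$image; ys <- source[[i]]$mask; yb <- yb_cache[[i]]
      if (aug_on) {
        a <- apply_augmentations(xs, ys, config$augmentations,
                                 seed = derive_seed(seed,
                                                    paste0("aug", iter)))
        xs <- a$image; ys <- a$mask
        yb <- boundary_ground_truth(ys, config$boundary_sigma)
      }
      # ---- generator step ----
      fs <- segnet_forward(net, xs, keep = TRUE)
      fe <- ft <- NULL
      if (config$use_cae) {
        fe <- segnet_forward(net, enhanced[[i]]$image, keep = TRUE)
      }
      if (config$use_bmal) {
        ft <- segnet_forward(net, target[[t_ord[step]]]$image, keep = TRUE)
      }
      labeled <- list(list(f = fs, y = ys, yb = yb, enh = FALSE))
      if (config$use_cae) {
        labeled <- c(labeled, list(list(f = fe, y = ys, yb = yb,
                                        enh = TRUE)))
      }
      nl <- length(labeled)
      L_m <- mean(vapply(labeled, function(s) mask_loss(s$f$mask_prob, s$y),
                         numeric(1)))
      L_b <- mean(vapply(labeled,
                         function(s) boundary_loss(s$f$boundary_pred, s$yb),
                         numeric(1)))
      L_adv_bp <- L_adv_b <- L_adv_m <- 0
      adv <- list()
      if (config$use_db_plus) {
        adv$bp <- discriminator_forward(dbp, fe$boundary_pred, keep = TRUE)
        L_adv_bp <- bce(adv$bp$probs, 1)
      }
      if (config$use_bmal) {
        adv$b <- discriminator_forward(db, ft$boundary_pred, keep = TRUE)
        ft_m_in <- if (config$disc_input == "entropy") {
          entropy_map(ft$mask_prob)
        } else ft$mask_prob
        adv$m <- discriminator_forward(dm, ft_m_in, keep = TRUE)
        L_adv_b <- bce(adv$b$probs, 1)
        L_adv_m <- bce(adv$m$probs, 1)
      }
      report <- total_loss(L_m, L_b, L_adv_m, L_adv_b, L_adv_bp, lam)
      if (!is.finite(report$L_total)) {
        warning("train_segmentation: non-finite loss at iteration ", iter,
                "; aborting and returning the last good checkpoint")
        diverged <- TRUE
        break
      }
      grads <- NULL
      for (s in labeled) {
        ne <- length(s$f$mask_prob)
        g_m <- (s$f$mask_prob - s$y) / (ne * nl)
        g_b <- grad_prob_to_logit(2 * (s$f$boundary_pred - s$yb) / (ne * nl),
                                  s$f$boundary_pred)
        if (lam > 0 && config$use_db_plus && s$enh) {
          dg <- discriminator_backward(dbp, adv$bp$caches,
                                       bce_grad_probs(adv$bp$probs, 1))
          g_b <- g_b + lam * grad_prob_to_logit(dg$gx[, , 1:2, drop = FALSE],
                                                s$f$boundary_pred)
        }
        gs <- segnet_backward(net, s$f$caches, g_mask_logit = g_m,
                              g_boundary_logit = g_b)
        grads <- if (is.null(grads)) gs else add_grads(grads, gs)
      }
      if (lam > 0 && config$use_bmal) {
        dgb <- discriminator_backward(db, adv$b$caches,
                                      bce_grad_probs(adv$b$probs, 1))
        g_bt <- lam * grad_prob_to_logit(dgb$gx[, , 1:2, drop = FALSE],
                                         ft$boundary_pred)
        dgm <- discriminator_backward(dm, adv$m$caches,
                                      bce_grad_probs(adv$m$probs, 1))
        g_m_in <- dgm$gx[, , 1:2, drop = FALSE]
        if (config$disc_input == "entropy") {
          g_m_in <- g_m_in * entropy_grad(ft$mask_prob)
        }
        g_mt <- lam * grad_prob_to_logit(g_m_in, ft$mask_prob)
        gt <- segnet_backward(net, ft$caches, g_mask_logit = g_mt,
                              g_boundary_logit = g_bt)
        grads <- add_grads(grads, gt)
      }
      if (!is.null(config$lr_decay_power)) {
        frac <- (iter - 1) / (config$epochs * length(source))
        opt_seg$lr <- config$seg_lr * (1 - frac)^config$lr_decay_power
      }
      layers <- segnet_layers(net)
      upd <- apply_grads(layers, grads[names(layers)], opt_seg)
      net <- segnet_set_layers(net, upd$layers)
      opt_seg <- upd$opt
      # ---- discriminator steps (generator frozen, detached maps) ----
      L_D_bp <- L_D_b <- L_D_m <- NA_real_
      if (config$use_db_plus) {
        r <- disc_step(dbp, opt_dbp,
                       real = list(fs$boundary_pred),
                       fake_fw = list(adv$bp))
        dbp <- r$disc; opt_dbp <- r$opt; L_D_bp <- r$loss
      }
      if (config$use_bmal) {
        # stochastic minibatch of the new source domain X_U: alternate
        # between the source and the enhanced prediction map
        use_enh <- config$use_cae && iter %% 2L == 0L
        fu <- if (use_enh) fe else fs
        r <- disc_step(db, opt_db, real = list(fu$boundary_pred),
                       fake_fw = list(adv$b))
        db <- r$disc; opt_db <- r$opt; L_D_b <- r$loss
        fu_m_in <- if (config$disc_input == "entropy") {
          entropy_map(fu$mask_prob)
        } else fu$mask_prob
        r <- disc_step(dm, opt_dm, real = list(fu_m_in),
                       fake_fw = list(adv$m))
        dm <- r$disc; opt_dm <- r$opt; L_D_m <- r$loss
      }
      log_rows[[iter]] <- data.frame(
        iter = iter, epoch = ep, L_m = L_m, L_b = L_b, L_adv_m = L_adv_m,
        L_adv_b = L_adv_b, L_adv_b_plus = L_adv_bp, L_D_m = L_D_m,
        L_D_b = L_D_b, L_D_b_plus = L_D_bp, L_total = report$L_total)
      last_good <- list(segnet = net, disc_b_plus = dbp, disc_b = db,
                        disc_m = dm, cae = cae, config = config)
    }
    if (diverged) break
    if (verbose) {
      rows <- do.call(rbind, log_rows[seq_len(iter)])
      ep_rows <- rows[rows$epoch == ep, , drop = FALSE]
      message(sprintf("epoch %d: L_m %.4f L_b %.4f L_total %.4f", ep,
                      mean(ep_rows$L_m), mean(ep_rows$L_b),
                      mean(ep_rows$L_total)))
    }
  }
  log <- do.call(rbind, log_rows[!vapply(log_rows, is.null, logical(1))])
  checkpoint <- last_good %||% list(segnet = net, disc_b_plus = dbp,
                                    disc_b = db, disc_m = dm, cae = cae,
                                    config = config)
  checkpoint$diverged <- diverged
  list(checkpoint = checkpoint, log = log)
}

# one SGD step on a discriminator: real maps labeled 1, fake maps labeled 0,
# each side normalized by its own batch size.  `fake_fw` may carry already
# computed forward results (probs + caches) for the fake maps — the
# discriminator has not been updated since the generator step, so those
# passes are identical and need not be recomputed.
disc_step <- function(disc, opt, real, fake = NULL, fake_fw = NULL) {
  loss <- 0
  grads <- zero_like_grads(disc$layers)
  for (x in real) {
    r <- discriminator_forward(disc, x, keep = TRUE)
    loss <- loss + bce(r$probs, 1) / length(real)
    bw <- discriminator_backward(disc, r$caches,
                                 bce_grad_probs(r$probs, 1) / length(real),
                                 input_grad = FALSE)
    grads <- add_grads(grads, bw$grads)
  }
  if (is.null(fake_fw)) {
    fake_fw <- lapply(fake, discriminator_forward, disc = disc, keep = TRUE)
  }
  for (r in fake_fw) {
    loss <- loss + bce(r$probs, 0) / length(fake_fw)
    bw <- discriminator_backward(disc, r$caches,
                                 bce_grad_probs(r$probs, 0) /
                                   length(fake_fw),
                                 input_grad = FALSE)
    grads <- add_grads(grads, bw$grads)
  }
  upd <- apply_grads(disc$layers, grads, opt)
  disc$layers <- upd$layers
  list(disc = disc, opt = upd$opt, loss = loss)
}

#' Predict segmentation masks for a list of images
#'
#' @param net a trained [build_segnet()].
#' @param images list of `H x W x 3` arrays.
#' @return list of `list(mask_prob, boundary_pred, mask)` where `mask` is
#'   the binarized prediction with the cup clipped to the disc (the cup is
#'   anatomically inside the disc, so cup pixels outside the predicted disc
#'   are dropped).
#' @export
predict_masks <- function(net, images) {
  lapply(images, function(x) {
    f <- segnet_forward(net, x, keep = FALSE)
    m <- binarize(f$mask_prob)
    m[, , 2] <- m[, , 2] * m[, , 1]
    list(mask_prob = f$mask_prob, boundary_pred = f$boundary_pred, mask = m)
  })
}
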