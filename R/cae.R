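# Convolutional autoencoder used to enhance the labeled source domain.
# Four stride-2 convolution stages contract the input by 16x into a latent
# code z = Q(x); a mirrored transposed-convolution decoder G maps z back to
# an image squashed into [0, 1].  The genuine information bottleneck makes
# reconstructions structurally faithful but blurred, with softened vessel
# detail — exactly the "same semantics, different details" images wanted for
# the enhanced domain.  The CAE is pretrained to minimize the reconstruction
# error on the source domain and then frozen; enhancement diversity comes
# from the bottleneck plus optional Gaussian latent jitter.

#' Build a convolutional autoencoder
#'
#' @param latent_channels channels of the latent code (spatial size is the
#'   input size divided by 16).
#' @param widths channel progression of the three intermediate encoder
#'   stages; the decoder mirrors it.
#' @param seed seed for weight initialization.
#' @return object of class `cae`.
#' @export
build_cae <- function(latent_channels = 16L, widths = c(32L, 64L, 128L),
                      seed = 1L) {
  stopifnot(length(widths) == 3)
  with_seed(seed, {
    enc <- list(nn_conv(3L, widths[1], 3L, stride = 2L, pad = 1L,
                        act = "lrelu"),
                nn_conv(widths[1], widths[2], 3L, stride = 2L, pad = 1L,
                        act = "lrelu"),
                nn_conv(widths[2], widths[3], 3L, stride = 2L, pad = 1L,
                        act = "lrelu"),
                nn_conv(widths[3], latent_channels, 3L, stride = 2L,
                        pad = 1L, act = "lrelu"))
    dec <- list(nn_tconv(latent_channels, widths[3], 4L, act = "lrelu"),
                nn_tconv(widths[3], widths[2], 4L, act = "lrelu"),
                nn_tconv(widths[2], widths[1], 4L, act = "lrelu"),
                nn_tconv(widths[1], 3L, 4L, act = "sigmoid"))
    structure(list(encoder = enc, decoder = dec,
                   latent_channels = as.integer(latent_channels),
                   pretrained = FALSE),
              class = "cae")
  })
}

check_cae_dims <- function(image) {
  d <- dim(image)
  if (d[1] %% 16L != 0L || d[2] %% 16L != 0L) {
    stop("cae: image dimensions must be divisible by 16 (four stride-2 ",
         "stages); got ", d[1], "x", d[2], call. = FALSE)
  }
}

#' Encode an image to its latent code
#'
#' @param cae a [build_cae()] object.
#' @param image `H x W x 3` array, `H` and `W` divisible by 16.
#' @return latent array of shape `H/16 x W/16 x latent_channels`.
#' @export
cae_encode <- function(cae, image) {
  check_cae_dims(image)
  seq_forward(cae$encoder, image, keep = FALSE)$out
}

#' Decode a latent code to an image
#'
#' @param cae a [build_cae()] object.
#' @param z latent array from [cae_encode()].
#' @return `H x W x 3` array with values in `[0, 1]`.
#' @export
cae_decode <- function(cae, z) {
  seq_forward(cae$decoder, z, keep = FALSE)$out
}

#' Autoencoder reconstruction error
#'
#' Mean squared pixel difference between an image and its reconstruction
#' (the squared L2 norm normalized by pixel count, so the scale is
#' independent of image size; set `normalize = FALSE` for the raw squared
#' norm).  Zero exactly when the two images are identical.
#'
#' @param x,x_plus equal-shape image arrays.
#' @param normalize divide by the number of elements (default).
#' @return nonnegative scalar.
#' @export
reconstruction_loss <- function(x, x_plus, normalize = TRUE) {
  if (!all(dim(x) == dim(x_plus))) {
    stop("reconstruction_loss: shape mismatch", call. = FALSE)
  }
  s <- sum((x - x_plus)^2)
  if (normalize) s / length(x) else s
}

#' Pretrain the autoencoder on source-domain images
#'
#' Minimizes the mean reconstruction error with Adam; stops early when the
#' epoch loss has stopped improving for `patience` epochs.
#'
#' @param cae a [build_cae()] object.
#' @param images list of `H x W x 3` arrays.
#' @param epochs maximum epochs.
#' @param lr Adam learning rate.
#' @param patience epochs without improvement before stopping.
#' @param seed seed controlling the shuffling order.
#' @param verbose print the epoch loss.
#' @return `list(cae, history)`; `history` is the per-epoch mean loss.
#' @export
pretrain_cae <- function(cae, images, epochs = 200L, lr = 1e-3,
                         patience = 20L, seed = 1L, verbose = FALSE) {
  stopifnot(length(images) >= 1)
  lapply(images, check_cae_dims)
  opt <- opt_adam(lr)
  layers <- c(cae$encoder, cae$decoder)
  n_enc <- length(cae$encoder)
  history <- numeric(0)
  best <- Inf
  stall <- 0L
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, paste0("cae-epoch", ep)),
                     sample.int(length(images)))
    ep_loss <- 0
    for (i in ord) {
      x <- images[[i]]
      fw <- seq_forward(layers, x, keep = TRUE)
      ep_loss <- ep_loss + reconstruction_loss(x, fw$out)
      g_out <- 2 * (fw$out - x) / length(x)
      bw <- seq_backward(layers, fw$caches, g_out, input_grad = FALSE)
      upd <- apply_grads(layers, bw$grads, opt)
      layers <- upd$layers
      opt <- upd$opt
    }
    ep_loss <- ep_loss / length(images)
    history <- c(history, ep_loss)
    if (verbose) message(sprintf("cae epoch %d: loss %.6f", ep, ep_loss))
    if (ep_loss < best - 1e-6) {
      best <- ep_loss
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  cae$encoder <- layers[seq_len(n_enc)]
  cae$decoder <- layers[-seq_len(n_enc)]
  cae$pretrained <- TRUE
  list(cae = cae, history = history)
}

#' Build the enhanced domain from the source domain
#'
#' Passes every source image through the frozen autoencoder (optionally
#' jittering the latent code with Gaussian noise) and attaches the source
#' label to the reconstruction — enhancement is 1:1, so the union of source
#' and enhanced sets has exactly twice the source count.
#'
#' @param cae a (pretrained) [build_cae()] object; using an untrained one
#'   logs a warning but proceeds.
#' @param source list of `list(image, mask, ...)` pairs.
#' @param jitter_sd standard deviation of latent jitter; 0 makes the
#'   enhanced set a deterministic function of weights and inputs.
#' @param seed seed for the jitter.
#' @return list of `list(image, mask, source_index)` of the same length as
#'   `source`, masks identical to the source masks by index.
#' @export
augment_domain <- function(cae, source, jitter_sd = 0.1, seed = 1L) {
  stopifnot(length(source) >= 1)
  if (!isTRUE(cae$pretrained)) {
    warning("augment_domain: autoencoder has not been pretrained; ",
            "enhanced images will be uninformative")
  }
  lapply(seq_along(source), function(i) {
    z <- cae_encode(cae, source[[i]]$image)
    if (jitter_sd > 0) {
      z <- z + with_seed(derive_seed(seed, paste0("jitter", i)),
                         array(rnorm(length(z), sd = jitter_sd), dim(z)))
    }
    list(image = cae_decode(cae, z), mask = source[[i]]$mask,
         source_index = i)
  })
}
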