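# Patch discriminators for output-space adversarial alignment.  The three
# discriminators (source-vs-enhanced boundary, new-source-vs-target boundary,
# new-source-vs-target mask) share one architecture and differ only in their
# input channels: five 4x4 stride-2 same-padded convolutions with channel
# progression base*(1,2,4,8) then 1, LeakyReLU after the first four layers
# and a sigmoid after the last.  Downsampling is 2^5 = 32, so a 512-px input
# yields a 16x16 grid of per-patch real/fake probabilities, and the analytic
# receptive field of one output unit is 94 px.

#' Build a patch discriminator
#'
#' @param in_channels channels of the input map (2 for the disc+cup boundary
#'   or mask maps).
#' @param base_channels width of the first layer; the published architecture
#'   uses 64 (channels 64/128/256/512/1), smaller values give the same
#'   geometry at desk scale.
#' @param slope LeakyReLU negative slope.  The printed value "alpha = 2" is
#'   not a usable slope (it would make the activation non-monotone in
#'   effect); the standard PatchGAN value 0.2 is the default and the slope
#'   stays configurable.
#' @param seed seed for weight initialization.
#' @return object of class `patch_discriminator`.
#' @export
build_discriminator <- function(in_channels, base_channels = 64L,
                                slope = 0.2, seed = 1L) {
  stopifnot(in_channels >= 1)
  ch <- c(in_channels, base_channels * c(1L, 2L, 4L, 8L), 1L)
  layers <- with_seed(seed, {
    lapply(seq_len(5), function(i) {
      act <- if (i < 5) "lrelu" else "sigmoid"
      nn_conv(ch[i], ch[i + 1], k = 4L, stride = 2L, pad = 1L, act = act,
              slope = slope)
    })
  })
  structure(list(layers = layers, in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels), slope = slope),
            class = "patch_discriminator")
}

#' Run a discriminator on a prediction map
#'
#' @param disc a [build_discriminator()] object.
#' @param x `H x W x C` input map (`C = in_channels`); `H`, `W` divisible
#'   by 32.
#' @param keep cache intermediate activations for a backward pass.
#' @return `list(probs, caches)`; `probs` is an `H/32 x W/32` grid with all
#'   entries strictly inside `(0, 1)`.
#' @export
discriminator_forward <- function(disc, x, keep = FALSE) {
  if (length(dim(x)) == 2) x <- array(x, c(dim(x), 1L))
  if (dim(x)[3] != disc$in_channels) {
    stop("discriminator_forward: expected ", disc$in_channels,
         " input channels, got ", dim(x)[3], call. = FALSE)
  }
  r <- seq_forward(disc$layers, x, keep = keep)
  list(probs = array(r$out[, , 1], dim(r$out)[1:2]), caches = r$caches)
}

# Backward pass; grad_probs has the patch-grid shape.  Returns gradients for
# the discriminator weights and for the input map (the latter carries the
# adversarial signal back into the segmentation network; skip it with
# `input_grad = FALSE` for pure discriminator updates).
discriminator_backward <- function(disc, caches, grad_probs,
                                   input_grad = TRUE) {
  g <- array(grad_probs, c(dim(grad_probs), 1L))
  seq_backward(disc$layers, caches, g, input_grad = input_grad)
}

#' Analytic receptive field of a stack of convolutions
#'
#' Applies the recurrence `rf = rf + (k - 1) * prod(previous strides)`
#' starting from a single pixel, giving the side length of the input region
#' seen by one output unit.
#'
#' @param kernels,strides equal-length integer vectors, one entry per layer.
#' @return receptive-field side length in input pixels.
#' @export
receptive_field <- function(kernels, strides) {
  if (length(kernels) == 0 || length(kernels) != length(strides)) {
    stop("receptive_field: kernels and strides must be nonempty and of ",
         "equal length", call. = FALSE)
  }
  r <- 1
  jump <- 1
  for (i in seq_along(kernels)) {
    r <- r + (kernels[i] - 1) * jump
    jump <- jump * strides[i]
  }
  r
}

#' Empirical receptive field of a built discriminator
#'
#' Measures the width of the input region whose perturbation changes one
#' central output unit, by perturbing single pixels along the central row of
#' an otherwise constant input.  With generic (e.g. random) nonzero weights
#' this equals the analytic [receptive_field()] of the layer stack, clipped
#' by the input size.
#'
#' @param disc a [build_discriminator()] object (or any list of conv layers
#'   under `$layers` with `$in_channels`).
#' @param input_size side length of the probe input; if smaller than the
#'   analytic receptive field the measured extent is clipped and a warning
#'   is raised.
#' @param delta perturbation magnitude.
#' @return measured receptive-field width in pixels.
#' @export
empirical_receptive_field <- function(disc, input_size = 128L, delta = 0.5) {
  kernels <- vapply(disc$layers, function(l) l$k, integer(1))
  strides <- vapply(disc$layers, function(l) l$stride, integer(1))
  analytic <- receptive_field(kernels, strides)
  if (input_size < analytic) {
    warning("empirical_receptive_field: input smaller than the analytic ",
            "receptive field; the measured extent is clipped")
  }
  x0 <- array(0.5, c(input_size, input_size, disc$in_channels))
  base <- seq_forward(disc$layers, x0, keep = FALSE)$out
  row <- input_size %/% 2L
  # find the output unit most sensitive to the central input pixel; its
  # receptive field contains the image center, so scanning the central row
  # traces that unit's full horizontal extent
  xc <- x0
  xc[row, row, ] <- xc[row, row, ] + delta
  dmap <- abs(seq_forward(disc$layers, xc, keep = FALSE)$out - base)
  if (max(dmap) <= 1e-12) return(0L)
  ctr <- which(dmap[, , 1] == max(dmap), arr.ind = TRUE)[1, ]
  affected <- logical(input_size)
  for (j in seq_len(input_size)) {
    x <- x0
    x[row, j, ] <- x[row, j, ] + delta
    out <- seq_forward(disc$layers, x, keep = FALSE)$out
    affected[j] <- abs(out[ctr[1], ctr[2], 1] - base[ctr[1], ctr[2], 1]) > 1e-12
  }
  if (!any(affected)) return(0L)
  as.integer(diff(range(which(affected))) + 1L)
}
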