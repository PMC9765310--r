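# Shared fixtures and oracles, all built in code.

fa <- asNamespace("fundusadapt")

# brute-force direct 2-d convolution, the oracle for the im2col path
brute_conv <- function(x, W, b, k, stride, pad, dilation = 1) {
  d <- dim(x); cin <- d[3]; cout <- length(b)
  keff <- (k - 1) * dilation + 1
  ho <- (d[1] + 2 * pad - keff) %/% stride + 1
  wo <- (d[2] + 2 * pad - keff) %/% stride + 1
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, cin))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  out <- array(0, c(ho, wo, cout))
  Wa <- array(W, c(k, k, cin, cout))
  for (o in seq_len(cout)) for (i in seq_len(ho)) for (j in seq_len(wo)) {
    acc <- b[o]
    for (c in seq_len(cin)) for (ki in seq_len(k)) for (kj in seq_len(k)) {
      acc <- acc + xp[(i - 1) * stride + (ki - 1) * dilation + 1,
                      (j - 1) * stride + (kj - 1) * dilation + 1, c] *
        Wa[ki, kj, c, o]
    }
    out[i, j, o] <- acc
  }
  out
}

# central-difference numerical gradient of scalar-valued f at x
num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rectangular two-channel mask: disc rows/cols, cup rows/cols (1-based)
rect_mask <- function(n, disc_r, disc_c, cup_r, cup_c) {
  m <- array(0, c(n, n, 2))
  m[disc_r, disc_c, 1] <- 1
  m[cup_r, cup_c, 2] <- 1
  m
}

# tiny labeled dataset of synthetic eyes for fast training tests
tiny_domain <- function(n, seed, size = 32L, shift = NULL) {
  sp <- if (is.null(shift)) {
    domain_spec(n, seed = seed, image_size = size)
  } else {
    domain_spec(n, shift = shift, seed = seed, image_size = size)
  }
  generate_domain(sp)
}

# a patch discriminator with constant output 0.5 (all weights and biases 0)
const_half_disc <- function(in_channels = 2L) {
  d <- build_discriminator(in_channels, base_channels = 2L, seed = 1L)
  d$layers <- lapply(d$layers, function(l) {
    l$W[] <- 0; l$b[] <- 0; l
  })
  d
}

# a discriminator calibrated to output ~1 on every patch of `hi` and ~0 on
# every patch of `lo` (all-positive weights are monotone in the input, so
# rescaling and shifting the last layer separates the two patch-logit sets)
calibrated_disc <- function(hi, lo) {
  d <- build_discriminator(dim(hi)[3], base_channels = 2L, seed = 1L)
  d$layers <- lapply(d$layers, function(l) { l$W[] <- abs(l$W); l$b[] <- 0; l })
  # pre-sigmoid logits of the last layer (the sigmoid itself saturates)
  pre <- function(x) {
    lin <- d; lin$layers[[5]]$act <- "linear"
    fa$seq_forward(lin$layers, x, keep = FALSE)$out
  }
  s_hi <- min(pre(hi))
  s_lo <- max(pre(lo))
  stopifnot(s_hi > s_lo)
  scale <- 40 / (s_hi - s_lo)
  d$layers[[5]]$W <- d$layers[[5]]$W * scale
  d$layers[[5]]$b <- -(s_hi + s_lo) / 2 * scale
  d
}
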