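# Minimal CNN layer toolkit: 2-d convolution, transposed convolution,
# nearest-neighbour upsampling and pointwise activations, each with an
# explicit backward pass.  Feature maps are H x W x C arrays; convolution is
# im2col (C++) + BLAS matrix products.  This is deliberately small: only the
# pieces the segmentation network, autoencoder and patch discriminators need.

conv_out_extent <- function(n, k, stride, pad, dilation = 1L) {
  keff <- (k - 1L) * dilation + 1L
  (n + 2L * pad - keff) %/% stride + 1L
}

act_forward <- function(z, act, slope = 0.2) {
  switch(act,
    linear = z,
    relu = pmax(z, 0),
    lrelu = ifelse(z > 0, z, slope * z),
    sigmoid = 1 / (1 + exp(-z))
  )
}

# derivative of the activation given pre-activation z and output a
act_grad <- function(z, a, act, slope = 0.2) {
  switch(act,
    linear = 1,
    relu = (z > 0) * 1,
    lrelu = ifelse(z > 0, 1, slope),
    sigmoid = a * (1 - a)
  )
}

he_init <- function(fan_in, n, act) {
  gain <- if (act %in% c("relu", "lrelu")) sqrt(2) else 1
  rnorm(n, sd = gain / sqrt(fan_in))
}

#' @noRd
nn_conv <- function(cin, cout, k, stride = 1L, pad = NULL, dilation = 1L,
                    act = "relu", slope = 0.2) {
  if (is.null(pad)) pad <- ((k - 1L) * dilation) %/% 2L  # same-padding, odd k
  W <- matrix(he_init(k * k * cin, k * k * cin * cout, act),
              nrow = k * k * cin, ncol = cout)
  list(type = "conv", cin = cin, cout = cout, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad),
       dilation = as.integer(dilation), act = act, slope = slope,
       W = W, b = numeric(cout))
}

#' @noRd
nn_tconv <- function(cin, cout, k, stride = 2L, pad = 1L, act = "relu",
                     slope = 0.2) {
  # weight layout (k*k*cout) x cin; forward is the adjoint of a conv
  W <- matrix(he_init(k * k * cin / (stride * stride), k * k * cout * cin, act),
              nrow = k * k * cout, ncol = cin)
  list(type = "tconv", cin = cin, cout = cout, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad), act = act,
       slope = slope, W = W, b = numeric(cout))
}

#' @noRd
nn_upsample <- function(factor) {
  list(type = "upsample", factor = as.integer(factor))
}

act_code <- function(act) {
  match(act, c("linear", "relu", "lrelu", "sigmoid")) - 1L
}

layer_forward <- function(layer, x) {
  switch(layer$type,
    conv = {
      out <- conv_fwd(x, layer$W, layer$b, layer$k, layer$stride,
                      layer$pad, layer$dilation, act_code(layer$act),
                      layer$slope)
      list(out = out, cache = list(x = x, a = out))
    },
    tconv = {
      out <- tconv_fwd(x, layer$W, layer$b, layer$k, layer$stride,
                       layer$pad, act_code(layer$act), layer$slope)
      list(out = out, cache = list(x = x, a = out))
    },
    upsample = {
      d <- dim(x)
      f <- layer$factor
      out <- x[rep(seq_len(d[1]), each = f), rep(seq_len(d[2]), each = f), ,
               drop = FALSE]
      list(out = out, cache = list(in_dim = d))
    }
  )
}

layer_backward <- function(layer, cache, grad_out, need_gx = TRUE) {
  switch(layer$type,
    conv = {
      conv_bwd(cache$x, cache$a, layer$W, grad_out, layer$k, layer$stride,
               layer$pad, layer$dilation, act_code(layer$act), layer$slope,
               need_gx)
    },
    tconv = {
      tconv_bwd(cache$x, cache$a, layer$W, grad_out, layer$k, layer$stride,
                layer$pad, act_code(layer$act), layer$slope, need_gx)
    },
    upsample = {
      f <- layer$factor
      d <- cache$in_dim
      m <- array(grad_out, c(f, d[1], f * d[2] * d[3]))
      s1 <- array(colSums(m, dims = 1), c(d[1], f, d[2], d[3]))
      s1 <- aperm(s1, c(2, 1, 3, 4))
      gx <- array(colSums(s1, dims = 1), d)
      list(gx = gx, gW = NULL, gb = NULL)
    }
  )
}

seq_forward <- function(layers, x, keep = TRUE) {
  caches <- if (keep) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x)
    x <- r$out
    if (keep) caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

seq_backward <- function(layers, caches, grad_out, input_grad = TRUE) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], caches[[i]], grad_out,
                        need_gx = input_grad || i > 1L)
    grad_out <- r$gx
    grads[[i]] <- list(gW = r$gW, gb = r$gb)
  }
  list(gx = grad_out, grads = grads)
}

# ---- gradient bookkeeping ---------------------------------------------------

zero_like_grads <- function(layers) {
  lapply(layers, function(l) {
    if (is.null(l$W)) list(gW = NULL, gb = NULL)
    else list(gW = array(0, dim(l$W)), gb = numeric(length(l$b)))
  })
}

add_grads <- function(g1, g2, scale = 1) {
  for (i in seq_along(g1)) {
    if (!is.null(g2[[i]]$gW)) {
      g1[[i]]$gW <- g1[[i]]$gW + scale * g2[[i]]$gW
      g1[[i]]$gb <- g1[[i]]$gb + scale * g2[[i]]$gb
    }
  }
  g1
}

# ---- optimizers -------------------------------------------------------------

opt_sgd <- function(lr) list(kind = "sgd", lr = lr)

opt_adam <- function(lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(kind = "adam", lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       t = 0L, m = list(), v = list())
}

# One optimizer step over a list of layers given matching grads.
# Returns list(layers, opt) (Adam carries moment state).
apply_grads <- function(layers, grads, opt) {
  if (opt$kind == "sgd") {
    for (i in seq_along(layers)) {
      if (is.null(grads[[i]]$gW)) next
      layers[[i]]$W <- layers[[i]]$W - opt$lr * grads[[i]]$gW
      layers[[i]]$b <- layers[[i]]$b - opt$lr * grads[[i]]$gb
    }
    return(list(layers = layers, opt = opt))
  }
  opt$t <- opt$t + 1L
  for (i in seq_along(layers)) {
    if (is.null(grads[[i]]$gW)) next
    key <- as.character(i)
    if (is.null(opt$m[[key]])) {
      opt$m[[key]] <- list(W = array(0, dim(layers[[i]]$W)),
                           b = numeric(length(layers[[i]]$b)))
      opt$v[[key]] <- opt$m[[key]]
    }
    for (p in c("W", "b")) {
      g <- grads[[i]][[paste0("g", p)]]
      u <- adam_fused(layers[[i]][[p]], g, opt$m[[key]][[p]],
                      opt$v[[key]][[p]], opt$lr, opt$beta1, opt$beta2,
                      opt$eps, opt$t)
      opt$m[[key]][[p]] <- u$m
      opt$v[[key]][[p]] <- u$v
      if (p == "W" && is.matrix(layers[[i]]$W)) {
        dim(u$w) <- dim(layers[[i]]$W)
      }
      layers[[i]][[p]] <- u$w
    }
  }
  list(layers = layers, opt = opt)
}
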