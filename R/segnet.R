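# Boundary-aware segmentation network.  An encoder backbone contracts the
# image (stride 8), an atrous spatial pyramid pooling (ASPP) block fuses
# parallel dilated convolutions at multiple rates, the fused high-level
# features are upsampled and concatenated with early low-level features
# (stride 4), and two branches predict per-structure soft boundaries and
# masks.  The mask branch sees the concatenation of the shared decoder
# features and the boundary prediction, so boundary evidence conditions the
# mask directly.  Disc and cup are scored with independent sigmoids
# (multi-label): the cup is always inside the disc, so the classes cannot be
# mutually exclusive.

segnet_registry <- function() {
  list(
    deeplab_like = list(w1 = 32L, w2 = 64L, w3 = 256L, wa = 64L,
                        wf = 256L, wb = 256L),
    tiny = list(w1 = 4L, w2 = 8L, w3 = 16L, wa = 4L, wf = 8L, wb = 8L)
  )
}

#' Build an encoder backbone with ASPP
#'
#' @param name one of the registered backbones: `deeplab_like` (full-width)
#'   or `tiny` (reduced width for desk-scale runs; same topology).
#' @param aspp_rates dilation rates of the parallel ASPP branches; rate 1 is
#'   realized as a 1x1 convolution.
#' @param seed seed for weight initialization.
#' @return object of class `seg_backbone` with `$layers`, `$widths`,
#'   `$rates`.
#' @export
build_backbone <- function(name = "tiny", aspp_rates = c(1L, 6L, 12L, 18L),
                           seed = 1L) {
  reg <- segnet_registry()
  if (!name %in% names(reg)) {
    stop("unknown backbone '", name, "'; registry: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  w <- reg[[name]]
  layers <- with_seed(seed, {
    l <- list(
      stem1 = nn_conv(3L, w$w1, 3L, stride = 2L, pad = 1L, act = "relu"),
      stem2 = nn_conv(w$w1, w$w2, 3L, stride = 2L, pad = 1L, act = "relu"),
      down3 = nn_conv(w$w2, w$w3, 3L, stride = 2L, pad = 1L, act = "relu")
    )
    for (i in seq_along(aspp_rates)) {
      r <- aspp_rates[i]
      l[[paste0("aspp_", i)]] <- if (r == 1L) {
        nn_conv(w$w3, w$wa, 1L, act = "relu")
      } else {
        nn_conv(w$w3, w$wa, 3L, dilation = as.integer(r),
                pad = as.integer(r), act = "relu")
      }
    }
    l$aspp_fuse <- nn_conv(length(aspp_rates) * w$wa, w$w3, 1L, act = "relu")
    l
  })
  structure(list(name = name, layers = layers, widths = w,
                 rates = as.integer(aspp_rates),
                 low_channels = w$w2, out_channels = w$w3),
            class = "seg_backbone")
}

#' Run a backbone on an image
#'
#' @param backbone a [build_backbone()] object.
#' @param x `H x W x 3` array, `H` and `W` divisible by 8.
#' @param keep cache activations for a backward pass.
#' @return `list(low, high, caches)`: low-level features at stride 4 and
#'   ASPP-fused high-level features at stride 8.
#' @export
backbone_forward <- function(backbone, x, keep = FALSE) {
  L <- backbone$layers
  ca <- list()
  r1 <- layer_forward(L$stem1, x);  if (keep) ca$stem1 <- r1$cache
  r2 <- layer_forward(L$stem2, r1$out); if (keep) ca$stem2 <- r2$cache
  r3 <- layer_forward(L$down3, r2$out); if (keep) ca$down3 <- r3$cache
  branches <- list()
  for (i in seq_along(backbone$rates)) {
    nm <- paste0("aspp_", i)
    rb <- layer_forward(L[[nm]], r3$out)
    if (keep) ca[[nm]] <- rb$cache
    branches[[i]] <- rb$out
  }
  d3 <- dim(branches[[1]])
  cat_out <- array(unlist(branches, use.names = FALSE),
                   c(d3[1], d3[2], d3[3] * length(branches)))
  rf <- layer_forward(L$aspp_fuse, cat_out)
  if (keep) {
    ca$aspp_fuse <- rf$cache
    ca$dims <- list(branch = d3, n_branch = length(branches))
  }
  list(low = r2$out, high = rf$out, caches = ca)
}

#' Build the full segmentation network
#'
#' @param backbone backbone name passed to [build_backbone()], or a
#'   prebuilt `seg_backbone`.
#' @param aspp_rates ASPP dilation rates.
#' @param shared_boundary_trunk if `TRUE` (default) the boundary branch is a
#'   shared 2-layer trunk with one 1-channel head per structure; if `FALSE`
#'   the whole 3-layer branch is duplicated per structure.
#' @param seed seed for weight initialization.
#' @return object of class `seg_network`.
#' @export
build_segnet <- function(backbone = "tiny", aspp_rates = c(1L, 6L, 12L, 18L),
                         shared_boundary_trunk = TRUE, seed = 1L) {
  if (is.character(backbone)) {
    backbone <- build_backbone(backbone, aspp_rates,
                               seed = derive_seed(seed, "backbone"))
  }
  w <- backbone$widths
  heads <- with_seed(derive_seed(seed, "heads"), {
    h <- list(
      dec = nn_conv(w$w3 + w$w2, w$wf, 3L, act = "relu")
    )
    if (shared_boundary_trunk) {
      h$btrunk1 <- nn_conv(w$wf, w$wb, 3L, act = "relu")
      h$btrunk2 <- nn_conv(w$wb, w$wb, 3L, act = "relu")
      h$bhead_disc <- nn_conv(w$wb, 1L, 1L, act = "linear")
      h$bhead_cup <- nn_conv(w$wb, 1L, 1L, act = "linear")
    } else {
      for (s in c("disc", "cup")) {
        h[[paste0("btrunk1_", s)]] <- nn_conv(w$wf, w$wb, 3L, act = "relu")
        h[[paste0("btrunk2_", s)]] <- nn_conv(w$wb, w$wb, 3L, act = "relu")
        h[[paste0("bhead_", s)]] <- nn_conv(w$wb, 1L, 1L, act = "linear")
      }
    }
    h$m1 <- nn_conv(w$wf + 2L, w$wb, 3L, act = "relu")
    h$m2 <- nn_conv(w$wb, 2L, 1L, act = "linear")
    h
  })
  structure(list(backbone = backbone, heads = heads,
                 shared_boundary_trunk = shared_boundary_trunk,
                 upsample = nn_upsample(4L)),
            class = "seg_network")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

boundary_branch_forward <- function(net, f, keep) {
  H <- net$heads
  ca <- list()
  if (net$shared_boundary_trunk) {
    t1 <- layer_forward(H$btrunk1, f); if (keep) ca$btrunk1 <- t1$cache
    t2 <- layer_forward(H$btrunk2, t1$out); if (keep) ca$btrunk2 <- t2$cache
    hd <- layer_forward(H$bhead_disc, t2$out)
    hc <- layer_forward(H$bhead_cup, t2$out)
    if (keep) { ca$bhead_disc <- hd$cache; ca$bhead_cup <- hc$cache }
    d <- dim(hd$out)
    logit <- array(c(hd$out, hc$out), c(d[1], d[2], 2L))
  } else {
    outs <- list()
    for (s in c("disc", "cup")) {
      t1 <- layer_forward(H[[paste0("btrunk1_", s)]], f)
      t2 <- layer_forward(H[[paste0("btrunk2_", s)]], t1$out)
      hh <- layer_forward(H[[paste0("bhead_", s)]], t2$out)
      if (keep) {
        ca[[paste0("btrunk1_", s)]] <- t1$cache
        ca[[paste0("btrunk2_", s)]] <- t2$cache
        ca[[paste0("bhead_", s)]] <- hh$cache
      }
      outs[[s]] <- hh$out
    }
    d <- dim(outs$disc)
    logit <- array(c(outs$disc, outs$cup), c(d[1], d[2], 2L))
  }
  list(logit = logit, caches = ca)
}

#' Forward pass of the segmentation network
#'
#' @param net a [build_segnet()] object.
#' @param x `H x W x 3` image, `H` and `W` divisible by 8.
#' @param keep cache activations for a backward pass (training mode).
#' @return `list(mask_prob, boundary_pred, shared_features, caches)`;
#'   `mask_prob` and `boundary_pred` are `H x W x 2` arrays in `[0, 1]`
#'   spatially aligned with the input (disc channel first).
#' @export
segnet_forward <- function(net, x, keep = FALSE) {
  d <- dim(x)
  if (d[1] %% 8L != 0L || d[2] %% 8L != 0L) {
    stop("segnet_forward: image dimensions must be divisible by 8",
         call. = FALSE)
  }
  bb <- backbone_forward(net$backbone, x, keep = keep)
  up2 <- nn_upsample(2L)
  ru <- layer_forward(up2, bb$high)
  dlow <- dim(bb$low)
  cat1 <- array(c(ru$out, bb$low),
                c(dlow[1], dlow[2], dim(ru$out)[3] + dlow[3]))
  rd <- layer_forward(net$heads$dec, cat1)
  f <- rd$out
  bfw <- boundary_branch_forward(net, f, keep)
  b_prob_low <- sigmoid(bfw$logit)
  df <- dim(f)
  cat2 <- array(c(f, b_prob_low), c(df[1], df[2], df[3] + 2L))
  rm1 <- layer_forward(net$heads$m1, cat2)
  rm2 <- layer_forward(net$heads$m2, rm1$out)
  m_prob_low <- sigmoid(rm2$out)
  upf <- layer_forward(net$upsample, m_prob_low)
  upb <- layer_forward(net$upsample, b_prob_low)
  caches <- NULL
  if (keep) {
    caches <- list(bb = bb$caches, up2 = ru$cache, dec = rd$cache,
                   branch = bfw$caches, m1 = rm1$cache, m2 = rm2$cache,
                   b_prob_low = b_prob_low, m_prob_low = m_prob_low,
                   dims = list(low = dlow, high = dim(bb$high), f = df,
                               up2_in = dim(bb$high)))
  }
  list(mask_prob = upf$out, boundary_pred = upb$out, shared_features = f,
       caches = caches)
}

downsample_sum <- function(g, f) {
  d <- dim(g)
  h <- d[1] %/% f; w <- d[2] %/% f; c <- d[3]
  m <- array(g, c(f, h, f * w * c))
  s1 <- array(colSums(m, dims = 1), c(h, f, w, c))
  array(colSums(aperm(s1, c(2, 1, 3, 4)), dims = 1), c(h, w, c))
}

# Backward pass.  Gradients are given with respect to the full-resolution
# mask/boundary LOGITS (the sigmoid is pointwise and the upsampling nearest-
# neighbour, so sigmoid(upsample(logit)) == upsample(sigmoid(logit)) and
# callers can phrase losses in either space; helpers below convert).
# Returns named grads for heads and backbone layers plus nothing else.
segnet_backward <- function(net, caches, g_mask_logit = NULL,
                            g_boundary_logit = NULL) {
  H <- net$heads
  ca <- caches
  grads <- list()
  df <- ca$dims$f
  # mask path
  if (is.null(g_mask_logit)) {
    g_m_low <- array(0, c(df[1], df[2], 2L))
  } else {
    g_m_low <- downsample_sum(g_mask_logit, 4L)
  }
  rm2 <- layer_backward(H$m2, ca$m2, g_m_low)
  grads$m2 <- rm2[c("gW", "gb")]
  rm1 <- layer_backward(H$m1, ca$m1, rm2$gx)
  grads$m1 <- rm1[c("gW", "gb")]
  gcat2 <- rm1$gx
  gF_m <- gcat2[, , seq_len(df[3]), drop = FALSE]
  g_bprob_from_mask <- gcat2[, , df[3] + (1:2), drop = FALSE]
  # boundary path
  g_b_low <- if (is.null(g_boundary_logit)) {
    array(0, c(df[1], df[2], 2L))
  } else {
    downsample_sum(g_boundary_logit, 4L)
  }
  s <- ca$b_prob_low
  g_b_logit_low <- g_b_low + g_bprob_from_mask * s * (1 - s)
  if (net$shared_boundary_trunk) {
    gd <- array(g_b_logit_low[, , 1], c(df[1], df[2], 1L))
    gc <- array(g_b_logit_low[, , 2], c(df[1], df[2], 1L))
    rhd <- layer_backward(H$bhead_disc, ca$branch$bhead_disc, gd)
    rhc <- layer_backward(H$bhead_cup, ca$branch$bhead_cup, gc)
    grads$bhead_disc <- rhd[c("gW", "gb")]
    grads$bhead_cup <- rhc[c("gW", "gb")]
    rt2 <- layer_backward(H$btrunk2, ca$branch$btrunk2, rhd$gx + rhc$gx)
    grads$btrunk2 <- rt2[c("gW", "gb")]
    rt1 <- layer_backward(H$btrunk1, ca$branch$btrunk1, rt2$gx)
    grads$btrunk1 <- rt1[c("gW", "gb")]
    gF_b <- rt1$gx
  } else {
    gF_b <- 0
    for (i in 1:2) {
      s_nm <- c("disc", "cup")[i]
      gh <- array(g_b_logit_low[, , i], c(df[1], df[2], 1L))
      rh <- layer_backward(H[[paste0("bhead_", s_nm)]],
                           ca$branch[[paste0("bhead_", s_nm)]], gh)
      grads[[paste0("bhead_", s_nm)]] <- rh[c("gW", "gb")]
      rt2 <- layer_backward(H[[paste0("btrunk2_", s_nm)]],
                            ca$branch[[paste0("btrunk2_", s_nm)]], rh$gx)
      grads[[paste0("btrunk2_", s_nm)]] <- rt2[c("gW", "gb")]
      rt1 <- layer_backward(H[[paste0("btrunk1_", s_nm)]],
                            ca$branch[[paste0("btrunk1_", s_nm)]], rt2$gx)
      grads[[paste0("btrunk1_", s_nm)]] <- rt1[c("gW", "gb")]
      gF_b <- gF_b + rt1$gx
    }
  }
  # decoder and backbone
  rdec <- layer_backward(H$dec, ca$dec, gF_m + gF_b)
  grads$dec <- rdec[c("gW", "gb")]
  dlow <- ca$dims$low
  n_up <- ca$dims$high[3]
  g_up <- rdec$gx[, , seq_len(n_up), drop = FALSE]
  g_low_extra <- rdec$gx[, , n_up + seq_len(dlow[3]), drop = FALSE]
  rup <- layer_backward(nn_upsample(2L), ca$up2, g_up)
  g_high <- rup$gx
  B <- net$backbone$layers
  rf <- layer_backward(B$aspp_fuse, ca$bb$aspp_fuse, g_high)
  grads$aspp_fuse <- rf[c("gW", "gb")]
  bd <- ca$bb$dims$branch
  g_d3 <- 0
  for (i in seq_len(ca$bb$dims$n_branch)) {
    nm <- paste0("aspp_", i)
    gi <- rf$gx[, , (i - 1L) * bd[3] + seq_len(bd[3]), drop = FALSE]
    rb <- layer_backward(B[[nm]], ca$bb[[nm]], gi)
    grads[[nm]] <- rb[c("gW", "gb")]
    g_d3 <- g_d3 + rb$gx
  }
  r3 <- layer_backward(B$down3, ca$bb$down3, g_d3)
  grads$down3 <- r3[c("gW", "gb")]
  r2 <- layer_backward(B$stem2, ca$bb$stem2, r3$gx + g_low_extra)
  grads$stem2 <- r2[c("gW", "gb")]
  r1 <- layer_backward(B$stem1, ca$bb$stem1, r2$gx, need_gx = FALSE)
  grads$stem1 <- r1[c("gW", "gb")]
  grads
}

# flat named list of all trainable layers of a segnet, and writing back
segnet_layers <- function(net) c(net$backbone$layers, net$heads)

segnet_set_layers <- function(net, layers) {
  nb <- names(net$backbone$layers)
  net$backbone$layers <- layers[nb]
  net$heads <- layers[setdiff(names(layers), nb)]
  net
}

# convert a gradient w.r.t. an output probability map into a gradient
# w.r.t. the corresponding logit map
grad_prob_to_logit <- function(g_prob, prob) g_prob * prob * (1 - prob)

#' Save / load network checkpoints
#'
#' @param object any package network object (`seg_network`, `cae`,
#'   `patch_discriminator`, or a list of them).
#' @param path file path.
#' @return `load_checkpoint` returns the stored object.
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
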