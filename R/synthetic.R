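# Seeded generator of fundus-like phantoms: an elliptical optic disc with a
# concentric-but-offset elliptical cup, curvilinear dark vessels, and a
# controllable source->target shift in brightness, contrast and vessel
# density.  Stands in for real cropped-ROI fundus datasets at desk scale.
#
# Coordinate convention: row-major, 0-based pixel indices; pixel (i, j)
# covers the unit square [i, i+1) x [j, j+1) and its center is (i+0.5,
# j+0.5).  Ellipses are rasterized by center inclusion, so an ellipse with
# integer-valued center and vertical semi-axis a spans exactly 2a rows.

#' Parameters of one synthetic eye
#'
#' Bundles the geometry and photometry of a single phantom: disc and cup
#' ellipses (the cup strictly inside the disc), vessel count/width, and
#' global tone/brightness/contrast/noise.  Axes are given as
#' `(vertical semi-axis, horizontal semi-axis)` in pixels.
#'
#' @param image_size side length in pixels (square images).
#' @param disc_center `(row, col)` center of the disc ellipse in pixels.
#' @param disc_axes `(semi-major, semi-minor)` in pixels; the first entry is
#'   the vertical (row) semi-axis.
#' @param cup_axes as `disc_axes`, strictly smaller componentwise.
#' @param cup_offset `(row, col)` offset of the cup center from the disc
#'   center.
#' @param vessel_count number of vessel strokes.
#' @param vessel_width stroke width in pixels.
#' @param background_tone base retinal tone in `[0, 1]`.
#' @param brightness multiplicative brightness factor.
#' @param contrast multiplicative contrast factor (about mid-gray).
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @return an object of class `eye_params`.
#' @export
eye_params <- function(image_size = 128L,
                       disc_center = c(image_size / 2, image_size / 2),
                       disc_axes = c(22, 20),
                       cup_axes = c(10, 9),
                       cup_offset = c(0, 0),
                       vessel_count = 4L,
                       vessel_width = 2,
                       background_tone = 0.5,
                       brightness = 1,
                       contrast = 1,
                       noise_sd = 0.02) {
  p <- list(image_size = as.integer(image_size), disc_center = disc_center,
            disc_axes = disc_axes, cup_axes = cup_axes,
            cup_offset = cup_offset, vessel_count = as.integer(vessel_count),
            vessel_width = vessel_width, background_tone = background_tone,
            brightness = brightness, contrast = contrast, noise_sd = noise_sd)
  class(p) <- "eye_params"
  validate_eye_params(p)
  p
}

validate_eye_params <- function(p) {
  stopifnot(p$image_size >= 16L, p$background_tone >= 0,
            p$background_tone <= 1, p$noise_sd >= 0, p$vessel_count >= 0)
  if (any(p$cup_axes >= p$disc_axes)) {
    stop("invalid geometry: cup axes must be strictly smaller than disc axes",
         call. = FALSE)
  }
  if (any(p$disc_center - p$disc_axes < 0) ||
      any(p$disc_center + p$disc_axes > p$image_size)) {
    stop("invalid geometry: disc ellipse exceeds image bounds", call. = FALSE)
  }
  disc <- rasterize_ellipse(p$image_size, p$disc_center, p$disc_axes)
  cup <- rasterize_ellipse(p$image_size, p$disc_center + p$cup_offset,
                           p$cup_axes)
  if (any(cup > disc)) {
    stop("invalid geometry: cup ellipse is not contained in the disc ellipse",
         call. = FALSE)
  }
  invisible(p)
}

# binary H x W matrix; center in 0-based continuous coordinates
rasterize_ellipse <- function(size, center, axes) {
  cc <- (seq_len(size) - 0.5)  # pixel centers
  du <- (cc - center[1]) / axes[1]
  dv <- (cc - center[2]) / axes[2]
  outer(du^2, dv^2, `+`) <= 1
}

quad_bezier <- function(p0, p1, p2, n = 400L) {
  t <- seq(0, 1, length.out = n)
  cbind((1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1],
        (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2])
}

# stamp dark strokes onto a H x W attenuation matrix (1 = untouched)
draw_vessels <- function(size, disc_center, disc_axes, count, width) {
  att <- matrix(1, size, size)
  if (count == 0L) return(att)
  half <- max(1, width) / 2
  for (v in seq_len(count)) {
    side <- sample.int(4L, 1L)
    s <- runif(1, 0.1, 0.9) * size
    p0 <- switch(side, c(0, s), c(size, s), c(s, 0), c(s, size))
    p2 <- switch(side, c(size, size - s), c(0, size - s),
                 c(size - s, size), c(size - s, 0))
    # control point near the disc so strokes cross the disc region
    p1 <- disc_center + rnorm(2, sd = disc_axes / 2)
    pts <- quad_bezier(p0, p1, p2)
    ij <- unique(round(pts - 0.5))
    for (r in seq(-ceiling(half), ceiling(half))) {
      for (c in seq(-ceiling(half), ceiling(half))) {
        if (r * r + c * c > half * half + 0.5) next
        pp <- sweep(ij, 2, c(r, c), `+`)
        keep <- pp[, 1] >= 0 & pp[, 1] < size & pp[, 2] >= 0 & pp[, 2] < size
        att[pp[keep, , drop = FALSE] + 1] <- 0.45
      }
    }
  }
  att
}

#' Generate one synthetic fundus image with its ground-truth mask
#'
#' Renders background, disc and cup as nested bright ellipses in a reddish
#' palette, overlays dark vessel strokes (which never alter the mask), then
#' applies brightness, contrast and additive Gaussian noise.
#'
#' @param params an [eye_params()] object.
#' @param seed integer seed; generation is a pure function of
#'   `(params, seed)`.
#' @return `list(image, mask)` where `image` is an `H x W x 3` array in
#'   `[0, 1]` and `mask` an `H x W x 2` binary array (disc, cup) with the cup
#'   a pixelwise subset of the disc.
#' @export
generate_eye <- function(params, seed = 1L) {
  validate_eye_params(params)
  with_seed(seed, {
    n <- params$image_size
    disc <- rasterize_ellipse(n, params$disc_center, params$disc_axes)
    cup <- rasterize_ellipse(n, params$disc_center + params$cup_offset,
                             params$cup_axes)
    tone <- params$background_tone
    base_rgb <- c(1.0, 0.55, 0.30)
    disc_rgb <- c(1.0, 0.92, 0.62)
    cup_rgb <- c(1.0, 1.0, 0.80)
    att <- draw_vessels(n, params$disc_center, params$disc_axes,
                        params$vessel_count, params$vessel_width)
    img <- array(0, c(n, n, 3))
    disc_tone <- min(tone + 0.25, 1)
    cup_tone <- min(tone + 0.40, 1)
    for (ch in 1:3) {
      plane <- tone * base_rgb[ch] * (1 - disc) +
        disc_tone * disc_rgb[ch] * (disc & !cup) +
        cup_tone * cup_rgb[ch] * cup
      img[, , ch] <- plane * att
    }
    img <- 0.5 + (img - 0.5) * params$contrast
    img <- img * params$brightness
    if (params$noise_sd > 0) {
      img <- img + rnorm(length(img), sd = params$noise_sd)
    }
    img <- pmin(pmax(img, 0), 1)
    mask <- array(0, c(n, n, 2))
    mask[, , 1] <- disc
    mask[, , 2] <- cup
    list(image = img, mask = mask)
  })
}

#' Default sampling intervals for synthetic eye parameters
#'
#' Intervals are fractions of the image size where geometric; these defaults
#' emulate a pre-cropped optic-disc ROI: the disc occupies roughly a third of
#' the frame, the cup 30-60% of the disc, with mild photometric variation.
#'
#' @return named list of `c(min, max)` intervals.
#' @export
default_param_ranges <- function() {
  list(center_frac = c(0.42, 0.58),      # disc center, fraction of size
       disc_frac = c(0.14, 0.20),        # vertical semi-axis / size
       disc_aspect = c(0.85, 1.0),       # horizontal / vertical semi-axis
       cup_ratio = c(0.30, 0.60),        # cup semi-axes / disc semi-axes
       cup_offset_frac = c(-0.15, 0.15), # offset / disc semi-axis
       vessel_count = c(3, 6),
       vessel_width = c(1.5, 2.5),
       background_tone = c(0.45, 0.55),
       brightness = c(0.92, 1.08),
       contrast = c(0.92, 1.08),
       noise_sd = c(0.015, 0.025))
}

sample_eye_params <- function(ranges, image_size, cup_ratio = NULL) {
  ru <- function(nm) runif(1, ranges[[nm]][1], ranges[[nm]][2])
  size <- image_size
  a <- ru("disc_frac") * size
  b <- a * ru("disc_aspect")
  ratio <- if (is.null(cup_ratio)) ru("cup_ratio") else cup_ratio
  center <- c(ru("center_frac"), ru("center_frac")) * size
  off_max <- (1 - ratio) * 0.8
  off <- pmin(pmax(c(ru("cup_offset_frac"), ru("cup_offset_frac")), -off_max),
              off_max) * c(a, b)
  eye_params(image_size = size,
             disc_center = center,
             disc_axes = c(a, b),
             cup_axes = ratio * c(a, b),
             cup_offset = off,
             vessel_count = round(ru("vessel_count")),
             vessel_width = ru("vessel_width"),
             background_tone = ru("background_tone"),
             brightness = ru("brightness"),
             contrast = ru("contrast"),
             noise_sd = ru("noise_sd"))
}

#' Specification of a synthetic image domain
#'
#' A domain is `n_images` eyes sampled from `param_ranges`, optionally
#' displaced by a photometric/vessel `shift` relative to the reference
#' (source) rendering.  The default target shift — darker, flatter, more
#' vascularized images — emulates a change of fundus camera.
#'
#' @param n_images number of images.
#' @param param_ranges sampling intervals, see [default_param_ranges()].
#' @param shift list with `brightness` (additive intensity offset),
#'   `contrast` (relative change of contrast about the image mean) and
#'   `vessel_density` (additive vessel count); all 0 for the source domain.
#' @param seed integer seed; equal specs give bit-identical datasets.
#' @param image_size side length in pixels.
#' @return an object of class `domain_spec`.
#' @export
domain_spec <- function(n_images, param_ranges = default_param_ranges(),
                        shift = list(brightness = 0, contrast = 0,
                                     vessel_density = 0),
                        seed = 1L, image_size = 128L) {
  stopifnot(n_images >= 1)
  shift <- modifyList(list(brightness = 0, contrast = 0, vessel_density = 0),
                      shift)
  ranges <- modifyList(default_param_ranges(), param_ranges)
  for (r in ranges) {
    if (length(r) != 2 || any(!is.finite(r)) || r[2] < r[1]) {
      stop("empty or malformed parameter range", call. = FALSE)
    }
  }
  structure(list(n_images = as.integer(n_images), param_ranges = ranges,
                 shift = shift, seed = as.integer(seed),
                 image_size = as.integer(image_size)),
            class = "domain_spec")
}

#' Shift used for the default synthetic target domain
#'
#' Emulates a change of fundus camera: darker, lower-contrast images with a
#' denser vessel tree.  The magnitude is chosen so that a network trained
#' only on the source domain loses a double-digit number of Dice points on
#' the target, the degradation regime reported for unadapted segmenters
#' across real fundus datasets; a token shift would leave no domain gap for
#' adaptation to close.
#'
#' @return list of brightness/contrast/vessel-density offsets.
#' @export
target_shift <- function() {
  list(brightness = -0.25, contrast = -0.5, vessel_density = 3)
}

#' Generate a synthetic domain
#'
#' @param spec a [domain_spec()].
#' @return list of `n_images` elements, each `list(image, mask, params)`.
#' @export
generate_domain <- function(spec) {
  stopifnot(inherits(spec, "domain_spec"))
  out <- vector("list", spec$n_images)
  for (i in seq_len(spec$n_images)) {
    item_seed <- derive_seed(spec$seed, paste0("eye", i))
    p <- with_seed(item_seed, sample_eye_params(spec$param_ranges,
                                                spec$image_size))
    p$vessel_count <- max(0L, p$vessel_count +
                            as.integer(round(spec$shift$vessel_density)))
    eye <- generate_eye(p, seed = derive_seed(item_seed, "render"))
    img <- eye$image
    if (spec$shift$contrast != 0) {
      mu <- mean(img)
      img <- mu + (img - mu) * (1 + spec$shift$contrast)
    }
    img <- pmin(pmax(img + spec$shift$brightness, 0), 1)
    out[[i]] <- list(image = img, mask = eye$mask, params = p)
  }
  out
}

#' Generate a screening cohort with known glaucoma status
#'
#' Each eye's true vertical cup-to-disc ratio (CDR) is drawn from its class
#' interval: elevated CDR is the classic structural sign of glaucomatous
#' cupping, so `cdr_glaucoma` should lie above `cdr_normal`.
#'
#' @param n cohort size.
#' @param prevalence probability of the glaucoma label.
#' @param cdr_normal,cdr_glaucoma CDR sampling intervals inside `(0, 1)`.
#' @param seed integer seed.
#' @param image_size side length in pixels.
#' @return list of `list(image, mask, label, cdr_true)`; `label` is 0/1.
#' @export
glaucoma_cohort <- function(n, prevalence = 0.5, cdr_normal = c(0.3, 0.5),
                            cdr_glaucoma = c(0.65, 0.85), seed = 1L,
                            image_size = 128L) {
  stopifnot(n >= 1, prevalence >= 0, prevalence <= 1,
            all(cdr_normal > 0), all(cdr_normal < 1),
            all(cdr_glaucoma > 0), all(cdr_glaucoma < 1))
  if (min(cdr_glaucoma) <= min(cdr_normal)) {
    stop("glaucoma CDR interval must lie above the normal interval",
         call. = FALSE)
  }
  if (min(cdr_glaucoma) < max(cdr_normal)) {
    warning("CDR class intervals overlap; classes will not be separable")
  }
  labels <- with_seed(derive_seed(seed, "labels"),
                      rbinom(n, 1L, prevalence))
  ranges <- default_param_ranges()
  out <- vector("list", n)
  for (i in seq_len(n)) {
    item_seed <- derive_seed(seed, paste0("cohort", i))
    interval <- if (labels[i] == 1L) cdr_glaucoma else cdr_normal
    cdr <- with_seed(item_seed, runif(1, interval[1], interval[2]))
    p <- with_seed(derive_seed(item_seed, "params"),
                   sample_eye_params(ranges, image_size, cup_ratio = cdr))
    eye <- generate_eye(p, seed = derive_seed(item_seed, "render"))
    out[[i]] <- list(image = eye$image, mask = eye$mask,
                     label = labels[i], cdr_true = cdr)
  }
  out
}
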