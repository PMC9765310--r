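# Dataset I/O.  Images and masks travel as lossless 8-bit PNG; masks use
# the REFUGE grayscale convention (0 = cup, 128 = disc rim, 255 =
# background), which encodes the nested structures in one file: the disc
# channel is every pixel <= 128, the cup channel every pixel == 0, so the
# cup is a subset of the disc by construction.

#' Read a label PNG into a two-channel mask
#'
#' @param path 8-bit grayscale PNG with pixel values in `{0, 128, 255}`.
#' @return `H x W x 2` binary array (disc, cup).
#' @export
read_mask <- function(path) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3) raw <- raw[, , 1]
  vals <- round(raw * 255)
  bad <- setdiff(unique(as.vector(vals)), c(0, 128, 255))
  if (length(bad)) {
    stop("read_mask: unexpected pixel values in ", path, ": ",
         paste(sort(bad), collapse = ", "), call. = FALSE)
  }
  mask <- array(0, c(dim(vals), 2L))
  mask[, , 1] <- (vals <= 128) * 1
  mask[, , 2] <- (vals == 0) * 1
  mask
}

#' Write a two-channel mask as a label PNG
#'
#' Inverse of [read_mask()]: cup pixels become 0, disc-rim pixels 128 and
#' background 255.
#'
#' @param mask `H x W x 2` binary array (disc, cup).
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  disc <- binarize(mask[, , 1])
  cup <- binarize(mask[, , 2])
  vals <- matrix(255, nrow(disc), ncol(disc))
  vals[disc == 1] <- 128
  vals[cup == 1] <- 0
  png::writePNG(vals / 255, path)
  invisible(path)
}

#' Read / write an RGB fundus image PNG
#'
#' @param path PNG path.
#' @return `H x W x 3` array in `[0, 1]`.
#' @export
read_fundus <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3L))
  img[, , 1:3, drop = FALSE]
}

#' @rdname read_fundus
#' @param image `H x W x 3` array in `[0, 1]`.
#' @export
write_fundus <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Write a dataset of image/mask pairs to a directory
#'
#' Creates `images/NNN.png`, `masks/NNN.png` (omitted for unlabeled items)
#' and a `manifest.json` recording per-item metadata.
#'
#' @param data list of `list(image, mask = NULL, ...)` items.
#' @param dir output directory (created).
#' @param domain tag stored in the manifest (`source` or `target`).
#' @param extra named list merged into the manifest root.
#' @export
write_dataset <- function(data, dir, domain = "source", extra = list()) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  has_mask <- any(vapply(data, function(d) !is.null(d$mask), logical(1)))
  if (has_mask) {
    dir.create(file.path(dir, "masks"), recursive = TRUE,
               showWarnings = FALSE)
  }
  entries <- lapply(seq_along(data), function(i) {
    nm <- sprintf("%03d.png", i)
    write_fundus(data[[i]]$image, file.path(dir, "images", nm))
    e <- list(image = file.path("images", nm), domain = domain)
    if (!is.null(data[[i]]$mask)) {
      write_mask(data[[i]]$mask, file.path(dir, "masks", nm))
      e$mask <- file.path("masks", nm)
    }
    if (!is.null(data[[i]]$label)) e$label <- data[[i]]$label
    if (!is.null(data[[i]]$params)) {
      e$params <- data[[i]]$params[c("disc_center", "disc_axes", "cup_axes",
                                     "cup_offset", "vessel_count")]
    }
    e
  })
  manifest <- c(list(domain = domain, n = length(data)), extra,
                list(entries = entries))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.json`.
#' @return list of `list(image, mask (or NULL), label (or NULL))`.
#' @export
read_dataset <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  lapply(mf$entries, function(e) {
    item <- list(image = read_fundus(file.path(dir, e$image)))
    if (!is.null(e$mask)) item$mask <- read_mask(file.path(dir, e$mask))
    if (!is.null(e$label)) item$label <- e$label
    item
  })
}

# JSON run manifest written next to every pipeline output
write_run_manifest <- function(dir, command, config, seed) {
  manifest <- list(command = command, seed = seed,
                   config_hash = digest_config(config),
                   r_version = as.character(getRversion()),
                   package_version =
                     as.character(utils::packageVersion("fundusadapt")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

digest_config <- function(config) {
  s <- paste(deparse(config), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)))
}
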