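# Patch loading, resizing and pixel normalization. A raw patch is an
# H x W x 3 array of integers in 0..255 (RGB); normalization converts it to
# the real-valued tensor a given backbone was trained on.

#' Construct a raw RGB patch
#'
#' @param pixels H x W x 3 numeric array, integer values in 0..255, RGB order.
#' @param item_id unique identifier within a collection.
#' @param label class name.
#' @param source_path optional originating file path.
#' @return object of class `raw_patch`.
#' @export
raw_patch <- function(pixels, item_id, label, source_path = NA_character_) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    hc_stop("hc_format_error", "patch pixels must be H x W x 3, got %s",
            paste(dim(pixels), collapse = " x "))
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    hc_stop("hc_format_error", "patch pixel values must lie in [0, 255]")
  }
  structure(list(pixels = pixels, item_id = as.character(item_id),
                 label = as.character(label),
                 source_path = as.character(source_path)),
            class = "raw_patch")
}

#' @export
print.raw_patch <- function(x, ...) {
  cat(sprintf("<raw_patch %s [%s] %s>\n", x$item_id, x$label,
              paste(dim(x$pixels), collapse = "x")))
  invisible(x)
}

# Decode an image file to a numeric array in [0, 1]; dispatch on extension.
hc_read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  reader <- switch(ext,
    png = png::readPNG,
    tif = , tiff = tiff::readTIFF,
    jpg = , jpeg = jpeg::readJPEG,
    hc_stop("hc_format_error",
            "unsupported image extension '%s' for '%s' (PNG/TIFF/JPEG)",
            ext, path))
  tryCatch(reader(path),
           error = function(e) {
             hc_stop("hc_io_error", "failed to decode image '%s': %s",
                     path, conditionMessage(e))
           })
}

#' Load a labeled patch from disk
#'
#' Decodes PNG, TIFF, or JPEG to RGB. Grayscale images are replicated to
#' three channels; an alpha channel is dropped.
#'
#' @param path image file path.
#' @param label class name to attach.
#' @param item_id unique identifier to attach.
#' @return a [raw_patch()].
#' @export
load_patch <- function(path, label, item_id) {
  if (!file.exists(path)) {
    hc_stop("hc_io_error", "image file not found: '%s'", path)
  }
  img <- hc_read_image(path)
  if (length(dim(img)) == 2L) {
    img <- array(img, dim = c(dim(img), 1L))
  }
  if (length(dim(img)) != 3L) {
    hc_stop("hc_format_error", "unexpected image dimensionality in '%s'", path)
  }
  nc <- dim(img)[3]
  img <- if (nc == 1L) img[, , c(1L, 1L, 1L), drop = FALSE]
         else if (nc == 2L) img[, , c(1L, 1L, 1L), drop = FALSE]  # gray+alpha
         else img[, , 1:3, drop = FALSE]                           # drop alpha
  raw_patch(round(img * 255), item_id = item_id, label = label,
            source_path = path)
}

#' Resize a patch to a square side length
#'
#' Bilinear interpolation by default; the aspect ratio is not preserved (the
#' backbones expect square inputs). Resizing to the current side is a no-op.
#'
#' @param patch a [raw_patch()].
#' @param target_side output side length in pixels.
#' @param method `"bilinear"` or `"nearest"`.
#' @return resized [raw_patch()].
#' @export
resize_patch <- function(patch, target_side, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(patch, "raw_patch"), target_side >= 1)
  d <- dim(patch$pixels)
  if (d[1] == target_side && d[2] == target_side) return(patch)
  # EBImage stores images x-major: transpose in, transpose out.
  img <- EBImage::Image(aperm(patch$pixels, c(2, 1, 3)) / 255,
                        colormode = "Color")
  out <- EBImage::resize(img, w = target_side, h = target_side,
                         filter = if (method == "bilinear") "bilinear" else "none")
  px <- aperm(EBImage::imageData(out), c(2, 1, 3)) * 255
  px <- round(pmin(pmax(px, 0), 255))
  raw_patch(px, item_id = patch$item_id, label = patch$label,
            source_path = patch$source_path)
}

#' Normalize a resized patch for a backbone
#'
#' Applies the pixel normalization a pre-trained backbone expects:
#' \describe{
#'   \item{SCALE_SYMMETRIC}{`x / 127.5 - 1`, mapping 0..255 onto -1..1.}
#'   \item{SCALE_UNIT_IMAGENET}{`x / 255`, then per-channel
#'     `(x - mean) / sd` with ImageNet channel statistics.}
#'   \item{BGR_ZERO_CENTER}{reverse channels RGB to BGR, subtract per-channel
#'     ImageNet means, no scaling.}
#'   \item{IDENTITY}{cast to double, values unchanged.}
#' }
#'
#' @param patch a [raw_patch()], already resized to the backbone input size.
#' @param mode one of [preprocess_modes()].
#' @param channel_stats optional list overriding the shipped ImageNet
#'   statistics: `bgr_mean` (length 3, BGR order) for `BGR_ZERO_CENTER`;
#'   `unit_mean` and `unit_sd` (length 3, RGB order) for
#'   `SCALE_UNIT_IMAGENET`.
#' @return object of class `prepared_input` with fields `pixels` (double
#'   array) and `mode`.
#' @export
normalize_patch <- function(patch, mode, channel_stats = NULL) {
  mode <- match.arg(toupper(mode), preprocess_modes())
  stopifnot(inherits(patch, "raw_patch"))
  x <- patch$pixels * 1.0
  stats <- channel_stats %||% hc_preprocess_defaults()
  out <- switch(mode,
    SCALE_SYMMETRIC = x / 127.5 - 1,
    IDENTITY = x,
    BGR_ZERO_CENTER = {
      m <- stats$bgr_mean
      if (is.null(m) || length(m) != 3L) {
        hc_stop("hc_config_error",
                "BGR_ZERO_CENTER requires channel_stats$bgr_mean (length 3)")
      }
      y <- x[, , c(3L, 2L, 1L), drop = FALSE]
      sweep(y, 3L, m, "-")
    },
    SCALE_UNIT_IMAGENET = {
      m <- stats$unit_mean; s <- stats$unit_sd
      if (is.null(m) || is.null(s) || length(m) != 3L || length(s) != 3L) {
        hc_stop("hc_config_error",
                "SCALE_UNIT_IMAGENET requires channel_stats$unit_mean and $unit_sd (length 3)")
      }
      sweep(sweep(x / 255, 3L, m, "-"), 3L, s, "/")
    })
  structure(list(pixels = out, mode = mode,
                 item_id = patch$item_id, label = patch$label),
            class = "prepared_input")
}

#' Prepare a patch for a backbone in one step
#'
#' Resize to the backbone's input side, then apply its normalization mode.
#'
#' @param patch a [raw_patch()].
#' @param backbone backbone name.
#' @param channel_stats see [normalize_patch()].
#' @param method resize interpolation, see [resize_patch()].
#' @return a `prepared_input`.
#' @export
prepare_patch <- function(patch, backbone, channel_stats = NULL,
                          method = "bilinear") {
  spec <- backbone_spec(backbone)
  normalize_patch(resize_patch(patch, spec$input_size, method = method),
                  spec$preprocess, channel_stats = channel_stats)
}
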