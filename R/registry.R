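# Backbone/layer catalogue: which pre-trained CNNs the retrieval pipeline
# knows about, which intermediate layers are tapped for deep features, the
# spatial shape of each tapped feature map, and the per-backbone input size
# and pixel-normalization mode. The catalogue is shipped as data (JSON), not
# code, so an extraction backend can be validated against it at run time:
# a shape mismatch between a backend's output and the catalogue is a hard
# error, because silent shape drift is the main failure mode when backbone
# implementations evolve.

.hc_env <- new.env(parent = emptyenv())

hc_catalogue_path <- function() {
  system.file("extdata", "backbone_catalogue.json", package = "histocbir",
              mustWork = TRUE)
}

hc_catalogue <- function() {
  if (is.null(.hc_env$catalogue)) {
    .hc_env$catalogue <- jsonlite::read_json(hc_catalogue_path(),
                                             simplifyVector = FALSE)
  }
  .hc_env$catalogue
}

hc_layer_df <- function(layers) {
  data.frame(
    name = vapply(layers, function(l) l$name, character(1)),
    height = vapply(layers, function(l) as.integer(l$h), integer(1)),
    width = vapply(layers, function(l) as.integer(l$w), integer(1)),
    channels = vapply(layers, function(l) as.integer(l$c), integer(1)),
    pooled_size = vapply(layers, function(l) as.integer(l$pooled), integer(1)),
    flatten_size = vapply(layers, function(l) as.integer(l$flatten), integer(1)),
    stringsAsFactors = FALSE)
}

#' The three feature-map reduction operators
#'
#' `"GAP"` (global average pooling) and `"GMP"` (global max pooling) collapse
#' an H x W x C activation map to a length-C vector; `"FLATTEN"` linearizes it
#' to length H*W*C.
#'
#' @return character vector of reduction tags.
#' @export
reductions <- function() c("GAP", "GMP", "FLATTEN")

#' Pixel-normalization modes
#'
#' Each registered backbone expects one of four input normalizations:
#' `BGR_ZERO_CENTER` (RGB to BGR, subtract ImageNet channel means, no
#' scaling), `SCALE_SYMMETRIC` (rescale 0..255 to -1..1),
#' `SCALE_UNIT_IMAGENET` (rescale to 0..1, then standardize per channel with
#' ImageNet statistics), and `IDENTITY` (raw pixel values).
#'
#' @return character vector of mode tags.
#' @export
preprocess_modes <- function() {
  c("BGR_ZERO_CENTER", "SCALE_SYMMETRIC", "SCALE_UNIT_IMAGENET", "IDENTITY")
}

#' List the registered CNN backbones
#'
#' Returns the catalogue of the nine pre-trained architectures the pipeline
#' supports, in stable order: name, square input size in pixels, pixel
#' normalization mode, and the tapped extraction layers with their feature-map
#' shapes.
#'
#' @param extended if `TRUE`, Xception is listed with its extended ten-layer
#'   catalogue (entry flow, all eight middle-flow block outputs, exit flow)
#'   instead of the default three representative layers.
#' @return named list of backbone specs; each spec is a list with `name`,
#'   `input_size`, `preprocess`, and `layers` (a data frame with columns
#'   `name`, `height`, `width`, `channels`, `pooled_size`, `flatten_size`).
#' @export
#' @examples
#' names(list_backbones())
#' list_backbones()[["VGG16"]]$input_size
list_backbones <- function(extended = FALSE) {
  cat_ <- hc_catalogue()
  specs <- lapply(cat_$backbones, function(b) {
    layers <- b$layers
    if (isTRUE(extended) && !is.null(b$extended_layers)) {
      layers <- b$extended_layers
    }
    list(name = b$name,
         input_size = as.integer(b$input_size),
         preprocess = b$preprocess,
         layers = hc_layer_df(layers))
  })
  names(specs) <- vapply(specs, function(s) s$name, character(1))
  specs
}

#' Look up a single backbone spec
#'
#' @param backbone backbone name (see [list_backbones()]).
#' @inheritParams list_backbones
#' @return a backbone spec list.
#' @export
backbone_spec <- function(backbone, extended = FALSE) {
  specs <- list_backbones(extended = extended)
  if (!backbone %in% names(specs)) {
    hc_stop("hc_lookup_error",
            "unknown backbone '%s'; valid choices: %s",
            backbone, paste(names(specs), collapse = ", "))
  }
  specs[[backbone]]
}

#' Extraction layers registered for a backbone
#'
#' @inheritParams backbone_spec
#' @return data frame of layer specs (`name`, `height`, `width`, `channels`,
#'   `pooled_size`, `flatten_size`), in catalogue order.
#' @export
#' @examples
#' layer_specs("VGG16")$name
layer_specs <- function(backbone, extended = FALSE) {
  backbone_spec(backbone, extended = extended)$layers
}

#' Look up one layer of one backbone
#'
#' @inheritParams backbone_spec
#' @param layer layer name as printed in the catalogue.
#' @return one-row data frame of the layer spec.
#' @export
layer_spec <- function(backbone, layer, extended = FALSE) {
  ls <- layer_specs(backbone, extended = extended)
  i <- match(layer, ls$name)
  if (is.na(i)) {
    hc_stop("hc_lookup_error",
            "unknown layer '%s' for backbone '%s'; valid layers: %s",
            layer, backbone, paste(ls$name, collapse = ", "))
  }
  ls[i, , drop = FALSE]
}

#' Length of a reduced deep-feature vector
#'
#' Global average and global max pooling collapse the spatial grid, so the
#' reduced vector has one entry per channel; flattening keeps every activation,
#' so the length is `height * width * channels`.
#'
#' @param layer a layer spec: any list or one-row data frame with `height`,
#'   `width`, `channels`.
#' @param reduction one of [reductions()].
#' @return positive integer vector length.
#' @export
#' @examples
#' reduced_size(layer_spec("VGG16", "block5_pool"), "FLATTEN")  # 25088
reduced_size <- function(layer, reduction) {
  reduction <- match.arg(toupper(reduction), reductions())
  h <- as.integer(layer$height)
  w <- as.integer(layer$width)
  c_ <- as.integer(layer$channels)
  stopifnot(length(h) == 1, h >= 1, w >= 1, c_ >= 1)
  if (reduction == "FLATTEN") h * w * c_ else c_
}

# ImageNet channel statistics used by the normalization modes; shipped in the
# catalogue so deployments can override them without touching code.
hc_preprocess_defaults <- function() {
  d <- hc_catalogue()$preprocess_defaults
  list(bgr_mean = as.numeric(unlist(d$bgr_mean)),
       unit_mean = as.numeric(unlist(d$unit_mean)),
       unit_sd = as.numeric(unlist(d$unit_sd)))
}

#' Catalogue schema version
#'
#' @return integer version of the bundled backbone catalogue.
#' @export
catalogue_version <- function() as.integer(hc_catalogue()$schema_version)
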