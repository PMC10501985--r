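# Deep-feature extraction: forward a prepared input through a backend to a
# named layer (a 3-D activation map), then reduce the map to the 1-D vector
# that the retrieval index stores.

#' Construct a feature map
#'
#' Wraps an H x W x C activation array, validating its shape against the
#' catalogue entry for `backbone`/`layer`. A mismatch is an error: it means
#' the extraction backend is not producing what the catalogue promises.
#'
#' @param values H x W x C numeric array.
#' @param backbone backbone name.
#' @param layer layer name.
#' @param item_id,label optional provenance carried to the reduced vector.
#' @return object of class `feature_map`.
#' @export
feature_map <- function(values, backbone, layer,
                        item_id = NA_character_, label = NA_character_) {
  spec <- layer_spec(backbone, layer)
  expected <- c(spec$height, spec$width, spec$channels)
  actual <- dim(values)
  if (length(actual) != 3L || !all(actual == expected)) {
    hc_stop("hc_validation_error",
            "feature map shape mismatch for %s/%s: catalogue says %s, backend returned %s",
            backbone, layer, paste(expected, collapse = "x"),
            paste(actual, collapse = "x"))
  }
  structure(list(values = values, backbone = backbone, layer = spec,
                 item_id = as.character(item_id), label = as.character(label)),
            class = "feature_map")
}

#' Construct a feature vector
#'
#' @param values 1-D numeric vector; must be finite and of the length the
#'   catalogue prescribes for `layer`/`reduction`.
#' @param backbone,layer,reduction extraction provenance.
#' @param item_id,label identity of the source patch.
#' @return object of class `feature_vector`.
#' @export
feature_vector <- function(values, backbone, layer, reduction,
                           item_id, label) {
  if (!all(is.finite(values))) {
    hc_stop("hc_validation_error",
            "feature vector for '%s' contains non-finite values", item_id)
  }
  structure(list(values = as.double(values), backbone = backbone,
                 layer = layer, reduction = reduction,
                 item_id = as.character(item_id), label = as.character(label)),
            class = "feature_vector")
}

#' Forward a prepared input through a backend to a named layer
#'
#' The backend is an injected interface (see [new_backend()]); whatever it
#' returns is validated against the catalogue shape for the layer before it
#' is accepted.
#'
#' @param input a `prepared_input` (see [normalize_patch()]).
#' @param backbone,layer catalogue names.
#' @param backend an `hc_backend` object.
#' @return a [feature_map()].
#' @export
extract_feature_map <- function(input, backbone, layer, backend) {
  stopifnot(inherits(input, "prepared_input"), inherits(backend, "hc_backend"))
  spec <- backbone_spec(backbone)
  d <- dim(input$pixels)
  if (d[1] != spec$input_size || d[2] != spec$input_size) {
    hc_stop("hc_validation_error",
            "%s expects a %dx%d input, got %dx%d",
            backbone, spec$input_size, spec$input_size, d[1], d[2])
  }
  values <- backend$forward(backbone, layer, input$pixels)
  feature_map(values, backbone, layer,
              item_id = input$item_id %||% NA_character_,
              label = input$label %||% NA_character_)
}

#' Reduce a 3-D feature map to a 1-D deep feature
#'
#' `GAP` takes the mean of each channel over the spatial grid, `GMP` the
#' maximum; both give one value per channel. `FLATTEN` linearizes the map
#' row-major with the channel index varying fastest.
#'
#' @param fm a [feature_map()].
#' @param reduction one of [reductions()].
#' @return a [feature_vector()].
#' @export
#' @examples
#' m <- feature_map(array(rnorm(7 * 7 * 512), c(7, 7, 512)), "VGG16", "block5_pool")
#' length(reduce_feature_map(m, "GAP")$values)      # 512
#' length(reduce_feature_map(m, "FLATTEN")$values)  # 25088
reduce_feature_map <- function(fm, reduction) {
  stopifnot(inherits(fm, "feature_map"))
  reduction <- match.arg(toupper(reduction), reductions())
  v <- fm$values
  out <- switch(reduction,
    GAP = apply(v, 3L, mean),
    GMP = apply(v, 3L, max),
    FLATTEN = as.vector(aperm(v, c(3L, 2L, 1L))))
  stopifnot(length(out) == reduced_size(fm$layer, reduction))
  feature_vector(out, backbone = fm$backbone, layer = fm$layer$name,
                 reduction = reduction, item_id = fm$item_id, label = fm$label)
}

#' Extract a deep-feature vector from a raw patch
#'
#' The full per-patch pipeline: resize to the backbone input size, normalize,
#' forward to the named layer, reduce. The patch's `item_id` and `label`
#' travel with the vector.
#'
#' @param patch a [raw_patch()].
#' @param backbone,layer catalogue names.
#' @param reduction one of [reductions()].
#' @param backend an `hc_backend`.
#' @param channel_stats optional normalization override, see
#'   [normalize_patch()].
#' @return a [feature_vector()].
#' @export
extract_vector <- function(patch, backbone, layer, reduction, backend,
                           channel_stats = NULL) {
  input <- prepare_patch(patch, backbone, channel_stats = channel_stats)
  fm <- extract_feature_map(input, backbone, layer, backend)
  vec <- reduce_feature_map(fm, reduction)
  vec$item_id <- patch$item_id
  vec$label <- patch$label
  vec
}
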