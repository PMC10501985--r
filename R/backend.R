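# Extraction backends. The pipeline treats the network as an injected
# forward pass: (backbone, layer, S x S x 3 input) -> H x W x C activation
# map. Any object honouring that contract can drive extraction — a wrapper
# around a deep-learning runtime with published pre-trained weights, or the
# built-in seeded random-projection backend, which needs no weights and is
# fully deterministic, so the whole pipeline runs offline and reproducibly.

#' Create an extraction backend
#'
#' @param name short backend identifier, recorded in bank provenance.
#' @param forward function `(backbone, layer, pixels)` returning an
#'   H x W x C array matching the catalogue shape for the layer.
#' @return object of class `hc_backend`.
#' @export
new_backend <- function(name, forward) {
  stopifnot(is.character(name), is.function(forward))
  structure(list(name = name, forward = forward), class = "hc_backend")
}

#' @export
print.hc_backend <- function(x, ...) {
  cat(sprintf("<hc_backend '%s'>\n", x$name))
  invisible(x)
}

#' Seeded random-projection backend
#'
#' A deterministic, weight-free stand-in for a convolutional forward pass.
#' For a layer with catalogue shape H x W x C it block-averages the
#' normalized input down to the H x W grid, then applies a fixed random
#' linear map from the three colour channels to C channels followed by a
#' ReLU. The projection weights are drawn once per (backbone, layer) from a
#' seed derived from `seed` and the layer name, so the same seed always
#' yields the same features. The map is sensitive to colour and coarse
#' texture, which is what the synthetic patch classes differ in, so retrieval
#' behaviour on synthetic data exercises every downstream component.
#'
#' @param seed integer seed controlling all projection weights.
#' @return an `hc_backend`.
#' @export
#' @examples
#' b <- seeded_backend(1)
#' m <- b$forward("VGG16", "block5_pool",
#'                array(runif(224 * 224 * 3), c(224, 224, 3)))
#' dim(m)  # 7 7 512
seeded_backend <- function(seed = 1L) {
  seed <- as.integer(seed)
  force(seed)
  new_backend(
    name = sprintf("seeded-random(seed=%d)", seed),
    forward = function(backbone, layer, pixels) {
      spec <- layer_spec(backbone, layer)
      h <- spec$height; w <- spec$width; ch <- spec$channels
      pooled <- hc_block_mean(pixels, h, w)            # h x w x 3
      rms <- sqrt(mean(pooled^2))
      if (rms > 0) pooled <- pooled / rms
      wseed <- seed_from_string(seed, paste(backbone, layer, sep = "/"))
      proj <- with_seed(wseed, {
        list(A = matrix(stats::rnorm(ch * 3), nrow = 3, ncol = ch),
             b = stats::rnorm(ch, sd = 0.5))
      })
      z <- matrix(pooled, nrow = h * w, ncol = 3) %*% proj$A
      z <- sweep(z, 2L, proj$b, "+")
      z[z < 0] <- 0                                    # ReLU
      array(z, dim = c(h, w, ch))
    })
}

# Block-average an S1 x S2 x 3 array down to h x w x 3. When the target grid
# is coarser, each output cell averages the input rows/cols mapped into it;
# when finer (never the case for catalogue layers, but kept total), nearest
# input pixels are replicated.
hc_block_mean <- function(pixels, h, w) {
  shrink_rows <- function(m, n_out) {
    n_in <- nrow(m)
    if (n_in >= n_out) {
      g <- pmin(ceiling(seq_len(n_in) * n_out / n_in), n_out)
      rowsum(m, g) / as.vector(table(g))
    } else {
      src <- pmin(pmax(ceiling((seq_len(n_out) - 0.5) * n_in / n_out), 1L), n_in)
      m[src, , drop = FALSE]
    }
  }
  out <- array(0, dim = c(h, w, 3L))
  for (k in 1:3) {
    m <- shrink_rows(pixels[, , k], h)
    out[, , k] <- t(shrink_rows(t(m), w))
  }
  out
}
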