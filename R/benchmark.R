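# Published benchmark values bundled with the package: leave-one-out
# retrieval precision reported for the BACH breast-histology collection
# (400 H&E patches, four classes) using ImageNet-pretrained backbones with
# global-average-pooled deep features. Three tables: the chosen layer's
# P@k row per backbone, the best layer (and its P@k) at each depth, and
# gain/loss P@k comparisons for the backbones whose best layer changes
# with depth. They serve as reference inputs for the selection procedures
# and for arithmetic cross-checks of the evaluation machinery.

#' Bundled published retrieval benchmark
#'
#' @return list with `chosen_layer_precision` (data frame: backbone, layer,
#'   p5, p10, p50, p100), `best_layer_per_k` (backbone, k, layer, p),
#'   `layer_gain_loss` (backbone, reference, other, k, glp), plus `ks`,
#'   `n_queries`, and `reduction`.
#' @export
published_benchmark <- function() {
  if (is.null(.hc_env$benchmark)) {
    path <- system.file("extdata", "bach_benchmark.json",
                        package = "histocbir", mustWork = TRUE)
    .hc_env$benchmark <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  .hc_env$benchmark
}

#' Reconstruct per-layer P@k cells for a conflicted backbone
#'
#' For backbones whose published best layer differs across depths, the
#' benchmark prints the chosen layer's full P@k row and its gain/loss
#' against every other candidate; the candidates' own rows follow by
#' arithmetic (`other = reference - glp`). This returns those cells as a
#' metric table suitable for [select_best_layer()].
#'
#' @param backbone backbone name present in the benchmark's gain/loss table.
#' @return metric table (backbone, layer, reduction, k, p).
#' @export
benchmark_layer_cells <- function(backbone) {
  bm <- published_benchmark()
  gl <- bm$layer_gain_loss[bm$layer_gain_loss$backbone == backbone, ]
  if (nrow(gl) == 0L) {
    hc_stop("hc_lookup_error",
            "no per-layer gain/loss rows for backbone '%s'; available: %s",
            backbone, paste(unique(bm$layer_gain_loss$backbone), collapse = ", "))
  }
  chosen <- bm$chosen_layer_precision
  ref_row <- chosen[chosen$backbone == backbone, ]
  ks <- bm$ks
  ref <- data.frame(backbone = backbone, layer = ref_row$layer,
                    reduction = bm$reduction, k = ks,
                    p = as.numeric(ref_row[paste0("p", ks)]),
                    stringsAsFactors = FALSE)
  others <- do.call(rbind, lapply(unique(gl$other), function(lay) {
    sub <- gl[gl$other == lay, ]
    data.frame(backbone = backbone, layer = lay, reduction = bm$reduction,
               k = sub$k, p = ref$p[match(sub$k, ref$k)] - sub$glp,
               stringsAsFactors = FALSE)
  }))
  rbind(ref, others)
}
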