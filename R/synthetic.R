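# Synthetic fixtures with analytically known retrieval behaviour. Two
# generators: (i) class-structured feature banks — orthonormal class
# centroids plus isotropic Gaussian noise, so the chance level at zero
# separation and the perfect-retrieval limit at high separation are exact —
# and (ii) labeled RGB patch collections whose classes differ in mean
# colour and texture frequency, emulating a balanced four-class histology
# patch dataset at the 4 x 100 scale without any claim to histological
# realism.

#' Generate a class-structured synthetic feature bank
#'
#' Class c has a unit-norm centroid; centroids are pairwise orthogonal
#' (standard basis vectors), which requires `n_classes <= dim`. Item
#' vectors are `separation * centroid + noise` with isotropic Gaussian
#' noise, so `separation` measures class separation in units of the noise
#' scale: at `separation = 0` items are exchangeable across classes and
#' leave-one-out P@k has expectation `(per_class - 1) / (N - 1)`; at
#' `separation >> noise_sd` retrieval is perfect for `k <= per_class - 1`.
#' The same seed always reproduces the same bank.
#'
#' @param n_classes number of classes (>= 2). With the default 4, classes
#'   are named after the breast-histology categories invasive, insitu,
#'   benign, normal; otherwise `class1`, `class2`, ...
#' @param per_class items per class (>= 2); default 100 gives the canonical
#'   400-item balanced collection.
#' @param dim feature dimension (>= `n_classes`).
#' @param separation centroid scale relative to the noise, >= 0.
#' @param noise_sd Gaussian noise standard deviation, > 0.
#' @param seed integer seed governing all randomness.
#' @return a [feature_bank()] with provenance backbone `"synthetic"`.
#' @export
#' @examples
#' b <- generate_feature_bank(per_class = 10, dim = 16, separation = 8, seed = 1)
#' evaluate_leave_one_out(b, ks = 5)$map  # 1: classes fully separated
generate_feature_bank <- function(n_classes = 4L, per_class = 100L,
                                  dim = 64L, separation = 4,
                                  noise_sd = 1, seed = 1L) {
  n_classes <- as.integer(n_classes); per_class <- as.integer(per_class)
  dim <- as.integer(dim)
  stopifnot(n_classes >= 2L, per_class >= 2L, separation >= 0, noise_sd > 0)
  if (n_classes > dim) {
    hc_stop("hc_config_error",
            "orthogonal centroids need dim >= n_classes (%d < %d)",
            dim, n_classes)
  }
  classes <- hc_class_names(n_classes)
  n <- n_classes * per_class
  with_seed(seed, {
    m <- matrix(stats::rnorm(n * dim, sd = noise_sd), nrow = n, ncol = dim)
    labels <- rep(classes, each = per_class)
    for (ci in seq_len(n_classes)) {
      rows <- which(labels == classes[ci])
      m[rows, ci] <- m[rows, ci] + separation
    }
    ids <- sprintf("%s-%03d", labels, sequence(rep(per_class, n_classes)))
    feature_bank(m, labels = labels, ids = ids,
                 provenance = list(backbone = "synthetic", layer = "synthetic",
                                   reduction = "GAP",
                                   generator = list(n_classes = n_classes,
                                                    per_class = per_class,
                                                    dim = dim,
                                                    separation = separation,
                                                    noise_sd = noise_sd,
                                                    seed = as.integer(seed))))
  })
}

hc_class_names <- function(n_classes) {
  if (n_classes == 4L) c("invasive", "insitu", "benign", "normal")
  else sprintf("class%d", seq_len(n_classes))
}

#' Generate a labeled synthetic patch dataset on disk
#'
#' Writes `n_classes * per_class` square RGB PNG patches into one
#' subdirectory per class, plus a `manifest.csv` (path, label, item_id).
#' Each class carries a distinctive chromatic signature (a class-specific
#' mean colour) and a periodic texture (a class-specific stripe frequency),
#' both with amplitude proportional to `separation`, on top of pixel-wise
#' Gaussian noise. At `separation = 0` all classes are statistically
#' identical noise. The same seed yields a byte-identical manifest and
#' identical images.
#'
#' @param dir output directory (created if needed).
#' @param n_classes,per_class class structure; defaults give the canonical
#'   4 x 100 balanced collection.
#' @param patch_size square patch side in pixels.
#' @param separation signature amplitude relative to noise, >= 0.
#' @param noise_sd pixel noise standard deviation (0..255 scale).
#' @param seed integer seed.
#' @return the manifest data frame, invisibly.
#' @export
generate_patch_dataset <- function(dir, n_classes = 4L, per_class = 100L,
                                   patch_size = 64L, separation = 1,
                                   noise_sd = 8, seed = 1L) {
  n_classes <- as.integer(n_classes); per_class <- as.integer(per_class)
  s <- as.integer(patch_size)
  stopifnot(n_classes >= 2L, per_class >= 1L, s >= 8L, separation >= 0,
            noise_sd > 0)
  classes <- hc_class_names(n_classes)
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2L) != 0L) {
    hc_stop("hc_io_error", "cannot write to directory '%s'", dir)
  }
  # class signatures: hue angle and stripe frequency, fixed by class index
  theta <- 2 * pi * (seq_len(n_classes) - 1) / n_classes
  freq <- 2 + seq_len(n_classes)
  xg <- matrix(seq_len(s), s, s, byrow = TRUE)
  yg <- matrix(seq_len(s), s, s)
  rows <- vector("list", n_classes * per_class)
  with_seed(seed, {
    idx <- 0L
    for (ci in seq_len(n_classes)) {
      cdir <- file.path(dir, classes[ci])
      if (!dir.exists(cdir)) dir.create(cdir)
      chroma <- 40 * min(separation, 2) *
        c(cos(theta[ci]), cos(theta[ci] + 2 * pi / 3),
          cos(theta[ci] + 4 * pi / 3))
      stripes <- 25 * min(separation, 2) *
        sin(2 * pi * freq[ci] * (xg + yg) / s)
      for (j in seq_len(per_class)) {
        idx <- idx + 1L
        px <- array(0, dim = c(s, s, 3L))
        for (ch in 1:3) {
          px[, , ch] <- 140 + chroma[ch] + stripes +
            matrix(stats::rnorm(s * s, sd = noise_sd), s, s)
        }
        px <- round(pmin(pmax(px, 0), 255))
        item_id <- sprintf("%s-%03d", classes[ci], j)
        rel <- file.path(classes[ci], paste0(item_id, ".png"))
        png::writePNG(px / 255, file.path(dir, rel))
        rows[[idx]] <- data.frame(path = rel, label = classes[ci],
                                  item_id = item_id, stringsAsFactors = FALSE)
      }
    }
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read a patch-collection manifest
#'
#' Accepts either a directory containing `manifest.csv` (as written by
#' [generate_patch_dataset()]), a CSV manifest path with columns
#' `path`, `label`, `item_id`, or a directory laid out as one subdirectory
#' per class label (ids are then derived from file names).
#'
#' @param path dataset directory or manifest CSV.
#' @return data frame `path` (absolute), `label`, `item_id`.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) {
    mf <- file.path(path, "manifest.csv")
    if (file.exists(mf)) {
      df <- utils::read.csv(mf, stringsAsFactors = FALSE)
      df$path <- file.path(path, df$path)
    } else {
      subs <- list.dirs(path, recursive = FALSE)
      if (length(subs) == 0L) {
        hc_stop("hc_io_error", "no class subdirectories in '%s'", path)
      }
      rows <- lapply(subs, function(d) {
        files <- list.files(d, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                            ignore.case = TRUE, full.names = TRUE)
        if (length(files) == 0L) return(NULL)
        data.frame(path = files, label = basename(d),
                   item_id = tools::file_path_sans_ext(basename(files)),
                   stringsAsFactors = FALSE)
      })
      df <- do.call(rbind, rows)
    }
  } else if (file.exists(path)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    hc_stop("hc_io_error", "dataset path '%s' does not exist", path)
  }
  need <- c("path", "label", "item_id")
  if (!all(need %in% names(df))) {
    hc_stop("hc_format_error", "manifest must have columns path, label, item_id")
  }
  if (anyDuplicated(df$item_id)) {
    hc_stop("hc_consistency_error", "duplicate item ids in manifest")
  }
  df
}
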