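# The offline feature store: an N x D matrix of deep features with labels,
# ids and extraction provenance, persisted as a single HDF5 file. Features
# are stored in 32-bit floating point (storage economy for flatten-sized
# banks); similarity is always computed in 64-bit. To keep the persistence
# round trip an exact identity, the in-memory matrix is rounded through
# float32 at construction time.

HC_BANK_SCHEMA <- 1L

#' Construct a feature bank
#'
#' Low-level constructor; most users go through [build_bank()].
#'
#' @param matrix N x D numeric matrix, one feature vector per row.
#' @param labels length-N character vector of class names.
#' @param ids length-N character vector of unique item ids.
#' @param provenance list with `backbone`, `layer`, `reduction`, and
#'   optionally `preprocess` and `backend`.
#' @return object of class `feature_bank`.
#' @export
feature_bank <- function(matrix, labels, ids, provenance) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != length(labels) || nrow(matrix) != length(ids)) {
    hc_stop("hc_consistency_error",
            "bank rows (%d), labels (%d) and ids (%d) must agree",
            nrow(matrix), length(labels), length(ids))
  }
  if (anyDuplicated(ids)) {
    hc_stop("hc_consistency_error", "bank item ids must be unique (dup: %s)",
            ids[duplicated(ids)][1])
  }
  needed <- c("backbone", "layer", "reduction")
  if (!all(needed %in% names(provenance))) {
    hc_stop("hc_format_error",
            "bank provenance must contain backbone, layer and reduction")
  }
  structure(list(matrix = round_to_float32(matrix),
                 labels = as.character(labels), ids = as.character(ids),
                 provenance = provenance),
            class = "feature_bank")
}

#' @export
print.feature_bank <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<feature_bank %d x %d | %s/%s/%s | %d classes>\n",
              nrow(x$matrix), ncol(x$matrix), p$backbone, p$layer,
              p$reduction, length(unique(x$labels))))
  invisible(x)
}

#' @export
dim.feature_bank <- function(x) dim(x$matrix)

#' Assemble a bank from extracted feature vectors
#'
#' All vectors must share the same provenance (backbone, layer, reduction)
#' and length; row order follows input order.
#'
#' @param vectors list of [feature_vector()] objects.
#' @return a [feature_bank()].
#' @export
build_bank <- function(vectors) {
  if (length(vectors) == 0L) {
    hc_stop("hc_consistency_error", "cannot build a bank from zero vectors")
  }
  stopifnot(all(vapply(vectors, inherits, logical(1), "feature_vector")))
  prov <- lapply(vectors, function(v) c(v$backbone, v$layer, v$reduction))
  if (length(unique(prov)) != 1L) {
    hc_stop("hc_consistency_error",
            "all vectors must share backbone/layer/reduction; found %d distinct provenances",
            length(unique(prov)))
  }
  lens <- vapply(vectors, function(v) length(v$values), integer(1))
  if (length(unique(lens)) != 1L) {
    hc_stop("hc_consistency_error",
            "all vectors must have equal length; found lengths %s",
            paste(unique(lens), collapse = ", "))
  }
  v1 <- vectors[[1]]
  feature_bank(do.call(rbind, lapply(vectors, function(v) v$values)),
               labels = vapply(vectors, function(v) v$label, character(1)),
               ids = vapply(vectors, function(v) v$item_id, character(1)),
               provenance = list(backbone = v1$backbone, layer = v1$layer,
                                 reduction = v1$reduction))
}

#' Persist a bank to an HDF5 file
#'
#' Layout: dataset `/features` (float32, N x D) plus root attributes
#' `metadata` (JSON: labels, ids, provenance) and `schema_version`.
#' [load_bank()] of the written file reproduces the bank exactly.
#'
#' @param bank a [feature_bank()].
#' @param path output file path (overwritten if present).
#' @return `path`, invisibly.
#' @export
save_bank <- function(bank, path) {
  stopifnot(inherits(bank, "feature_bank"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  d <- dim(bank$matrix)
  rhdf5::h5createDataset(path, "features", dims = d,
                         H5type = "H5T_IEEE_F32LE",
                         chunk = c(min(d[1], 64L), min(d[2], 4096L)))
  rhdf5::h5write(bank$matrix, path, "features")
  meta <- jsonlite::toJSON(list(labels = bank$labels, ids = bank$ids,
                                provenance = bank$provenance),
                           auto_unbox = TRUE, digits = NA)
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(as.character(meta), fid, "metadata")
  rhdf5::h5writeAttribute(HC_BANK_SCHEMA, fid, "schema_version")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Load a bank written by [save_bank()]
#'
#' @param path HDF5 file path.
#' @return a [feature_bank()].
#' @export
load_bank <- function(path) {
  if (!file.exists(path)) {
    hc_stop("hc_io_error", "bank file not found: '%s'", path)
  }
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  att <- rhdf5::h5readAttributes(path, "/")
  if (is.null(att$metadata)) {
    hc_stop("hc_format_error", "'%s' has no metadata block; not a bank file",
            path)
  }
  ver <- as.integer(att$schema_version)
  if (length(ver) != 1L || is.na(ver) || ver != HC_BANK_SCHEMA) {
    hc_stop("hc_format_error",
            "bank schema version mismatch in '%s': file %s, supported %d",
            path, paste(att$schema_version, collapse = ","), HC_BANK_SCHEMA)
  }
  meta <- jsonlite::fromJSON(att$metadata, simplifyVector = TRUE)
  m <- rhdf5::h5read(path, "features")
  feature_bank(m, labels = meta$labels, ids = meta$ids,
               provenance = as.list(meta$provenance))
}

#' Export a bank's (id, label) table as CSV
#'
#' @param bank a [feature_bank()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_bank_ids <- function(bank, path) {
  stopifnot(inherits(bank, "feature_bank"))
  utils::write.csv(data.frame(item_id = bank$ids, label = bank$labels,
                              stringsAsFactors = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
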