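# Online retrieval: score a query vector against every stored vector with
# cosine similarity and return the candidates in decreasing similarity.
# Ties are broken by ascending item id so that rankings — and therefore
# P@k on datasets with duplicated patches — are reproducible.

#' Cosine similarity between two vectors
#'
#' `<u, v> / (||u|| ||v||)`, computed in double precision. A zero-norm input
#' is an error rather than similarity 0: in this pipeline a zero feature
#' vector signals a dead layer or a backend bug, and silently scoring it
#' would corrupt rankings.
#'
#' @param u,v numeric vectors of equal length.
#' @return similarity in `[-1, 1]` (up to rounding).
#' @export
#' @examples
#' cosine_similarity(c(1, 0), c(0, 1))  # 0
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) {
    hc_stop("hc_dimension_error",
            "vector lengths differ: %d vs %d", length(u), length(v))
  }
  nu <- sqrt(sum(as.double(u)^2)); nv <- sqrt(sum(as.double(v)^2))
  if (nu == 0 || nv == 0) {
    hc_stop("hc_degenerate_error",
            "cosine similarity undefined for a zero-norm vector")
  }
  sum(as.double(u) * as.double(v)) / (nu * nv)
}

#' Rank a bank against a query vector
#'
#' Every non-excluded bank item is scored with cosine similarity against the
#' query and returned in decreasing similarity, ties broken by ascending
#' item id. The query's own id is not excluded automatically; pass it in
#' `exclude_ids` for leave-one-out protocols.
#'
#' @param query a [feature_vector()] whose provenance matches the bank's.
#' @param bank a [feature_bank()].
#' @param exclude_ids character vector of item ids to drop from the
#'   candidate set.
#' @return object of class `ranked_retrieval`: `query_id`, `query_label`,
#'   `entries` (data frame `item_id`, `label`, `similarity`), `excluded_ids`.
#' @export
rank_bank <- function(query, bank, exclude_ids = character(0)) {
  stopifnot(inherits(query, "feature_vector"), inherits(bank, "feature_bank"))
  p <- bank$provenance
  if (!identical(c(query$backbone, query$layer, query$reduction),
                 c(p$backbone, p$layer, p$reduction))) {
    hc_stop("hc_consistency_error",
            "query provenance %s/%s/%s does not match bank %s/%s/%s",
            query$backbone, query$layer, query$reduction,
            p$backbone, p$layer, p$reduction)
  }
  if (length(query$values) != ncol(bank$matrix)) {
    hc_stop("hc_dimension_error", "query length %d != bank dimension %d",
            length(query$values), ncol(bank$matrix))
  }
  keep <- !(bank$ids %in% exclude_ids)
  if (!any(keep)) {
    hc_stop("hc_insufficient_error",
            "no candidates remain after exclusion")
  }
  m <- bank$matrix[keep, , drop = FALSE]
  norms <- sqrt(rowSums(m^2))
  if (any(norms == 0)) {
    hc_stop("hc_degenerate_error",
            "bank contains a zero-norm vector (id %s)",
            bank$ids[keep][norms == 0][1])
  }
  qn <- sqrt(sum(query$values^2))
  if (qn == 0) {
    hc_stop("hc_degenerate_error", "query vector has zero norm")
  }
  # colSums accumulates each candidate independently in a fixed order, so
  # duplicated vectors score bit-identical similarities and tie-breaking by
  # id is exact (BLAS gemv can round identical rows differently).
  sims <- colSums(t(m) * query$values) / (norms * qn)
  ids <- bank$ids[keep]
  ord <- order(-sims, ids)
  structure(list(query_id = query$item_id, query_label = query$label,
                 entries = data.frame(item_id = ids[ord],
                                      label = bank$labels[keep][ord],
                                      similarity = sims[ord],
                                      stringsAsFactors = FALSE),
                 excluded_ids = exclude_ids),
            class = "ranked_retrieval")
}

#' @export
print.ranked_retrieval <- function(x, ...) {
  cat(sprintf("<ranked_retrieval query=%s [%s], %d candidates>\n",
              x$query_id, x$query_label, nrow(x$entries)))
  print(utils::head(x$entries, 5L))
  invisible(x)
}

#' First k entries of a ranking
#'
#' Requesting more entries than the candidate list holds is an explicit
#' error, because precision-at-k divides by k and a silently shorter list
#' would bias it.
#'
#' @param r a `ranked_retrieval`.
#' @param k number of top entries.
#' @return data frame of the first `k` entries.
#' @export
top_k <- function(r, k) {
  stopifnot(inherits(r, "ranked_retrieval"))
  k <- as.integer(k)
  if (k < 1L || k > nrow(r$entries)) {
    hc_stop("hc_insufficient_error",
            "k = %d but only %d ranked candidates are available",
            k, nrow(r$entries))
  }
  r$entries[seq_len(k), , drop = FALSE]
}
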