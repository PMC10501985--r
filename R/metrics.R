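# Retrieval evaluation. The headline metric is precision at k: the fraction
# of the k top-ranked candidates sharing the query's class. MAP@k here is
# the plain mean of P@k over queries — NOT interpolated mean average
# precision from the IR literature; the term follows common usage in
# retrieval benchmarking of histology patches, where each query has a
# single relevance class. GLP@k quantifies the gain (positive) or loss
# (negative) in P@k of a reference configuration — canonically global
# average pooling — over an alternative.

#' Construct a per-query retrieval outcome
#'
#' @param query_id,query_label identity and class of the query.
#' @param retrieved_labels class names of the ranked candidates, best first;
#'   must be at least as long as the largest k to be evaluated.
#' @return object of class `query_outcome`.
#' @export
query_outcome <- function(query_id, query_label, retrieved_labels) {
  structure(list(query_id = as.character(query_id),
                 query_label = as.character(query_label),
                 retrieved_labels = as.character(retrieved_labels)),
            class = "query_outcome")
}

#' Precision at k for one query
#'
#' The number of the top-k retrieved items whose class equals the query's,
#' divided by k.
#'
#' @param outcome a [query_outcome()].
#' @param k evaluation depth; must not exceed the retrieved list.
#' @return precision in `[0, 1]`.
#' @export
#' @examples
#' o <- query_outcome("q", "benign", c("benign", "normal", "benign",
#'                                     "invasive", "benign"))
#' precision_at_k(o, 5)  # 0.6
precision_at_k <- function(outcome, k) {
  stopifnot(inherits(outcome, "query_outcome"))
  k <- as.integer(k)
  if (k < 1L || k > length(outcome$retrieved_labels)) {
    hc_stop("hc_insufficient_error",
            "k = %d exceeds the %d retrieved labels",
            k, length(outcome$retrieved_labels))
  }
  sum(outcome$retrieved_labels[seq_len(k)] == outcome$query_label) / k
}

#' Gain/loss precision difference
#'
#' The difference `reference - other` between two mean P@k cells. With the
#' reference being global average pooling, a positive value means average
#' pooling gains precision over the alternative; a negative value is a loss.
#'
#' @param reference,other mean P@k values in `[0, 1]`.
#' @return the difference.
#' @export
glp <- function(reference, other) {
  if (any(reference < 0 | reference > 1) || any(other < 0 | other > 1)) {
    hc_stop("hc_validation_error", "P@k cells must lie in [0, 1]")
  }
  reference - other
}

#' Mean P@k over a set of outcomes
#'
#' @param outcomes list of [query_outcome()] objects.
#' @param k evaluation depth.
#' @return mean precision at `k`.
#' @export
map_at_k <- function(outcomes, k) {
  mean(vapply(outcomes, precision_at_k, numeric(1), k = k))
}

#' Per-class confusion matrix at depth k
#'
#' Rows index the query class, columns the retrieved class. Entry (i, j) is
#' the mean, over queries of class i, of the fraction of their top-k
#' retrieved items belonging to class j — so each row sums to 1 and the
#' diagonal entry is mean P@k restricted to that query class.
#'
#' @param outcomes list of [query_outcome()] objects.
#' @param k evaluation depth.
#' @param classes optional ordered class names; defaults to the sorted
#'   classes present among the queries.
#' @return C x C numeric matrix with dimnames.
#' @export
confusion_at_k <- function(outcomes, k, classes = NULL) {
  qlabs <- vapply(outcomes, function(o) o$query_label, character(1))
  classes <- classes %||% sort(unique(qlabs))
  frac <- t(vapply(outcomes, function(o) {
    top <- o$retrieved_labels[seq_len(k)]
    vapply(classes, function(cl) sum(top == cl) / k, numeric(1))
  }, numeric(length(classes))))
  m <- do.call(rbind, lapply(classes, function(cl) {
    colMeans(frac[qlabs == cl, , drop = FALSE])
  }))
  dimnames(m) <- list(query = classes, retrieved = classes)
  m
}

#' Leave-one-out retrieval evaluation of a bank
#'
#' Every bank item is used once as a query by example against all remaining
#' items (the query itself is left out of the result set), yielding N
#' queries for a bank of N items. For each query the top `max(ks)`
#' candidates are recorded and P@k computed at every requested depth;
#' MAP@k is the mean over queries and a per-class confusion matrix is
#' built at each depth.
#'
#' @param bank a [feature_bank()] with at least `max(ks) + 1` items.
#' @param ks evaluation depths; default `c(5, 10, 50, 100)`.
#' @return list with `map` (named vector, one mean P@k per depth),
#'   `confusion` (named list of matrices), `outcomes` (list of
#'   [query_outcome()]), `per_query` (data frame of per-query P@k), and
#'   `ks`.
#' @export
evaluate_leave_one_out <- function(bank, ks = c(5L, 10L, 50L, 100L)) {
  stopifnot(inherits(bank, "feature_bank"))
  ks <- sort(unique(as.integer(ks)))
  n <- nrow(bank$matrix)
  kmax <- max(ks)
  if (n <= kmax) {
    hc_stop("hc_insufficient_error",
            "bank of %d items cannot be evaluated at k = %d (need at least k + 1)",
            n, kmax)
  }
  m <- bank$matrix
  norms <- sqrt(rowSums(m^2))
  if (any(norms == 0)) {
    hc_stop("hc_degenerate_error",
            "bank contains a zero-norm vector (id %s)", bank$ids[norms == 0][1])
  }
  # per-query colSums keeps duplicated vectors bit-identical in similarity,
  # matching rank_bank's tie semantics (see retrieval.R)
  mn <- m / norms
  tmn <- t(mn)
  outcomes <- vector("list", n)
  for (i in seq_len(n)) {
    sims_i <- colSums(tmn * mn[i, ])
    cand <- setdiff(seq_len(n), i)
    ord <- cand[order(-sims_i[cand], bank$ids[cand])]
    outcomes[[i]] <- query_outcome(bank$ids[i], bank$labels[i],
                                   bank$labels[ord[seq_len(kmax)]])
  }
  per_query <- data.frame(query_id = bank$ids, query_label = bank$labels,
                          stringsAsFactors = FALSE)
  for (k in ks) {
    per_query[[paste0("p", k)]] <-
      vapply(outcomes, precision_at_k, numeric(1), k = k)
  }
  map <- vapply(ks, function(k) mean(per_query[[paste0("p", k)]]), numeric(1))
  names(map) <- paste0("p", ks)
  confusion <- lapply(ks, function(k) confusion_at_k(outcomes, k))
  names(confusion) <- paste0("k", ks)
  list(map = map, confusion = confusion, outcomes = outcomes,
       per_query = per_query, ks = ks)
}
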