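# Configuration-selection procedures over a metric table: which reduction
# to use (grand-mean P@k, audited with per-backbone gain/loss averages),
# which layer per backbone (unanimous argmax, else minimal total deficit
# across depths), and how the backbones rank against each other.
#
# A metric table is a long-format data frame with columns
# backbone, layer, reduction, k, p — one mean-P@k cell per configuration
# and depth.

hc_check_metric_table <- function(tbl, cols = c("backbone", "layer",
                                                "reduction", "k", "p")) {
  missing <- setdiff(cols, names(tbl))
  if (length(missing)) {
    hc_stop("hc_format_error", "metric table lacks columns: %s",
            paste(missing, collapse = ", "))
  }
  if (any(tbl$p < 0 | tbl$p > 1)) {
    hc_stop("hc_validation_error", "metric table cells must lie in [0, 1]")
  }
  invisible(tbl)
}

#' Average gain/loss of global average pooling per backbone
#'
#' For each backbone, alternative reduction m (GMP, FLATTEN) and depth k,
#' computes the mean over that backbone's layers of
#' `P_GAP@k - P_m@k` — the average gain (positive) or loss (negative) in
#' precision from preferring average pooling on that backbone.
#'
#' @param tbl metric table covering all three reductions for every
#'   (backbone, layer) pair it mentions.
#' @return data frame `backbone`, `reduction`, `k`, `glp`.
#' @export
reduction_gain_table <- function(tbl) {
  hc_check_metric_table(tbl)
  out <- list()
  for (bb in unique(tbl$backbone)) {
    sub <- tbl[tbl$backbone == bb, ]
    for (m in c("GMP", "FLATTEN")) {
      for (k in sort(unique(sub$k))) {
        ref <- sub[sub$reduction == "GAP" & sub$k == k, ]
        oth <- sub[sub$reduction == m & sub$k == k, ]
        if (nrow(ref) == 0 || nrow(oth) == 0 ||
            !setequal(ref$layer, oth$layer)) {
          hc_stop("hc_completeness_error",
                  "metric table missing GAP or %s cells for %s at k = %d",
                  m, bb, k)
        }
        oth_p <- oth$p[match(ref$layer, oth$layer)]
        out[[length(out) + 1L]] <-
          data.frame(backbone = bb, reduction = m, k = k,
                     glp = mean(glp(ref$p, oth_p)),
                     stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Select the best reduction operator
#'
#' Returns the reduction maximizing the grand mean of P@k over every layer,
#' backbone and depth in the table; ties resolve in the fixed preference
#' order GAP, GMP, FLATTEN. The per-backbone gain/loss table is attached so
#' the decision can be audited.
#'
#' @param tbl metric table with all three reductions.
#' @return list with `reduction`, `grand_means` (named vector), `tie`
#'   (logical), and `gain_table` (from [reduction_gain_table()]).
#' @export
select_best_reduction <- function(tbl) {
  hc_check_metric_table(tbl)
  prefs <- reductions()    # GAP, GMP, FLATTEN: also the tie-break order
  missing <- setdiff(prefs, unique(tbl$reduction))
  if (length(missing)) {
    hc_stop("hc_completeness_error", "metric table lacks reductions: %s",
            paste(missing, collapse = ", "))
  }
  gm <- vapply(prefs, function(r) mean(tbl$p[tbl$reduction == r]), numeric(1))
  best <- max(gm)
  winners <- prefs[gm >= best - 1e-12]
  list(reduction = winners[1], grand_means = gm,
       tie = length(winners) > 1L, gain_table = reduction_gain_table(tbl))
}

#' Select the best layer of one backbone
#'
#' If a single layer achieves the best mean P@k at every depth, that layer
#' is chosen (unanimous argmax). Otherwise the candidates are the per-depth
#' winners, and the chosen layer minimizes the total deficit
#' `sum_k (max_layer P@k - P_candidate@k)` — the aggregate precision it
#' gives up across depths. Remaining ties prefer the smaller reduced
#' feature size (when the layer is in the catalogue), then the earlier
#' name. A pairwise gain/loss report of the selected layer against every
#' other candidate is attached for audit.
#'
#' @param tbl metric table restricted to one backbone (a single `reduction`).
#' @return list with `layer`, `unanimous`, `per_k_best` (data frame),
#'   `deficits` (named vector over candidates), and `report` (pairwise
#'   gain/loss data frame, `NULL` when unanimous).
#' @export
select_best_layer <- function(tbl) {
  hc_check_metric_table(tbl)
  if (length(unique(tbl$backbone)) != 1L) {
    hc_stop("hc_consistency_error",
            "layer selection expects a single backbone, got: %s",
            paste(unique(tbl$backbone), collapse = ", "))
  }
  if (length(unique(tbl$reduction)) != 1L) {
    hc_stop("hc_consistency_error",
            "layer selection expects a single reduction, got: %s",
            paste(unique(tbl$reduction), collapse = ", "))
  }
  bb <- tbl$backbone[1]
  ks <- sort(unique(tbl$k))
  per_k_best <- do.call(rbind, lapply(ks, function(k) {
    sub <- tbl[tbl$k == k, ]
    top <- sub[sub$p >= max(sub$p) - 1e-12, ]
    data.frame(k = k, layer = top$layer[order(top$layer)][1], p = max(sub$p),
               stringsAsFactors = FALSE)
  }))
  candidates <- unique(per_k_best$layer)
  if (length(candidates) == 1L) {
    return(list(layer = candidates, unanimous = TRUE, per_k_best = per_k_best,
                deficits = stats::setNames(0, candidates), report = NULL))
  }
  deficits <- vapply(candidates, function(lay) {
    sum(vapply(ks, function(k) {
      cell <- tbl$p[tbl$layer == lay & tbl$k == k]
      if (length(cell) != 1L) {
        hc_stop("hc_completeness_error",
                "missing P@%d cell for candidate layer '%s'", k, lay)
      }
      per_k_best$p[per_k_best$k == k] - cell
    }, numeric(1)))
  }, numeric(1))
  best <- min(deficits)
  tied <- candidates[deficits <= best + 1e-12]
  if (length(tied) > 1L) {
    sizes <- vapply(tied, function(lay) {
      sz <- tryCatch(reduced_size(layer_spec(bb, lay), tbl$reduction[1]),
                     error = function(e) NA_integer_)
      as.numeric(sz)
    }, numeric(1))
    if (!anyNA(sizes)) tied <- tied[order(sizes, tied)] else tied <- sort(tied)
  }
  chosen <- tied[1]
  report <- do.call(rbind, lapply(setdiff(candidates, chosen), function(oth) {
    data.frame(backbone = bb, reference = chosen, other = oth, k = ks,
               glp = vapply(ks, function(k) {
                 glp(tbl$p[tbl$layer == chosen & tbl$k == k],
                     tbl$p[tbl$layer == oth & tbl$k == k])
               }, numeric(1)),
               stringsAsFactors = FALSE)
  }))
  list(layer = chosen, unanimous = FALSE, per_k_best = per_k_best,
       deficits = deficits, report = report)
}

#' Rank backbones by retrieval precision
#'
#' Expects one row per backbone and depth — each backbone at its chosen
#' layer and a fixed reduction — and returns the backbones ordered by mean
#' P@5 descending, ties broken by P@10 and then by name.
#'
#' @param tbl metric table with one (layer, reduction) per backbone.
#' @param confusion optional named list of per-backbone confusion matrices
#'   to attach.
#' @return list with `ranking` (wide data frame, best backbone first) and
#'   `confusion`.
#' @export
compare_backbones <- function(tbl, confusion = NULL) {
  hc_check_metric_table(tbl)
  ks <- sort(unique(tbl$k))
  per_bb <- unique(tbl[, c("backbone", "layer")])
  if (anyDuplicated(per_bb$backbone)) {
    hc_stop("hc_consistency_error",
            "expected a single chosen layer per backbone")
  }
  wide <- per_bb
  for (k in ks) {
    wide[[paste0("p", k)]] <- vapply(seq_len(nrow(per_bb)), function(i) {
      cell <- tbl$p[tbl$backbone == per_bb$backbone[i] & tbl$k == k]
      if (length(cell) != 1L) {
        hc_stop("hc_completeness_error", "missing P@%d cell for backbone %s",
                k, per_bb$backbone[i])
      }
      cell
    }, numeric(1))
  }
  key2 <- if ("p10" %in% names(wide)) wide$p10 else wide[[paste0("p", ks[1])]]
  ord <- order(-wide[[paste0("p", ks[1])]], -key2, wide$backbone)
  ranking <- wide[ord, , drop = FALSE]
  rownames(ranking) <- NULL
  list(ranking = ranking, confusion = confusion)
}
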