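mk_tbl <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(backbone = r[[1]], layer = r[[2]], reduction = r[[3]],
               k = as.numeric(r[[4]]), p = as.numeric(r[[5]]),
               stringsAsFactors = FALSE)
  }))
}

test_that("reduction gain table averages per-layer differences", {
  tbl <- expand.grid(layer = c("l1", "l2"), reduction = reductions(),
                     k = c(5, 10), stringsAsFactors = FALSE)
  tbl$backbone <- "net"
  tbl$p <- 0.5
  tbl$p[tbl$reduction == "GAP"] <- c(0.6, 0.7, 0.5, 0.55)
  tbl$p[tbl$reduction == "GMP"] <- c(0.55, 0.6, 0.52, 0.5)
  tbl$p[tbl$reduction == "FLATTEN"] <- c(0.4, 0.5, 0.56, 0.6)
  gt <- reduction_gain_table(tbl)
  pick <- function(m, k) gt$glp[gt$reduction == m & gt$k == k]
  # hand-computed layer averages of (GAP - m)
  expect_equal(pick("GMP", 5), mean(c(0.6 - 0.55, 0.7 - 0.6)))
  expect_equal(pick("GMP", 10), mean(c(0.5 - 0.52, 0.55 - 0.5)))
  expect_equal(pick("FLATTEN", 5), mean(c(0.6 - 0.4, 0.7 - 0.5)))
  expect_equal(pick("FLATTEN", 10), mean(c(0.5 - 0.56, 0.55 - 0.6)))
  # negative entries (a loss for average pooling) are legitimate
  expect_true(any(gt$glp < 0))
  # all-equal table -> all differences zero
  tbl0 <- tbl; tbl0$p <- 0.5
  expect_true(all(reduction_gain_table(tbl0)$glp == 0))
  # missing cells are a completeness error
  expect_error(reduction_gain_table(tbl[tbl$reduction != "GMP", ]),
               class = "hc_completeness_error")
})

test_that("select_best_reduction maximizes the grand mean with fixed tie order", {
  base <- expand.grid(backbone = "net", layer = c("l1", "l2"),
                      reduction = reductions(), k = c(5, 10),
                      stringsAsFactors = FALSE)
  gap_best <- base
  gap_best$p <- ifelse(gap_best$reduction == "GAP", 0.8, 0.5)
  expect_identical(select_best_reduction(gap_best)$reduction, "GAP")
  fl_best <- base
  fl_best$p <- ifelse(fl_best$reduction == "FLATTEN", 0.9, 0.2)
  expect_identical(select_best_reduction(fl_best)$reduction, "FLATTEN")
  # mixed table: argmax of hand-computed grand means
  set.seed(17)
  mixed <- base
  mixed$p <- runif(nrow(mixed))
  gm <- vapply(reductions(), function(r) mean(mixed$p[mixed$reduction == r]),
               numeric(1))
  res <- select_best_reduction(mixed)
  expect_identical(res$reduction, names(which.max(gm)))
  expect_equal(res$grand_means, gm)
  # exact tie resolves to GAP and is flagged
  tie <- base; tie$p <- 0.5
  res_tie <- select_best_reduction(tie)
  expect_identical(res_tie$reduction, "GAP")
  expect_true(res_tie$tie)
})

test_that("select_best_layer is plain argmax when one layer dominates", {
  tbl <- mk_tbl(list("net", "top", "GAP", 5, 0.9),
                list("net", "top", "GAP", 10, 0.8),
                list("net", "mid", "GAP", 5, 0.5),
                list("net", "mid", "GAP", 10, 0.4))
  res <- select_best_layer(tbl)
  expect_identical(res$layer, "top")
  expect_true(res$unanimous)
  expect_null(res$report)
})

test_that("conflicted layer selection minimizes the total deficit", {
  # three candidate layers, each best at some k; deficits enumerable by hand
  tbl <- rbind(
    mk_tbl(list("net", "A", "GAP", 5, 0.70), list("net", "A", "GAP", 10, 0.60),
           list("net", "A", "GAP", 50, 0.40)),
    mk_tbl(list("net", "B", "GAP", 5, 0.68), list("net", "B", "GAP", 10, 0.62),
           list("net", "B", "GAP", 50, 0.41)),
    mk_tbl(list("net", "C", "GAP", 5, 0.60), list("net", "C", "GAP", 10, 0.55),
           list("net", "C", "GAP", 50, 0.45)))
  # per-k maxima: 0.70 (A), 0.62 (B), 0.45 (C)
  # deficits: A = 0 + 0.02 + 0.05 = 0.07; B = 0.02 + 0 + 0.04 = 0.06;
  #           C = 0.10 + 0.07 + 0 = 0.17 -> B wins
  res <- select_best_layer(tbl)
  expect_false(res$unanimous)
  expect_identical(res$layer, "B")
  expect_equal(unname(res$deficits[c("A", "B", "C")]), c(0.07, 0.06, 0.17))
  # the audit report holds the pairwise differences of B against A and C
  expect_setequal(unique(res$report$other), c("A", "C"))
  expect_equal(res$report$glp[res$report$other == "A" & res$report$k == 5],
               0.68 - 0.70)
  # exhaustive check against a brute-force argmin on random tables
  set.seed(23)
  for (i in 1:10) {
    t2 <- expand.grid(backbone = "net", layer = c("x", "y", "z"),
                      reduction = "GAP", k = c(5, 10, 50),
                      stringsAsFactors = FALSE)
    t2$p <- round(runif(nrow(t2)), 3)
    res2 <- select_best_layer(t2)
    maxima <- tapply(t2$p, t2$k, max)
    cands <- unique(vapply(names(maxima), function(kk) {
      sub <- t2[t2$k == as.numeric(kk), ]
      sort(sub$layer[sub$p == max(sub$p)])[1]
    }, character(1)))
    if (length(cands) == 1) {
      expect_identical(res2$layer, cands)
    } else {
      defs <- vapply(cands, function(l) {
        sum(maxima - t2$p[t2$layer == l][order(t2$k[t2$layer == l])])
      }, numeric(1))
      expect_identical(res2$layer,
                       sort(names(defs)[defs <= min(defs) + 1e-12])[1])
    }
  }
})

test_that("published conflicted-layer cells select the published choices", {
  for (case in list(c("MobileNetV2", "block_14_add"),
                    c("NASNetLarge", "normal_concat_12"),
                    c("VGG16", "block5_pool"))) {
    cells <- benchmark_layer_cells(case[1])
    res <- select_best_layer(cells)
    expect_false(res$unanimous)
    expect_identical(res$layer, case[2])
  }
})

test_that("compare_backbones orders by P@5 with documented tie-breaks", {
  tbl <- rbind(mk_tbl(list("netA", "la", "GAP", 5, 0.70),
                      list("netA", "la", "GAP", 10, 0.60)),
               mk_tbl(list("netB", "lb", "GAP", 5, 0.74),
                      list("netB", "lb", "GAP", 10, 0.67)))
  res <- compare_backbones(tbl)
  expect_identical(res$ranking$backbone, c("netB", "netA"))
  expect_identical(names(res$ranking), c("backbone", "layer", "p5", "p10"))
  # tie on P@5 resolves by P@10, then name
  t2 <- rbind(mk_tbl(list("netA", "la", "GAP", 5, 0.7),
                     list("netA", "la", "GAP", 10, 0.65)),
              mk_tbl(list("netB", "lb", "GAP", 5, 0.7),
                     list("netB", "lb", "GAP", 10, 0.60)),
              mk_tbl(list("netC", "lc", "GAP", 5, 0.7),
                     list("netC", "lc", "GAP", 10, 0.65)))
  expect_identical(compare_backbones(t2)$ranking$backbone,
                   c("netA", "netC", "netB"))
  # hand-built three-backbone ranking from the published chosen-layer rows
  bm <- published_benchmark()$chosen_layer_precision
  sub <- bm[bm$backbone %in% c("VGG16", "EfficientNetV2L", "InceptionV3"), ]
  long <- do.call(rbind, lapply(seq_len(nrow(sub)), function(i) {
    data.frame(backbone = sub$backbone[i], layer = sub$layer[i],
               reduction = "GAP", k = c(5, 10, 50, 100),
               p = as.numeric(sub[i, c("p5", "p10", "p50", "p100")]),
               stringsAsFactors = FALSE)
  }))
  expect_identical(compare_backbones(long)$ranking$backbone,
                   c("EfficientNetV2L", "InceptionV3", "VGG16"))
})
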