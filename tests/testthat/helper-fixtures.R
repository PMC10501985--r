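# Shared fixtures: hand-rolled oracles kept independent of the package's
# own code paths.

# Brute-force ranking oracle: scalar cosine per candidate, stable sort by
# (-similarity, id).
oracle_rank <- function(query_values, matrix, ids, labels,
                        exclude = character(0)) {
  keep <- !(ids %in% exclude)
  sims <- vapply(which(keep), function(i) {
    u <- as.double(matrix[i, ]); v <- as.double(query_values)
    sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  }, numeric(1))
  ord <- order(-sims, ids[keep])
  data.frame(item_id = ids[keep][ord], label = labels[keep][ord],
             similarity = sims[ord], stringsAsFactors = FALSE)
}

# Random bank with optional duplicated rows (tie construction).
random_bank <- function(n, d, seed, n_dups = 0) {
  set.seed(seed)
  m <- matrix(rnorm(n * d), n, d)
  if (n_dups > 0) {
    src <- sample(n, n_dups, replace = TRUE)
    dst <- sample(setdiff(seq_len(n), src), n_dups)
    m[dst, ] <- m[src, ]
  }
  feature_bank(m, labels = sample(c("a", "b"), n, replace = TRUE),
               ids = sprintf("it%03d", seq_len(n)),
               provenance = list(backbone = "synthetic", layer = "synthetic",
                                 reduction = "GAP"))
}

# Random per-query outcome fixtures over a fixed label alphabet.
random_outcomes <- function(n_queries, kmax, classes, seed) {
  set.seed(seed)
  lapply(seq_len(n_queries), function(i) {
    query_outcome(sprintf("q%02d", i), sample(classes, 1),
                  sample(classes, kmax, replace = TRUE))
  })
}

# Small constant-colour patch for preprocessing tests.
flat_patch <- function(r, g, b, side = 8, id = "p1", label = "benign") {
  px <- array(0, c(side, side, 3))
  px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
  raw_patch(px, item_id = id, label = label)
}
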