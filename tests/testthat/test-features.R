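test_that("feature maps validate their shape against the catalogue", {
  ok <- feature_map(array(0.5, c(7, 7, 512)), "VGG16", "block5_pool")
  expect_s3_class(ok, "feature_map")
  expect_error(feature_map(array(0, c(7, 7, 511)), "VGG16", "block5_pool"),
               class = "hc_validation_error")
  expect_error(feature_map(array(0, c(14, 14, 512)), "VGG16", "block5_pool"),
               class = "hc_validation_error")
  # a backend returning the wrong shape is rejected at extraction
  bad <- new_backend("bad-shape", function(bb, lay, px) array(0, c(2, 2, 2)))
  input <- prepare_patch(flat_patch(10, 20, 30, side = 16), "VGG16")
  err <- tryCatch(extract_feature_map(input, "VGG16", "block5_pool", bad),
                  error = identity)
  expect_s3_class(err, "hc_validation_error")
  expect_match(conditionMessage(err), "7x7x512")
  expect_match(conditionMessage(err), "2x2x2")
})

test_that("GAP, GMP and FLATTEN match hand arithmetic on a 2x2x1 map", {
  # bypass catalogue lookup with a synthetic layer spec via direct structure
  vals <- array(0, c(2, 2, 1))
  vals[1, 1, 1] <- 1; vals[1, 2, 1] <- 2; vals[2, 1, 1] <- 3; vals[2, 2, 1] <- 4
  fm <- structure(list(values = vals, backbone = "synthetic",
                       layer = list(name = "toy", height = 2L, width = 2L,
                                    channels = 1L),
                       item_id = "i", label = "l"), class = "feature_map")
  expect_equal(reduce_feature_map(fm, "GAP")$values, 2.5)
  expect_equal(reduce_feature_map(fm, "GMP")$values, 4)
  expect_equal(reduce_feature_map(fm, "FLATTEN")$values, c(1, 2, 3, 4))
})

test_that("flatten is row-major with the channel index fastest", {
  vals <- array(seq_len(2 * 3 * 2), c(2, 3, 2))  # H=2, W=3, C=2
  fm <- structure(list(values = vals, backbone = "synthetic",
                       layer = list(name = "toy", height = 2L, width = 3L,
                                    channels = 2L),
                       item_id = "i", label = "l"), class = "feature_map")
  flat <- reduce_feature_map(fm, "FLATTEN")$values
  # index ((h-1)*W + (w-1))*C + c
  manual <- numeric(12)
  for (h in 1:2) for (w in 1:3) for (ch in 1:2) {
    manual[((h - 1) * 3 + (w - 1)) * 2 + ch] <- vals[h, w, ch]
  }
  expect_equal(flat, manual)
})

test_that("pooling invariants hold on random catalogue-shaped maps", {
  set.seed(42)
  for (rep in 1:5) {
    vals <- array(rnorm(7 * 7 * 160), c(7, 7, 160))
    fm <- feature_map(vals, "MobileNetV2", "block_14_add")
    gap <- reduce_feature_map(fm, "GAP")$values
    gmp <- reduce_feature_map(fm, "GMP")$values
    expect_true(all(gmp >= gap))
    # constant map: both poolings return the constant
    cst <- feature_map(array(3.25, c(7, 7, 160)), "MobileNetV2", "block_14_add")
    expect_equal(unique(reduce_feature_map(cst, "GAP")$values), 3.25)
    expect_equal(unique(reduce_feature_map(cst, "GMP")$values), 3.25)
    # spatial permutation leaves global pooling unchanged
    perm <- sample(49)
    shuffled <- array(apply(vals, 3, function(ch) as.vector(ch)[perm]),
                      c(7, 7, 160))
    fs <- feature_map(shuffled, "MobileNetV2", "block_14_add")
    expect_equal(reduce_feature_map(fs, "GAP")$values, gap)
    expect_equal(reduce_feature_map(fs, "GMP")$values, gmp)
    # linearity of GAP and FLATTEN; positive homogeneity of GMP
    fm2 <- feature_map(2 * vals, "MobileNetV2", "block_14_add")
    expect_equal(reduce_feature_map(fm2, "GAP")$values, 2 * gap)
    expect_equal(reduce_feature_map(fm2, "FLATTEN")$values,
                 2 * reduce_feature_map(fm, "FLATTEN")$values)
    expect_equal(reduce_feature_map(fm2, "GMP")$values, 2 * gmp)
  }
})

test_that("reduced vector lengths match the catalogue on sampled layers", {
  be <- seeded_backend(11)
  probe <- list(c("VGG16", "block5_pool"),
                c("MobileNetV2", "block_13_project_BN"),
                c("DenseNet201", "pool3_pool"))
  patch <- flat_patch(90, 140, 180, side = 24)
  for (pr in probe) {
    spec <- layer_spec(pr[1], pr[2])
    for (red in reductions()) {
      v <- extract_vector(patch, pr[1], pr[2], red, be)
      expect_length(v$values, reduced_size(spec, red))
      expect_true(all(is.finite(v$values)))
    }
  }
})

test_that("the seeded backend is deterministic and seed-sensitive", {
  patch <- flat_patch(120, 60, 200, side = 24)
  v1 <- extract_vector(patch, "VGG16", "block5_pool", "GAP", seeded_backend(5))
  v2 <- extract_vector(patch, "VGG16", "block5_pool", "GAP", seeded_backend(5))
  expect_identical(v1$values, v2$values)
  v3 <- extract_vector(patch, "VGG16", "block5_pool", "GAP", seeded_backend(6))
  expect_false(identical(v1$values, v3$values))
  # extraction does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99)
  invisible(extract_vector(patch, "VGG16", "block5_pool", "GAP",
                           seeded_backend(5)))
  expect_identical(rnorm(1), before)
})

test_that("provenance travels from patch to vector", {
  p <- flat_patch(10, 20, 30, id = "patch-7", label = "insitu")
  v <- extract_vector(p, "VGG16", "block4_pool", "GMP", seeded_backend(1))
  expect_identical(v$item_id, "patch-7")
  expect_identical(v$label, "insitu")
  expect_identical(v$backbone, "VGG16")
  expect_identical(v$layer, "block4_pool")
  expect_identical(v$reduction, "GMP")
})
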