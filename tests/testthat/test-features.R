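test_that("quantisation maps ranges into level bands as documented", {
  expect_true(all(quantize(matrix(5, 4, 4))$levels == 1L))

  q2 <- quantize(matrix(c(0, 255, 0, 255), 2, 2), Ng = 2)
  expect_setequal(as.vector(q2$levels), c(1L, 2L))

  # linear ramp into 4 equal-count bands
  ramp <- matrix(seq(0, 255, length.out = 256), 16, 16)
  q4 <- quantize(ramp, Ng = 4)
  expect_equal(as.vector(table(q4$levels)), rep(64L, 4))
  expect_equal(sort(unique(as.vector(q4$levels))), 1:4)

  qw <- quantize(matrix(c(3, 10, 17, 25), 2, 2), mode = "fixed_bin_width",
                 bin_width = 8)
  expect_equal(sort(unique(as.vector(qw$levels))), c(1L, 2L, 3L, 4L))

  expect_error(quantize(matrix(1, 2, 2), Ng = 1), "Ng")
})

test_that("first-order features match hand arithmetic", {
  fo <- first_order_features(matrix(7, 8, 8))
  expect_equal(fo[["firstorder_Variance"]], 0)
  expect_equal(fo[["firstorder_MeanAbsoluteDeviation"]], 0)
  expect_equal(fo[["firstorder_Minimum"]], 7)
  expect_equal(fo[["firstorder_Maximum"]], 7)
  expect_equal(fo[["firstorder_Entropy"]], 0)
  expect_equal(fo[["firstorder_Uniformity"]], 1)
  expect_equal(fo[["firstorder_Skewness"]], 0)

  fo2 <- first_order_features(matrix(c(1, 2, 3, 4), 2, 2))
  expect_equal(fo2[["firstorder_Mean"]], 2.5)
  expect_equal(fo2[["firstorder_Variance"]], 1.25)  # population variance
  expect_equal(fo2[["firstorder_MeanAbsoluteDeviation"]], 1.0)
  expect_equal(fo2[["firstorder_Energy"]], 1 + 4 + 9 + 16)
  expect_equal(fo2[["firstorder_RootMeanSquared"]], sqrt(30 / 4))
  expect_equal(fo2[["firstorder_Range"]], 3)

  # permutation invariance
  p <- random_patch(8, Ng = 200, seed = 2)
  perm <- matrix(sample(as.vector(p)), 8, 8)
  expect_equal(first_order_features(p), first_order_features(perm))
})

test_that("shape features behave geometrically", {
  sq <- shape2d_features(matrix(TRUE, 64, 64), mm_per_px = 0.1)
  expect_equal(sq[["shape2d_PixelSurface"]], 4096 * 0.01)
  expect_equal(sq[["shape2d_Elongation"]], 1)
  expect_equal(sq[["shape2d_MajorAxisLength"]],
               sq[["shape2d_MinorAxisLength"]])
  expect_equal(sq[["shape2d_MaximumDiameter"]], sqrt(2) * 63 * 0.1)

  # a disc is rounder than a square of the same area
  n <- 65
  cc <- (n + 1) / 2
  disc <- outer(1:n, 1:n, function(r, c) (r - cc)^2 + (c - cc)^2 <= 24^2)
  side <- round(sqrt(sum(disc)))
  square <- matrix(FALSE, n, n); square[1:side, 1:side] <- TRUE
  sd_ <- shape2d_features(disc); ss <- shape2d_features(square)
  expect_gt(sd_[["shape2d_Sphericity"]], ss[["shape2d_Sphericity"]])
  expect_lt(abs(sd_[["shape2d_Sphericity"]] - 1), 0.1)

  expect_error(shape2d_features(matrix(FALSE, 4, 4)), "empty")
})

test_that("GLCM features match brute-force pair enumeration", {
  # horizontal pairs of [[1,2],[1,2]]: counts {(1,2): 2, (2,1): 2}
  lev <- matrix(c(1L, 1L, 2L, 2L), 2, 2)  # column-major: rows (1,2),(1,2)
  q <- structure(list(levels = lev, Ng = 2L, original = lev),
                 class = "quantized_patch")
  P0 <- echotherm:::cooccurrence_matrix(lev, 2L, c(0L, 1L))
  expect_equal(P0, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  st <- echotherm:::glcm_stats_one(P0)
  expect_equal(st[["Contrast"]], 1)
  expect_equal(st[["MaximumProbability"]], 0.5)

  # constant patch degenerate conventions
  gc <- glcm_features(quantize(matrix(3, 8, 8)))
  expect_equal(gc[["glcm_ClusterProminence"]], 0)
  expect_equal(gc[["glcm_Contrast"]], 0)
  expect_equal(gc[["glcm_MaximumProbability"]], 1)
  expect_equal(gc[["glcm_JointEntropy"]], 0)
  expect_equal(gc[["glcm_Correlation"]], 1)
})

test_that("angle-averaged texture features are 90-degree rotation invariant", {
  for (seed in 1:5) {
    p <- random_patch(8, Ng = 5, seed = seed)
    q1 <- quantize(p, Ng = 5)
    q2 <- quantize(rotate90(p), Ng = 5)
    expect_equal(glcm_features(q1), glcm_features(q2), tolerance = 1e-12)
    expect_equal(glrlm_features(q1), glrlm_features(q2), tolerance = 1e-12)
    expect_equal(glszm_features(q1), glszm_features(q2), tolerance = 1e-12)
    expect_equal(ngtdm_features(q1), ngtdm_features(q2), tolerance = 1e-12)
    expect_equal(gldm_features(q1), gldm_features(q2), tolerance = 1e-12)
  }
})

test_that("run and zone structure of simple patches is enumerated exactly", {
  # constant 4 x 4 patch: every direction sees runs of length 4
  qc <- quantize(matrix(5, 4, 4))
  rl <- glrlm_features(qc)
  # horizontal/vertical: 4 runs of length 4 -> LRE 16 each; each diagonal
  # family: runs of length 1,2,3,4,3,2,1 -> LRE 44/7; averaged: 78/7
  expect_equal(rl[["glrlm_LongRunEmphasis"]], (16 + 16 + 44 / 7 + 44 / 7) / 4)
  sz <- glszm_features(qc)
  expect_equal(sz[["glszm_LargeAreaEmphasis"]], 256)  # single zone of 16
  expect_equal(sz[["glszm_ZonePercentage"]], 1 / 16)

  # checkerboard: 8-connectivity merges diagonals, so exactly 2 zones
  cb <- quantize(checkerboard(8), Ng = 2)
  zb <- echotherm:::label_zones(cb$levels)
  expect_equal(length(unique(zb$labels)), 2)
  expect_equal(glszm_features(cb)[["glszm_ZonePercentage"]], 2 / 64)
  # and the brute-force flood fill agrees
  expect_equal(nrow(oracle_zones(cb$levels)), 2)

  expect_equal(ngtdm_features(qc)[["ngtdm_Contrast"]], 0)
})

test_that("texture features match the brute-force oracles on random patches", {
  for (seed in 1:8) {
    p <- random_patch(8, Ng = 6, seed = seed)
    q <- quantize(p, Ng = 6)
    impl <- c(glcm_features(q), glrlm_features(q), glszm_features(q),
              ngtdm_features(q), gldm_features(q))
    orac <- oracle_all_matrix_features(q)
    expect_equal(impl, orac[names(impl)], tolerance = 1e-9)
  }
})

test_that("the assembled battery honours the 104-feature contract", {
  expect_length(feature_names(), 104)
  counts <- vapply(FEATURE_FAMILIES, function(f) length(feature_names(f)),
                   integer(1))
  expect_equal(unname(counts), c(19L, 10L, 24L, 16L, 16L, 5L, 14L))

  for (p in list(matrix(42, 64, 64), checkerboard(64),
                 random_patch(64, Ng = 256, seed = 9))) {
    v <- extract_features(p, mm_per_px = 0.1)
    expect_length(v, 104)
    expect_true(all(is.finite(v)))
    expect_identical(names(v), feature_names())
  }

  # deterministic
  p <- random_patch(16, Ng = 100, seed = 3)
  expect_identical(extract_features(p), extract_features(p))
})

test_that("z-score normalisation uses training statistics only", {
  with_seed <- get("with_seed", asNamespace("echotherm"))
  x <- with_seed(4, matrix(rnorm(200, 5, 2), 50, 4,
                           dimnames = list(NULL, paste0("f", 1:4))))
  x[, 3] <- 7  # constant feature
  st <- fit_normalizer(x)
  z <- apply_normalizer(st, x)
  expect_equal(unname(colMeans(z)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(z[, c(1, 2, 4)], 2, sd)), rep(1, 3),
               tolerance = 1e-12)
  expect_true(all(z[, 3] == 0))

  # held-out vector equal to the training mean maps to zero
  z0 <- apply_normalizer(st, st$mean)
  expect_true(all(abs(z0) < 1e-12))

  expect_error(fit_normalizer(x[1, , drop = FALSE]), "at least 2")
  expect_error(apply_normalizer(st, x[, 1:2]), "missing feature")
})
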