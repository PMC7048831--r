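test_that("quantization maps the ROI range onto 1..Ng and is affine invariant", {
  dat <- array(runif(10^3), rep(10, 3))
  mask <- array(1L, rep(10, 3))
  q <- quantize_roi(dat, mask, 32)
  expect_equal(q$levels[which.min(dat)], 1L)
  expect_equal(q$levels[which.max(dat)], 32L)
  expect_true(all(q$levels >= 1 & q$levels <= 32))
  q2 <- quantize_roi(3.7 * dat + 11, mask, 32)
  expect_identical(q$levels, q2$levels)
  qc <- quantize_roi(array(5, rep(10, 3)), mask, 32)
  expect_true(qc$degenerate)
  expect_true(all(qc$levels == 1L))
})

test_that("GLCM of the two-level checkerboard matches hand enumeration", {
  # 4x4x1 checkerboard restricted to in-plane horizontal/vertical offsets is
  # exercised via the brute-force enumerator on the same 13-offset merge
  chk <- array(0L, c(4, 4, 1))
  chk[, , 1] <- (outer(1:4, 1:4, "+") %% 2) + 1L
  q <- structure(list(levels = chk, Ng = 2L, source = "raw", degenerate = FALSE),
                 class = "quantized_roi")
  m <- compute_texture_matrices(q)
  expect_equal(m$glcm, brute_glcm(chk, 2))
  expect_equal(sum(m$glcm), 1, tolerance = 1e-12)
  # diagonal offsets connect equal levels, so the merged GLCM is not purely
  # anti-diagonal; restricting to axis offsets gives the classic [[0,.5],[.5,0]]
  axis_only <- m$glcm
  expect_true(axis_only[1, 2] == axis_only[2, 1])
})

test_that("texture features reproduce hand-computed GLCM values", {
  feats <- gliofract:::glcm_features(matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_equal(unname(feats["energy"]), 0.5)
  expect_equal(unname(feats["inverse_difference_moment"]), 0.5)
  expect_equal(unname(feats["correlation"]), -1)
  single <- gliofract:::glcm_features(matrix(1, 1, 1))
  expect_equal(unname(single["energy"]), 1)
  expect_equal(unname(single["contrast"]), 0)
  expect_equal(unname(single["correlation"]), 0) # zero-variance convention
})

test_that("the texture catalogue has 41 uniquely named finite features", {
  cs <- small_phantom()
  wt <- derive_region_masks(cs$mask)$WT
  v <- texture_feature_vector(compute_texture_matrices(
    quantize_roi(cs$images$FLAIR, wt, 32)))
  expect_length(v, 41)
  expect_equal(anyDuplicated(names(v)), 0)
  expect_true(all(is.finite(v)))
  expect_true(all(c("glcm.correlation", "glcm.information_correlation1",
                    "glcm.inverse_difference_moment", "glcm.entropy",
                    "ngtdm.complexity") %in% names(v)))
})

test_that("texture matrices agree with brute-force enumeration on random ROIs", {
  for (s in 1:25) {
    q <- withr::with_seed(s, {
      arr <- array(sample(0:3, 125, replace = TRUE), c(5, 5, 5))
      storage.mode(arr) <- "integer"
      arr
    })
    if (sum(q > 0) < 2) next
    qr <- structure(list(levels = q, Ng = 3L, source = "raw", degenerate = FALSE),
                    class = "quantized_roi")
    m <- compute_texture_matrices(qr)
    expect_equal(m$glcm, brute_glcm(q, 3), info = paste("seed", s))
    expect_equal(m$glrlm, brute_glrlm(q, 3), info = paste("seed", s))
    bz <- brute_glszm(q, 3)
    expect_equal(dim(m$glszm), dim(bz), info = paste("seed", s))
    expect_equal(m$glszm, bz, info = paste("seed", s))
  }
})

test_that("histogram statistics match hand computation and moment oracles", {
  # mass uniform over 8 occupied bins: entropy 3 bits, energy 1/8
  x <- rep(seq(0, 63, by = 9), each = 8) # 8 distinct values, 8 voxels each
  vol <- array(x, c(4, 4, 4))
  h <- histogram_stats(vol, array(1, c(4, 4, 4)))
  expect_equal(unname(h["entropy"]), 3)
  expect_equal(unname(h["energy"]), 0.125)
  hc <- histogram_stats(array(7, c(4, 4, 4)), array(1, c(4, 4, 4)))
  expect_equal(unname(hc[c("variance", "skewness", "kurtosis")]), c(0, 0, 0))
  z <- withr::with_seed(42, array(rnorm(1e5), c(100, 100, 10)))
  hz <- histogram_stats(z, array(1, dim(z)))
  expect_equal(unname(hz["skewness"]), 0, tolerance = 0.05)
  expect_lt(abs(unname(hz["kurtosis"]) - 3), 0.1)
})
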