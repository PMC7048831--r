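test_that("triangular-prism fractal dimension has exact flat limits", {
  expect_identical(ptpsa_dimension(matrix(5, 17, 17)), 2)
  # planar ramp: bilinear center lies on the plane, area constant across scales
  expect_equal(ptpsa_dimension(outer(1:17, rep(1, 17))), 2, tolerance = 1e-12)
  expect_error(ptpsa_dimension(matrix(0, 18, 18)), "divisible")
  # shift invariance
  p <- generate_fbm_field(c(33, 33), 0.5, 4)
  expect_equal(ptpsa_dimension(p), ptpsa_dimension(p + 100), tolerance = 1e-8)
})

test_that("fractal dimension decreases with the Hurst exponent", {
  ds <- sapply(c(0.2, 0.5, 0.8), function(h) {
    mean(sapply(1:20, function(s) ptpsa_dimension(generate_fbm_field(c(65, 65), h, s))))
  })
  expect_true(all(diff(ds) < 0))
  expect_true(all(ds > 2 & ds < 3))
})

test_that("wavelet Hurst estimator recovers the generator's exponent", {
  for (h in c(0.3, 0.5, 0.7)) {
    est <- sapply(1:20, function(s)
      as.numeric(mbm_hurst(generate_fbm_field(c(128, 128), h, s))))
    expect_lt(abs(mean(est) - h), 0.1)
    # cross-check against the independent variogram oracle
    vg <- sapply(1:20, function(s) variogram_hurst(generate_fbm_field(c(128, 128), h, s)))
    expect_lt(abs(mean(est) - mean(vg)), 0.15)
  }
  est3 <- mean(sapply(1:20, function(s) as.numeric(mbm_hurst(generate_fbm_field(c(128, 128), 0.2, s)))))
  est5 <- mean(sapply(1:20, function(s) as.numeric(mbm_hurst(generate_fbm_field(c(128, 128), 0.5, s)))))
  est8 <- mean(sapply(1:20, function(s) as.numeric(mbm_hurst(generate_fbm_field(c(128, 128), 0.8, s)))))
  expect_true(est3 < est5 && est5 < est8)
})

test_that("wavelet Hurst estimator hits the white-noise and flat limits", {
  wn <- withr::with_seed(1, matrix(rnorm(128 * 128), 128))
  expect_lte(as.numeric(mbm_hurst(wn)), 0.15)
  flat <- mbm_hurst(matrix(2, 64, 64))
  expect_true(attr(flat, "degenerate"))
  # shift invariance
  p <- generate_fbm_field(c(64, 64), 0.5, 9)
  expect_equal(as.numeric(mbm_hurst(p)), as.numeric(mbm_hurst(p + 7)), tolerance = 1e-8)
})

test_that("Hoelder exponent matches analytic local regularity", {
  g <- 33; ctr <- c(17, 17, 17); ax <- 1:g
  cusp <- array(0, rep(g, 3))
  for (z in ax) for (y in ax)
    cusp[, y, z] <- sqrt(sqrt((ax - 17)^2 + (y - 17)^2 + (z - 17)^2))
  expect_equal(holder_exponent(cusp, ctr), 0.5, tolerance = 0.1)
  ramp <- array(rep(ax, g * g), rep(g, 3))
  expect_equal(holder_exponent(ramp, ctr), 1.0, tolerance = 0.05)
  expect_equal(holder_exponent(array(3, rep(g, 3)), ctr), 2)
  expect_error(holder_exponent(ramp, c(2, 17, 17)), "boundary")
})

test_that("characterization maps are flat-exact, mask-local and deterministic", {
  cs <- small_phantom()
  wt <- derive_region_masks(cs$mask)$WT
  flat <- volume_image(array(1, dim(wt)) + 0 * wt, modality = "FLAIR")
  m <- characterization_map(flat, wt, "PTPSA")
  expect_true(all(m$data[wt == 1] == 2))
  expect_true(all(m$data[wt == 0] == 0))
  expect_equal(m$modality, "PTPSA")
  expect_error(characterization_map(flat, array(0, dim(wt)), "MBM"), "empty")
  m1 <- characterization_map(cs$images$FLAIR, wt, "HE")
  m2 <- characterization_map(cs$images$FLAIR, wt, "HE")
  expect_identical(m1$data, m2$data)
  # in-map values bounded by the estimator's range
  mb <- characterization_map(cs$images$FLAIR, wt, "MBM")
  expect_true(all(mb$data[wt == 1] >= 0 & mb$data[wt == 1] <= 1))
})

test_that("regularity-organized classes separate in the Hoelder map", {
  sp <- phantom_spec(grid_size = 48)
  vals <- function(cls, seeds) sapply(seeds, function(s) {
    cs <- generate_phantom_case(sp, c(IDH = cls), seed = s, effect_hurst = 0.4)
    wt <- derive_region_masks(cs$mask)$WT
    m <- characterization_map(cs$images$FLAIR, wt, "HE")
    x <- m$data[wt == 1]
    mean((x - mean(x))^4) / mean((x - mean(x))^2)^2 # heavy-tailed local regularity
  })
  pos <- vals("positive", 1:12)
  neg <- vals("negative", 21:32)
  expect_lt(t.test(pos, neg)$p.value, 0.01)
})
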