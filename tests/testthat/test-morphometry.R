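test_that("volumetric features are exact on hand-counted masks", {
  v <- c(V_WT = 700, V_ED = 400, V_ET = 200, V_NCR = 100, V_brain = 10000)
  f <- volumetric_features(v)
  expect_length(f, 12)
  expect_equal(unname(f["V_WT"]), 700)
  expect_equal(unname(f["V_WT_over_V_brain"]), 0.07)
  expect_equal(unname(f["V_ET_over_V_ED"]), 0.5)
  expect_equal(unname(f["V_NCR_over_V_ED_plus_V_ET"]), 0.1667, tolerance = 1e-3)
  expect_equal(unname(f["V_ED_over_V_ET_plus_V_NCR"]), 1.3333, tolerance = 1e-3)
  # zero denominator convention
  v0 <- c(V_WT = 300, V_ED = 0, V_ET = 200, V_NCR = 100, V_brain = 1000)
  f0 <- volumetric_features(v0)
  expect_equal(unname(f0["V_ET_over_V_ED"]), 0)
  expect_true("V_ET_over_V_ED" %in% attr(f0, "degenerate"))
})

test_that("projected rectangle properties match second-moment oracles", {
  reg <- array(0L, c(30, 40, 5))
  reg[6:15, 11:30, 2] <- 1L # 10 x 20 axis-aligned rectangle on one slice
  p <- projection_region_properties(reg, "z")
  expect_equal(unname(p["area"]), 200)
  expect_equal(unname(p[c("bbox_width", "bbox_height")]), c(10, 20))
  expect_equal(unname(p["extent"]), 1)
  expect_equal(unname(p["solidity"]), 1)
  expect_equal(unname(p["perimeter"]), 60) # 2*(10+20) exposed edges
  # major axis = 4*sqrt(discrete variance of 1..20) = 4*sqrt(33.25)
  expect_equal(unname(p["major_axis_length"]), 4 * sqrt((20^2 - 1) / 12),
               tolerance = 1e-8)
  expect_equal(unname(p["orientation"]), 90) # long side along second axis
  # translation invariance of everything but location entries
  reg2 <- array(0L, c(30, 40, 5)); reg2[16:25, 16:35, 4] <- 1L
  p2 <- projection_region_properties(reg2, "z")
  loc <- c("bbox_corner_x", "bbox_corner_y", "centroid_x", "centroid_y")
  expect_equal(p[setdiff(names(p), loc)], p2[setdiff(names(p2), loc)])
})

test_that("disk projection approaches circular limits", {
  g <- 41
  reg <- array(0L, c(g, g, 3))
  for (i in 1:g) for (j in 1:g)
    if ((i - 21)^2 + (j - 21)^2 <= 100) reg[i, j, 2] <- 1L
  p <- projection_region_properties(reg, "z")
  expect_lte(unname(p["eccentricity"]), 0.05)
  expect_gte(unname(p["solidity"]), 0.95)
})

test_that("90-degree in-plane rotation swaps axes and orientation", {
  reg <- array(0L, c(40, 40, 3)); reg[6:15, 11:34, 2] <- 1L
  rot <- array(0L, c(40, 40, 3)); rot[11:34, 6:15, 2] <- 1L
  p <- projection_region_properties(reg, "z")
  q <- projection_region_properties(rot, "z")
  expect_equal(unname(p["major_axis_length"]), unname(q["major_axis_length"]))
  expect_equal(unname(p["bbox_width"]), unname(q["bbox_height"]))
  expect_equal(abs(unname(p["orientation"]) - unname(q["orientation"])), 90)
})

test_that("shape block covers 4 regions x 3 axes x 14 properties", {
  cs <- small_phantom()
  b <- shape_feature_block(cs$mask)
  expect_length(b, 168)
  expect_equal(anyDuplicated(names(b)), 0)
  # spherical phantom: per-axis areas of one region agree within 10%
  areas <- b[sprintf("mask.WT.shape_%s.area", c("x", "y", "z"))]
  expect_lt(diff(range(areas)) / mean(areas), 0.1)
  # empty region contributes zeros
  lab <- array(0L, c(12, 12, 12)); lab[4:8, 4:8, 4:8] <- 2L
  b2 <- shape_feature_block(segmentation_mask(lab))
  expect_true(all(b2[grep("^mask\\.NCR", names(b2))] == 0))
})
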