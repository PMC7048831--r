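VOLUMETRIC_NAMES <- c("V_WT", "V_WT_over_V_brain", "V_ED_over_V_WT",
                      "V_ET_over_V_WT", "V_NCR_over_V_WT", "V_ED_over_V_brain",
                      "V_ET_over_V_brain", "V_NCR_over_V_brain",
                      "V_ET_over_V_ED", "V_NCR_over_V_ED",
                      "V_ED_over_V_ET_plus_V_NCR", "V_NCR_over_V_ED_plus_V_ET")

#' Region voxel volumes of a case
#'
#' @param mask a [segmentation_mask()].
#' @param brain_mask binary 3D array.
#' @return Named numeric vector of voxel counts (1 voxel = 1 mm^3):
#'   `V_WT`, `V_ED`, `V_ET`, `V_NCR`, `V_brain`.
#' @export
region_volumes <- function(mask, brain_mask) {
  rm_ <- derive_region_masks(mask)
  c(V_WT = sum(rm_$WT), V_ED = sum(rm_$ED), V_ET = sum(rm_$ET),
    V_NCR = sum(rm_$NCR), V_brain = sum(brain_mask != 0))
}

#' The 12 volumetric ratio features
#'
#' Whole-tumor volume, its fraction of the brain, each sub-region as a
#' fraction of the whole tumor and of the brain, enhancing tumor and necrosis
#' relative to edema, edema relative to (enhancing + necrosis), and necrosis
#' relative to (edema + enhancing). Ratios with a zero denominator are 0 and
#' flagged.
#'
#' @param v named vector from [region_volumes()].
#' @return Named numeric vector of length 12; attribute `degenerate` names any
#'   zero-denominator entries.
#' @export
volumetric_features <- function(v) {
  safe_div <- function(a, b) if (b > 0) a / b else 0
  out <- c(v[["V_WT"]],
           safe_div(v[["V_WT"]], v[["V_brain"]]),
           safe_div(v[["V_ED"]], v[["V_WT"]]),
           safe_div(v[["V_ET"]], v[["V_WT"]]),
           safe_div(v[["V_NCR"]], v[["V_WT"]]),
           safe_div(v[["V_ED"]], v[["V_brain"]]),
           safe_div(v[["V_ET"]], v[["V_brain"]]),
           safe_div(v[["V_NCR"]], v[["V_brain"]]),
           safe_div(v[["V_ET"]], v[["V_ED"]]),
           safe_div(v[["V_NCR"]], v[["V_ED"]]),
           safe_div(v[["V_ED"]], v[["V_ET"]] + v[["V_NCR"]]),
           safe_div(v[["V_NCR"]], v[["V_ED"]] + v[["V_ET"]]))
  names(out) <- VOLUMETRIC_NAMES
  dens <- c(1, v[["V_brain"]], v[["V_WT"]], v[["V_WT"]], v[["V_WT"]],
            v[["V_brain"]], v[["V_brain"]], v[["V_brain"]], v[["V_ED"]],
            v[["V_ED"]], v[["V_ET"]] + v[["V_NCR"]], v[["V_ED"]] + v[["V_ET"]])
  attr(out, "degenerate") <- VOLUMETRIC_NAMES[dens == 0]
  out
}

SHAPE_PROPS <- c("area", "bbox_corner_x", "bbox_corner_y", "bbox_width",
                 "bbox_height", "centroid_x", "centroid_y", "perimeter",
                 "major_axis_length", "minor_axis_length", "eccentricity",
                 "orientation", "solidity", "extent")

# shoelace area of a polygon given vertex coordinates
poly_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Shape properties of a region projected along one axis
#'
#' The 3D region is collapsed by any-voxel projection along `axis`; the
#' resulting pixel set yields area, tight bounding box (corner = minimal
#' in-plane indices), centroid, perimeter (exposed pixel-edge count), major
#' and minor axis lengths (4 x sqrt of the eigenvalues of the second central
#' moment matrix of the pixel coordinates), eccentricity, orientation
#' (degrees in (-90, 90] from the first in-plane axis), solidity (area over
#' the pixel count of the rasterized convex hull, as in the standard
#' region-properties convention) and extent (area over bounding-box area).
#' An empty region returns all zeros, flagged.
#'
#' @param region binary 3D array.
#' @param axis `"x"`, `"y"` or `"z"` (projection axis; `"z"` gives the axial
#'   view).
#' @return Named numeric vector of the 14 properties; attribute `degenerate`
#'   is `TRUE` for an empty region.
#' @export
projection_region_properties <- function(region, axis = c("z", "x", "y")) {
  axis <- match.arg(axis)
  ax <- match(axis, c("x", "y", "z"))
  proj <- apply(region != 0, setdiff(1:3, ax), any)
  px <- which(proj, arr.ind = TRUE)
  if (nrow(px) == 0) {
    out <- stats::setNames(rep(0, length(SHAPE_PROPS)), SHAPE_PROPS)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  u <- px[, 1]; v <- px[, 2]
  area <- nrow(px)
  bb <- c(min(u), min(v), max(u) - min(u) + 1, max(v) - min(v) + 1)
  cen <- c(mean(u), mean(v))
  # perimeter: count of pixel edges adjacent to background
  per <- 0
  occ <- proj
  nr <- nrow(occ); nc <- ncol(occ)
  padded <- matrix(FALSE, nr + 2, nc + 2)
  padded[2:(nr + 1), 2:(nc + 1)] <- occ
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    shifted <- padded[(2:(nr + 1)) + d[1], (2:(nc + 1)) + d[2]]
    per <- per + sum(occ & !shifted)
  }
  # second central moments (population) of the pixel set
  mu20 <- mean((u - cen[1])^2); mu02 <- mean((v - cen[2])^2)
  mu11 <- mean((u - cen[1]) * (v - cen[2]))
  tr <- mu20 + mu02
  det_ <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(0, (tr / 2)^2 - det_))
  l1 <- tr / 2 + disc; l2 <- max(0, tr / 2 - disc)
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  ecc <- if (l1 > 0) sqrt(max(0, 1 - l2 / l1)) else 0
  theta <- if (abs(mu11) < 1e-12 && abs(mu20 - mu02) < 1e-12) 0 else
    0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  if (theta <= -90) theta <- theta + 180
  if (theta > 90) theta <- theta - 180
  # solidity: area over the pixel count of the rasterized convex hull
  # (hull of pixel centers, counted at pixel centers)
  h <- grDevices::chull(u, v)
  hx <- u[h]; hy <- v[h]
  cand <- expand.grid(x = min(u):max(u), y = min(v):max(v))
  inside <- rep(TRUE, nrow(cand))
  nh <- length(hx)
  for (k in seq_len(nh)) { # chull returns clockwise order; interior is right of edges
    k2 <- if (k == nh) 1 else k + 1
    cross <- (hx[k2] - hx[k]) * (cand$y - hy[k]) - (hy[k2] - hy[k]) * (cand$x - hx[k])
    inside <- inside & (cross <= 1e-9)
  }
  hull_px <- sum(inside)
  sol <- if (hull_px > 0) min(1, area / hull_px) else 1
  out <- c(area, bb[1], bb[2], bb[3], bb[4], cen[1], cen[2], per,
           major, minor, ecc, theta, sol, area / (bb[3] * bb[4]))
  names(out) <- SHAPE_PROPS
  attr(out, "degenerate") <- FALSE
  out
}

#' Full per-viewpoint shape feature block
#'
#' [projection_region_properties()] for every region (WT, ED, ET, NCR) and
#' projection axis (x, y, z): 4 x 3 x 14 = 168 named scalars, e.g.
#' `mask.NCR.shape_z.bbox_width` is the necrosis width on the axial view.
#' Empty regions contribute zeros.
#'
#' @param mask a [segmentation_mask()].
#' @return Named numeric vector of length 168.
#' @export
shape_feature_block <- function(mask) {
  rm_ <- derive_region_masks(mask)
  out <- numeric(0)
  for (reg in c("WT", "ED", "ET", "NCR")) {
    for (ax in c("x", "y", "z")) {
      p <- projection_region_properties(rm_[[reg]], ax)
      names(p) <- sprintf("mask.%s.shape_%s.%s", reg, ax, SHAPE_PROPS)
      out <- c(out, p)
    }
  }
  out
}
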