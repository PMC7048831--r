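#' Configuration for fractal texture characterization maps
#'
#' @param window odd side length (voxels) of the local axial patch.
#' @param ptpsa_steps cell sizes (powers of two) for the triangular-prism
#'   surface-area scaling fit; at least 3; `window - 1` must be divisible by
#'   the largest step.
#' @param wavelet_levels number of dyadic wavelet levels J for the Hurst fit.
#' @param wavelet_name analysis wavelet (only `"db4"`, the orthonormal
#'   Daubechies filter with 4 vanishing moments, is built in).
#' @param holder_radii Chebyshev-ball radii for the oscillation fit; >= 3.
#' @param epsilon small positive stabilizer for log-oscillation.
#' @param alpha_cap Hoelder exponent assigned to locally constant patches.
#' @return A `fractal_map_config` list.
#' @export
fractal_map_config <- function(window = 17, ptpsa_steps = c(1, 2, 4, 8),
                               wavelet_levels = 3, wavelet_name = "db4",
                               holder_radii = c(1, 2, 3, 4),
                               epsilon = 1e-6, alpha_cap = 2) {
  if (window %% 2 == 0) stop("fractal_map_config: window must be odd")
  if (length(ptpsa_steps) < 3) stop("fractal_map_config: need >= 3 ptpsa steps")
  if (length(holder_radii) < 3) stop("fractal_map_config: need >= 3 holder radii")
  if (window < 2 * max(ptpsa_steps))
    stop("fractal_map_config: window must be >= 2 * max(ptpsa_steps)")
  if (!identical(wavelet_name, "db4"))
    stop("fractal_map_config: only the db4 analysis wavelet is available")
  list(window = as.integer(window), ptpsa_steps = as.integer(sort(ptpsa_steps)),
       wavelet_levels = as.integer(wavelet_levels), wavelet_name = wavelet_name,
       holder_radii = as.integer(sort(holder_radii)),
       epsilon = epsilon, alpha_cap = alpha_cap)
}

#' Fractal dimension of a 2D patch by triangular-prism surface area
#'
#' Tiles the height field at corner spacing `s` for each step, builds four
#' triangles per cell between the corner heights and the bilinear center, and
#' fits `log A(s)` against `log s`; the fractal dimension is `2 - slope`,
#' clipped to `[2, 3]`. A flat or planar patch gives exactly 2.
#'
#' @param patch 2D numeric matrix; `nrow - 1` and `ncol - 1` must be divisible
#'   by the largest step.
#' @param steps integer cell sizes (>= 3 values).
#' @return Fractal dimension in `[2, 3]`.
#' @export
ptpsa_dimension <- function(patch, steps = c(1, 2, 4, 8)) {
  steps <- as.integer(sort(steps))
  if (length(steps) < 3) stop("ptpsa_dimension: fewer than 3 scales")
  if ((nrow(patch) - 1) %% max(steps) != 0 || (ncol(patch) - 1) %% max(steps) != 0)
    stop("ptpsa_dimension: patch side minus one must be divisible by max step")
  A <- cpp_ptpsa_areas(patch, steps)
  if (any(A <= 0)) stop("ptpsa_dimension: degenerate surface area")
  slope <- stats::coef(stats::lm(log(A) ~ log(steps)))[2]
  min(3, max(2, 2 - unname(slope)))
}

#' Hurst exponent of a 2D patch via wavelet detail variance
#'
#' Applies a separable periodic Daubechies-4 transform to `J` levels, pools
#' the detail coefficients per level, and fits `log2 V(j)` on level `j`.
#' For 2D fractional Brownian fields `V(j) ~ 2^(j(2H+2))`, so
#' `H = (slope - 2)/2`, clipped to `[0, 1]`.
#'
#' @param patch 2D numeric matrix; sides must be divisible by `2^J`.
#' @param config a [fractal_map_config()].
#' @return Hurst estimate in `[0, 1]`; attribute `degenerate` is `TRUE` when
#'   all detail bands have zero variance (flat patch).
#' @export
mbm_hurst <- function(patch, config = fractal_map_config()) {
  J <- config$wavelet_levels
  if (nrow(patch) %% 2^J != 0 || ncol(patch) %% 2^J != 0)
    stop("mbm_hurst: patch sides must be divisible by 2^J")
  V <- cpp_dwt2_detail_vars(patch, J)
  use <- V > 1e-20 * (1 + mean(patch^2)) # numerically zero bands are degenerate
  if (sum(use) < 2) {
    out <- 1
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  beta <- stats::coef(stats::lm(log2(V[use]) ~ seq_len(J)[use]))[2]
  H <- (unname(beta) - 2) / 2
  out <- min(1, max(0, H))
  attr(out, "degenerate") <- FALSE
  out
}

#' Pointwise Hoelder exponent from local oscillation scaling
#'
#' `osc_r` is the intensity range within the Chebyshev ball of radius `r`
#' around the point; alpha is the least-squares slope of `log(osc_r + eps)`
#' against `log r`. Locally constant neighborhoods return `alpha_cap`.
#'
#' @param volume 3D numeric array.
#' @param point integer length-3 voxel index (1-based), at least `max(radii)`
#'   from every boundary.
#' @param radii integer radii (>= 3 values).
#' @param epsilon stabilizer; @param alpha_cap cap for constant patches.
#' @return Hoelder exponent in `[0, alpha_cap]`.
#' @export
holder_exponent <- function(volume, point, radii = c(1, 2, 3, 4),
                            epsilon = 1e-6, alpha_cap = 2) {
  radii <- as.integer(sort(radii))
  dm <- dim(volume)
  if (any(point - max(radii) < 1) || any(point + max(radii) > dm))
    stop("holder_exponent: point closer than max(radii) to the boundary")
  osc <- vapply(radii, function(r) {
    nb <- volume[(point[1] - r):(point[1] + r),
                 (point[2] - r):(point[2] + r),
                 (point[3] - r):(point[3] + r)]
    max(nb) - min(nb)
  }, 0.0)
  if (all(osc < epsilon)) return(alpha_cap)
  a <- unname(stats::coef(stats::lm(log(osc + epsilon) ~ log(radii)))[2])
  min(alpha_cap, max(0, a))
}

#' Fractal characterization map of a tumor region
#'
#' Slides an axial window over every in-ROI voxel and writes the local
#' estimate (PTPSA fractal dimension, wavelet Hurst exponent, or pointwise
#' Hoelder exponent) at the window center; voxels outside the ROI are zero.
#' Windows reaching past the volume boundary are filled by reflection.
#'
#' @param volume a [volume_image()].
#' @param roi binary 3D array, nonempty.
#' @param kind `"PTPSA"`, `"MBM"` or `"HE"`.
#' @param config a [fractal_map_config()].
#' @return A [volume_image()] tagged with the characterization modality.
#' @export
characterization_map <- function(volume, roi, kind = c("PTPSA", "MBM", "HE"),
                                 config = fractal_map_config()) {
  kind <- match.arg(kind)
  if (sum(roi) == 0) stop("characterization_map: roi is empty")
  dm <- dim(volume$data)
  roi_i <- as.integer(roi != 0)
  v <- as.numeric(volume$data)
  out <- switch(kind,
    PTPSA = cpp_ptpsa_map(v, dm, roi_i, config$window, config$ptpsa_steps),
    MBM = cpp_mbm_map(v, dm, roi_i, config$window, config$wavelet_levels),
    HE = cpp_holder_map(v, dm, roi_i, config$holder_radii,
                        config$epsilon, config$alpha_cap))
  volume_image(array(out, dm), spacing = volume$spacing, modality = kind)
}
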