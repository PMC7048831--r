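#' Equal-width gray-level quantization of an ROI
#'
#' In-mask intensities are binned from their minimum to maximum into `Ng`
#' levels (min maps to 1, max to Ng); voxels outside the mask get level 0.
#' The binning is invariant to affine intensity transforms of the ROI.
#'
#' @param volume a [volume_image()] (or bare 3D array).
#' @param mask binary 3D array, nonempty.
#' @param Ng number of gray levels (>= 2), default 32.
#' @return A `quantized_roi` list with `levels` (integer array), `Ng`,
#'   `source` (modality tag) and `degenerate` (constant ROI).
#' @export
quantize_roi <- function(volume, mask, Ng = 32) {
  dat <- if (inherits(volume, "volume_image")) volume$data else volume
  src <- if (inherits(volume, "volume_image")) volume$modality else "raw"
  if (Ng < 2) stop("quantize_roi: Ng must be >= 2")
  inm <- mask != 0
  if (!any(inm)) stop("quantize_roi: mask is empty")
  x <- dat[inm]
  lo <- min(x); hi <- max(x)
  lev <- array(0L, dim(dat))
  degenerate <- hi <= lo
  if (degenerate) {
    lev[inm] <- 1L
  } else {
    lev[inm] <- pmin(Ng, 1L + as.integer(floor((x - lo) / (hi - lo) * Ng)))
  }
  structure(list(levels = lev, Ng = as.integer(Ng), source = src,
                 degenerate = degenerate),
            class = "quantized_roi")
}

#' Gray-level texture matrices of a quantized ROI
#'
#' Computes the four standard 3D texture-matrix families with out-of-mask
#' neighbors excluded everywhere:
#' * GLCM: symmetric co-occurrence matrix merged over the 13 unique unit
#'   offsets at Chebyshev distance 1, normalized to sum 1;
#' * GLRLM: run-length counts merged over the 13 directions;
#' * GLSZM: 26-connected zone-size counts;
#' * NGTDM: per-level occurrence counts and summed absolute deviation from the
#'   26-neighborhood mean.
#'
#' @param q a [quantize_roi()] result.
#' @return A `texture_matrix_set` list with elements `glcm`, `glrlm`, `glszm`,
#'   `ngtdm` (list `s`, `n`), `n_voxels` and `degenerate`.
#' @export
compute_texture_matrices <- function(q) {
  dm <- dim(q$levels)
  lv <- as.integer(q$levels)
  n_vox <- sum(lv > 0L)
  degenerate <- n_vox < 2L || q$degenerate
  structure(list(glcm = cpp_glcm(lv, dm, q$Ng),
                 glrlm = cpp_glrlm(lv, dm, q$Ng),
                 glszm = cpp_glszm(lv, dm, q$Ng),
                 ngtdm = cpp_ngtdm(lv, dm, q$Ng),
                 n_voxels = n_vox, Ng = q$Ng,
                 degenerate = degenerate),
            class = "texture_matrix_set")
}

glcm_features <- function(P) {
  Ng <- nrow(P)
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(Ng) * px); muy <- sum(seq_len(Ng) * py)
  sx <- sqrt(sum((seq_len(Ng) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(Ng) - muy)^2 * py))
  nz <- P > 0
  ent <- -sum(P[nz] * log2(P[nz]))
  HX <- -sum(px[px > 0] * log2(px[px > 0]))
  HY <- -sum(py[py > 0] * log2(py[py > 0]))
  pxy <- outer(px, py)
  ok <- P > 0
  HXY1 <- -sum(P[ok] * log2(pxy[ok]))
  ok2 <- pxy > 0
  HXY2 <- -sum(pxy[ok2] * log2(pxy[ok2]))
  corr <- if (sx > 0 && sy > 0) sum((i - mux) * (j - muy) * P) / (sx * sy) else 0
  imc1 <- if (max(HX, HY) > 0 && sx > 0 && sy > 0) (ent - HXY1) / max(HX, HY) else 0
  imc2 <- if (sx > 0 && sy > 0) sqrt(max(0, 1 - exp(-2 * (HXY2 - ent)))) else 0
  # sum-average over the diagonal-sum distribution p_{x+y}
  k <- i + j
  sum_avg <- sum(k * P)
  c(energy = sum(P^2),
    contrast = sum((i - j)^2 * P),
    correlation = corr,
    entropy = ent,
    inverse_difference_moment = sum(P / (1 + (i - j)^2)),
    variance = sum((i - mux)^2 * P),
    sum_average = sum_avg,
    dissimilarity = sum(abs(i - j) * P),
    information_correlation1 = imc1,
    information_correlation2 = imc2)
}

# shared form for GLRLM (j = run length) and GLSZM (j = zone size)
rl_features <- function(M, n_vox, prefix) {
  Nr <- sum(M)
  if (Nr == 0) {
    v <- rep(0, 13)
  } else {
    Ng <- nrow(M); Nl <- ncol(M)
    i <- matrix(seq_len(Ng), Ng, Nl); j <- t(matrix(seq_len(Nl), Nl, Ng))
    p <- M / Nr
    mu_i <- sum(i * p); mu_j <- sum(j * p)
    v <- c(sum(M / j^2) / Nr,            # short emphasis
           sum(M * j^2) / Nr,            # long emphasis
           sum(rowSums(M)^2) / Nr,       # gray-level non-uniformity
           sum(colSums(M)^2) / Nr,       # length non-uniformity
           Nr / n_vox,                   # percentage
           sum(M / i^2) / Nr,            # low gray-level emphasis
           sum(M * i^2) / Nr,            # high gray-level emphasis
           sum(M / (i^2 * j^2)) / Nr,    # short low gray-level
           sum(M * i^2 / j^2) / Nr,      # short high gray-level
           sum(M * j^2 / i^2) / Nr,      # long low gray-level
           sum(M * i^2 * j^2) / Nr,      # long high gray-level
           sum(p * (i - mu_i)^2),        # gray-level variance
           sum(p * (j - mu_j)^2))        # length variance
  }
  names(v) <- paste0(prefix, c("e", "e2", "gln", "n2", "p", "lge", "hge",
                               "slge", "shge", "llge", "lhge", "glv", "v2"))
  v
}

ngtdm_features <- function(ng, n_vox) {
  s <- ng$s; ni <- ng$n
  n <- sum(ni)
  eps <- 1e-12
  if (n == 0)
    return(c(coarseness = 0, contrast = 0, busyness = 0, complexity = 0, strength = 0))
  p <- ni / n
  act <- which(p > 0)
  Ngp <- length(act)
  coars <- 1 / (eps + sum(p * s))
  if (Ngp > 1) {
    gij <- outer(act, act, "-")
    pij_w <- outer(p[act], p[act])
    contr <- (sum(pij_w * gij^2) / (Ngp * (Ngp - 1))) * (sum(s) / n)
    busy_den <- sum(abs(outer(act * p[act], act * p[act], "-")))
    busy <- if (busy_den > 0) sum(p * s) / busy_den else 0
    psum <- outer(p[act], p[act], "+")
    pssum <- outer(p[act] * s[act], p[act] * s[act], "+")
    compl <- sum(abs(gij) * pssum / (n * psum))
    strength <- sum(psum * gij^2) / (eps + sum(s))
  } else {
    contr <- 0; busy <- 0; compl <- 0; strength <- 0
  }
  c(coarseness = coars, contrast = contr, busyness = busy,
    complexity = compl, strength = strength)
}

#' The 41-feature texture catalogue
#'
#' Ten GLCM features (energy, contrast, correlation, entropy, inverse
#' difference moment, variance, sum average, dissimilarity, and both
#' information measures of correlation), thirteen GLRLM features, thirteen
#' GLSZM features, and five NGTDM features (coarseness, contrast, busyness,
#' complexity, strength), all by their standard published formulas with
#' logarithms in base 2. Zero-variance matrices set correlation and both
#' information measures to 0.
#'
#' @param m a [compute_texture_matrices()] result.
#' @return Named numeric vector of length 41.
#' @export
texture_feature_vector <- function(m) {
  g <- glcm_features(m$glcm)
  names(g) <- paste0("glcm.", names(g))
  r <- rl_features(m$glrlm, m$n_voxels, "")
  names(r) <- paste0("glrlm.", c("sre", "lre", "gln", "rln", "rp", "lgre",
                                 "hgre", "srlge", "srhge", "lrlge", "lrhge",
                                 "glv", "rlv"))
  z <- rl_features(m$glszm, m$n_voxels, "")
  names(z) <- paste0("glszm.", c("sze", "lze", "gln", "zsn", "zp", "lgze",
                                 "hgze", "szlge", "szhge", "lzlge", "lzhge",
                                 "glv", "zsv"))
  t <- ngtdm_features(m$ngtdm, m$n_voxels)
  names(t) <- paste0("ngtdm.", names(t))
  out <- c(g, r, z, t)
  out[!is.finite(out)] <- 0
  out
}

#' Histogram statistics of an ROI
#'
#' Mean and variance of in-mask intensities, skewness and kurtosis as the
#' standardized third/fourth central moments (kurtosis of a normal is 3, not
#' 0), and energy / entropy of a 64-bin equal-width histogram over the
#' in-mask range (energy = sum of squared bin probabilities, entropy in bits
#' with empty bins skipped). A constant ROI returns variance 0 and
#' skewness/kurtosis 0 by convention, with a `degenerate` attribute.
#'
#' @param volume a [volume_image()] or 3D array.
#' @param mask binary 3D array, nonempty.
#' @param bins histogram bin count (default 64).
#' @return Named numeric vector `mean`, `variance`, `skewness`, `kurtosis`,
#'   `energy`, `entropy`.
#' @export
histogram_stats <- function(volume, mask, bins = 64) {
  dat <- if (inherits(volume, "volume_image")) volume$data else volume
  x <- dat[mask != 0]
  if (length(x) == 0) stop("histogram_stats: mask is empty")
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 <= 0) {
    out <- c(mean = mu, variance = 0, skewness = 0, kurtosis = 0,
             energy = 1, entropy = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  skew <- mean((x - mu)^3) / m2^1.5
  kurt <- mean((x - mu)^4) / m2^2
  br <- seq(min(x), max(x), length.out = bins + 1)
  cnt <- tabulate(pmin(bins, 1L + as.integer(floor((x - min(x)) /
                  (max(x) - min(x)) * bins))), nbins = bins)
  p <- cnt / sum(cnt)
  p <- p[p > 0]
  out <- c(mean = mu, variance = m2, skewness = skew, kurtosis = kurt,
           energy = sum(p^2), entropy = -sum(p * log2(p)))
  attr(out, "degenerate") <- FALSE
  out
}
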