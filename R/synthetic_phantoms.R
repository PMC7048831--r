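#' Phantom geometry and texture specification
#'
#' Defines one synthetic tumor phantom family: an ellipsoidal "brain" carrying
#' a nested-sphere tumor (necrotic core, enhancing shell, edema shell), with
#' per-modality region mean intensities, fractional-Brownian texture whose
#' Hurst exponent depends on the case's class, and additive Gaussian noise.
#'
#' @param grid_size voxels per axis (isotropic grid).
#' @param brain_semi_axes numeric length-3 ellipsoid semi-axes in voxels.
#' @param region_radii numeric length-3 `(r_ncr, r_et, r_ed)` in voxels,
#'   strictly increasing and smaller than the smallest brain semi-axis.
#' @param modality_means matrix (modalities x regions `brain`,`NCR`,`ET`,`ED`)
#'   of mean intensities; default mimics relative T1/T1Gd/T2/FLAIR contrast.
#' @param hurst_by_class named list mapping class (`negative`, `positive`) to
#'   the central tumor-texture Hurst exponent in (0,1); the class effect
#'   spreads the positive class's local H by `effect_hurst` around this
#'   center (see [generate_phantom_case()]). Background brain texture is
#'   fixed at H = 0.5.
#' @param texture_amplitude intensity SD of the fBm texture component.
#' @param noise_sd SD of i.i.d. Gaussian voxel noise.
#' @param seed integer seed for the phantom family.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_size = 64,
                         brain_semi_axes = round(grid_size * c(0.44, 0.40, 0.36)),
                         region_radii = c(4, 6, 10),
                         modality_means = default_modality_means(),
                         hurst_by_class = list(negative = 0.5, positive = 0.5),
                         texture_amplitude = 10,
                         noise_sd = 2,
                         seed = 1L) {
  r <- region_radii
  if (!(r[1] > 0 && r[1] < r[2] && r[2] < r[3] && r[3] < min(brain_semi_axes)))
    stop("phantom_spec: need 0 < r_ncr < r_et < r_ed < min(brain_semi_axes)")
  for (h in unlist(hurst_by_class))
    if (h <= 0 || h >= 1) stop("phantom_spec: Hurst exponents must lie strictly in (0,1)")
  structure(list(grid_size = as.integer(grid_size),
                 brain_semi_axes = as.numeric(brain_semi_axes),
                 region_radii = as.numeric(r),
                 modality_means = modality_means,
                 hurst_by_class = hurst_by_class,
                 texture_amplitude = texture_amplitude,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_modality_means <- function() {
  m <- rbind(T1    = c(brain = 100, NCR = 60,  ET = 90,  ED = 80),
             T1Gd  = c(brain = 100, NCR = 50,  ET = 140, ED = 85),
             T2    = c(brain = 100, NCR = 130, ET = 110, ED = 140),
             FLAIR = c(brain = 100, NCR = 70,  ET = 110, ED = 150))
  m
}

#' Synthetic cohort specification
#'
#' @param n_cases number of cases (>= 4).
#' @param prevalence named vector of positive fractions per target in (0,1).
#' @param effect_hurst half-width of the spatial local-Hurst spread given to
#'   driver-target-positive tumors (their roughness varies across the tumor);
#'   negative cases get the phase-homogenized surrogate texture, so 0 makes
#'   the classes statistically indistinguishable.
#' @param effect_volume multiplicative factor on region radii for positive
#'   cases (1 = no volumetric effect).
#' @param driver_target the molecular target whose class drives texture and
#'   volume effects (other targets are independent labels).
#' @param survival_beta log-hazard per SD of the driver feature (the
#'   standardized mean in-tumor FLAIR intensity of each case).
#' @param baseline_rate baseline exponential event rate per month.
#' @param censor_rate independent exponential censoring rate per month
#'   (0 = no censoring).
#' @param label_mode `"exact"` assigns exactly `round(prevalence * n)`
#'   positives; `"binomial"` draws labels independently.
#' @param seed integer master seed for the cohort.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_cases = 108,
                        prevalence = c(MGMT = 91 / 105, IDH = 85 / 108,
                                       CODEL = 27 / 108, ATRX = 43 / 108,
                                       TERT = 46 / 108),
                        effect_hurst = 0, effect_volume = 1,
                        driver_target = "IDH",
                        survival_beta = 0, baseline_rate = 1 / 60,
                        censor_rate = 1 / 120,
                        label_mode = c("exact", "binomial"),
                        seed = 1L) {
  if (n_cases < 4) stop("cohort_spec: n_cases must be >= 4")
  if (any(prevalence <= 0 | prevalence >= 1))
    stop("cohort_spec: prevalence must lie strictly in (0,1)")
  structure(list(n_cases = as.integer(n_cases), prevalence = prevalence,
                 effect_hurst = effect_hurst, effect_volume = effect_volume,
                 driver_target = driver_target, survival_beta = survival_beta,
                 baseline_rate = baseline_rate, censor_rate = censor_rate,
                 label_mode = match.arg(label_mode), seed = as.integer(seed)),
            class = "cohort_spec")
}

# small deterministic seed substreams, kept below 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 999983 * as.numeric(offset)) %% 2147483647)
}

#' Spectrally synthesized fractional Brownian field
#'
#' Generates a zero-mean, unit-variance random field with isotropic power-law
#' spectrum: Fourier amplitudes proportional to
#' `(||f||^2 + f0^2)^(-(2H + d)/4)` for a d-dimensional grid, with random
#' phases, where the low-frequency regularizer `f0 = 1/max(shape)` removes the
#' DC singularity. Increment scaling follows `E|I(x+d) - I(x)|^2 ~ |d|^(2H)`
#' over small lags.
#'
#' @param shape integer vector (length 2 or 3) of grid dimensions, all >= 8.
#' @param H Hurst exponent, strictly in (0,1).
#' @param seed integer seed; the global RNG stream is left untouched.
#' @return Numeric array of dimension `shape`.
#' @export
generate_fbm_field <- function(shape, H, seed) {
  if (H <= 0 || H >= 1) stop("generate_fbm_field: H must lie strictly in (0,1)")
  if (any(shape < 8)) stop("generate_fbm_field: all dims must be >= 8")
  d <- length(shape)
  freqs <- lapply(shape, function(n) {
    k <- 0:(n - 1); k[k > n / 2] <- k[k > n / 2] - n; k / n
  })
  f2 <- array(0, dim = shape)
  for (ax in seq_len(d)) {
    rs <- rep(1L, d); rs[ax] <- shape[ax]
    f2 <- f2 + array(rep(freqs[[ax]]^2,
                         each = prod(shape[seq_len(ax - 1)])), dim = shape)
  }
  f0 <- 1 / max(shape)
  amp <- (f2 + f0^2)^(-(2 * H + d) / 4)
  field <- withr::with_seed(seed, {
    noise <- array(stats::rnorm(prod(shape)), dim = shape) +
      1i * array(stats::rnorm(prod(shape)), dim = shape)
    Re(stats::fft(amp * noise, inverse = TRUE))
  })
  field <- field - mean(field)
  s <- stats::sd(as.vector(field))
  if (s > 0) field <- field / s
  field
}

#' Amplitude-adjusted phase-randomized surrogate of a field
#'
#' Iteratively enforces the Fourier amplitude spectrum and the marginal value
#' distribution of `target` while randomizing phases; the surrogate shares
#' the second-order statistics and histogram of the original but has
#' spatially homogeneous higher-order structure.
#'
#' @param target numeric array.
#' @param seed integer seed.
#' @param iters number of enforcement iterations.
#' @return Array of the same dimension as `target`.
#' @export
iaaft_surrogate <- function(target, seed, iters = 30) {
  amp <- Mod(stats::fft(target))
  srt <- sort(as.vector(target))
  x <- withr::with_seed(seed, array(sample(as.vector(target)), dim(target)))
  for (it in seq_len(iters)) {
    X <- stats::fft(x)
    x <- Re(stats::fft(amp * exp(1i * Arg(X)), inverse = TRUE)) / length(x)
    x <- array(srt[rank(as.vector(x), ties.method = "first")], dim(x))
  }
  x
}

# intermittent texture: fBm fields of Hurst h_center +/- dh blended through a
# smooth indicator field, standardized to zero mean / unit variance
blend_texture <- function(shape, h_center, dh, seed) {
  h_lo <- min(max(h_center - dh, 0.05), 0.95)
  h_hi <- min(max(h_center + dh, 0.05), 0.95)
  f_lo <- generate_fbm_field(shape, h_lo, derive_seed(seed, 31))
  if (dh == 0) {
    f <- f_lo
  } else {
    f_hi <- generate_fbm_field(shape, h_hi, derive_seed(seed, 37))
    aux <- generate_fbm_field(shape, 0.8, derive_seed(seed, 41))
    w <- 1 / (1 + exp(-aux / 0.15))
    f <- w * f_lo + (1 - w) * f_hi
  }
  f <- f - mean(f)
  s <- stats::sd(as.vector(f))
  if (s > 0) f <- f / s
  f
}

# squared-distance field of nested ellipsoids; returns list of masks
phantom_geometry <- function(grid, semi_axes, radii) {
  ax <- seq_len(grid) - (grid + 1) / 2
  gx <- array(rep(ax, times = grid * grid), dim = rep(grid, 3))
  gy <- array(rep(rep(ax, each = grid), times = grid), dim = rep(grid, 3))
  gz <- array(rep(ax, each = grid * grid), dim = rep(grid, 3))
  brain <- (gx / semi_axes[1])^2 + (gy / semi_axes[2])^2 + (gz / semi_axes[3])^2 <= 1
  rr <- sqrt(gx^2 + gy^2 + gz^2)
  list(brain = brain * 1L,
       NCR = (rr <= radii[1]) * 1L,
       ET = (rr > radii[1] & rr <= radii[2]) * 1L,
       ED = (rr > radii[2] & rr <= radii[3]) * 1L)
}

#' Generate one textured tumor phantom case
#'
#' Builds nested spherical tumor sub-regions (necrotic core, enhancing shell,
#' edema shell) inside an ellipsoidal brain, and fills each raw MRI modality
#' with region mean + fBm texture + Gaussian noise. The tumor texture of a
#' driver-positive case is an intermittent blend of rough and smooth fBm
#' components (local Hurst exponent `H +/- effect_hurst` varying across the
#' tumor); a driver-negative case receives the amplitude-adjusted
#' phase-randomized surrogate of the same construction, which shares its
#' histogram and spectrum but has spatially homogeneous regularity. The class
#' difference therefore lives in the local multi-scale structure that fractal
#' characterizations measure. Brain background texture is fixed at H = 0.5.
#'
#' @param spec a [phantom_spec()].
#' @param class_assignments named character vector target -> class
#'   (`positive`/`negative`); missing targets default to `negative`.
#' @param seed integer seed for this case.
#' @param case_id identifier.
#' @param driver_target target whose class selects the tumor texture.
#' @param effect_hurst half-width of the local Hurst spread in the positive
#'   class (0 = both classes statistically identical).
#' @param effect_volume multiplicative factor on region radii applied when the
#'   driver class is positive.
#' @return A [case_record()].
#' @export
generate_phantom_case <- function(spec, class_assignments = c(IDH = "negative"),
                                  seed = spec$seed, case_id = "phantom",
                                  driver_target = "IDH", effect_hurst = 0,
                                  effect_volume = 1) {
  cls <- class_assignments[[driver_target]]
  if (is.null(cls) || is.na(cls)) cls <- "negative"
  radii <- spec$region_radii
  if (identical(cls, "positive")) radii <- radii * effect_volume
  if (!(radii[3] < min(spec$brain_semi_axes)))
    stop("generate_phantom_case: scaled radii exceed brain ellipsoid")
  g <- phantom_geometry(spec$grid_size, spec$brain_semi_axes, radii)
  WT <- (g$NCR | g$ET | g$ED) * 1L
  labels3d <- g$NCR * 1L + g$ED * 2L + g$ET * 4L
  H_tum <- spec$hurst_by_class[[cls]]
  shape <- rep(spec$grid_size, 3)
  bg <- generate_fbm_field(shape, 0.5, derive_seed(seed, 11))
  tum <- blend_texture(shape, H_tum, effect_hurst, derive_seed(seed, 13))
  if (!identical(cls, "positive") && effect_hurst > 0)
    tum <- iaaft_surrogate(tum, derive_seed(seed, 19))
  images <- list()
  for (k in seq_along(MODALITIES_RAW)) {
    m <- MODALITIES_RAW[k]
    mu <- spec$modality_means[m, ]
    base <- mu["brain"] * g$brain
    base[g$NCR == 1L] <- mu["NCR"]; base[g$ET == 1L] <- mu["ET"]
    base[g$ED == 1L] <- mu["ED"]
    tex <- bg * (1 - WT) + tum * WT
    noise <- withr::with_seed(derive_seed(seed, 17 + k), {
      array(stats::rnorm(prod(shape), sd = spec$noise_sd), dim = shape)
    })
    img <- (base + (spec$texture_amplitude * tex + noise) * g$brain) * g$brain
    images[[m]] <- volume_image(img, modality = m)
  }
  case_record(case_id, images, segmentation_mask(labels3d),
              brain_mask = g$brain, labels = class_assignments)
}

# exact-count or binomial label assignment for one target
draw_labels <- function(n, prev, mode, seed) {
  withr::with_seed(seed, {
    if (mode == "exact") {
      npos <- round(prev * n)
      lab <- c(rep("positive", npos), rep("negative", n - npos))
      sample(lab)
    } else {
      ifelse(stats::rbinom(n, 1, prev) == 1, "positive", "negative")
    }
  })
}

#' Draw exponential survival with a log-linear hazard in a covariate
#'
#' Event times are exponential with rate `baseline_rate * exp(beta * z)` for
#' the standardized covariate `z`; censoring is an independent exponential at
#' `censor_rate` (0 disables censoring).
#'
#' @param z numeric covariate (standardized internally).
#' @param beta log-hazard per SD.
#' @param baseline_rate,censor_rate events per month.
#' @param seed integer seed.
#' @return Data frame with `time`, `event`, `z`.
#' @export
generate_survival <- function(z, beta, baseline_rate, censor_rate, seed) {
  zs <- if (stats::sd(z) > 0) (z - mean(z)) / stats::sd(z) else z * 0
  withr::with_seed(seed, {
    t_death <- stats::rexp(length(z), rate = baseline_rate * exp(beta * zs))
    t_cens <- if (censor_rate > 0) stats::rexp(length(z), rate = censor_rate) else Inf
    data.frame(time = pmin(t_death, t_cens),
               event = as.integer(t_death <= t_cens), z = zs)
  })
}

#' Generate a full synthetic cohort
#'
#' Labels are drawn per target from the configured prevalences; the driver
#' target's class modulates the spatial organization of tumor texture
#' roughness (`effect_hurst`, see [generate_phantom_case()]) and region radii
#' (`effect_volume`); survival times follow a log-linear hazard in the
#' standardized per-case mean in-tumor FLAIR intensity (the driver feature).
#'
#' @param spec a [cohort_spec()].
#' @param phantom a [phantom_spec()].
#' @return A [cohort()]; attribute `driver_feature` holds the per-case driver
#'   values used for survival generation.
#' @export
generate_cohort <- function(spec, phantom = phantom_spec()) {
  n <- spec$n_cases
  labs <- lapply(seq_along(spec$prevalence), function(k) {
    draw_labels(n, spec$prevalence[k], spec$label_mode,
                derive_seed(spec$seed, 100 + k))
  })
  names(labs) <- names(spec$prevalence)
  cases <- vector("list", n)
  driver <- numeric(n)
  for (i in seq_len(n)) {
    cls <- vapply(labs, function(l) l[i], "")
    cs <- generate_phantom_case(phantom, class_assignments = cls,
                                seed = derive_seed(spec$seed, 1000 + i),
                                case_id = sprintf("case%03d", i),
                                driver_target = spec$driver_target,
                                effect_hurst = spec$effect_hurst,
                                effect_volume = spec$effect_volume)
    wt <- derive_region_masks(cs$mask)$WT
    driver[i] <- mean(cs$images$FLAIR$data[wt == 1L])
    cases[[i]] <- cs
  }
  surv <- generate_survival(driver, spec$survival_beta, spec$baseline_rate,
                            spec$censor_rate, derive_seed(spec$seed, 7))
  for (i in seq_len(n)) {
    cases[[i]]$survival_months <- surv$time[i]
    cases[[i]]$event <- surv$event[i]
  }
  co <- cohort(cases)
  attr(co, "driver_feature") <- driver
  co
}
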