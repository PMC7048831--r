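#' Feature extraction configuration
#'
#' @param Ng gray levels for texture quantization.
#' @param map_config a [fractal_map_config()].
#' @param map_source modality from which the characterization maps are
#'   computed in the default catalogue (`"FLAIR"`).
#' @param per_sequence_maps if `TRUE`, PTPSA/MBM/HE maps are computed for each
#'   of T1Gd, T2 and FLAIR (the texture block grows from 246 to 492 features
#'   and the catalogue from 516 to 744, approaching the full ~680-feature
#'   layout; the per-case map histogram block is subsumed by the per-sequence
#'   map texture blocks).
#' @return A `feature_config` list.
#' @export
feature_config <- function(Ng = 32, map_config = fractal_map_config(),
                           map_source = "FLAIR", per_sequence_maps = FALSE) {
  list(Ng = as.integer(Ng), map_config = map_config, map_source = map_source,
       per_sequence_maps = per_sequence_maps)
}

texture_block <- function(vol, wt, Ng, prefix) {
  q <- quantize_roi(vol, wt, Ng)
  f <- texture_feature_vector(compute_texture_matrices(q))
  names(f) <- sprintf("%s.WT.%s", prefix, names(f))
  f
}

hist_block <- function(vol, mask, prefix, region) {
  if (sum(mask) == 0) {
    h <- stats::setNames(rep(0, 6), c("mean", "variance", "skewness",
                                      "kurtosis", "energy", "entropy"))
  } else {
    h <- histogram_stats(vol, mask)
  }
  names(h) <- sprintf("%s.%s.histogram.%s", prefix, region, names(h))
  h
}

#' Assemble the named per-case feature vector
#'
#' Default catalogue (516 features):
#' * 41 texture features on the whole tumor for each of T1Gd, T2, FLAIR and
#'   each characterization map (PTPSA, MBM, HE): 246;
#' * 6 histogram statistics for each sub-region (ED, ET, NCR) on each raw
#'   sequence (T1, T1Gd, T2, FLAIR): 72, plus 6 histogram statistics of each
#'   characterization map on the whole tumor: 18;
#' * 12 volumetric ratio features;
#' * 168 projection shape features.
#'
#' With `per_sequence_maps = TRUE` the three maps are computed per sequence
#' (T1Gd, T2, FLAIR), giving 744 features.
#'
#' Missing sub-regions contribute zeros rather than dropped columns, so the
#' design matrix stays rectangular.
#'
#' @param case a [case_record()].
#' @param config a [feature_config()].
#' @return Named numeric vector (516 or 744 features, all finite).
#' @export
assemble_case_features <- function(case, config = feature_config()) {
  rm_ <- derive_region_masks(case$mask)
  wt <- rm_$WT
  out <- numeric(0)
  tex_sources <- c("T1Gd", "T2", "FLAIR")
  for (m in tex_sources)
    out <- c(out, texture_block(case$images[[m]], wt, config$Ng, m))
  map_sources <- if (config$per_sequence_maps) tex_sources else config$map_source
  for (src in map_sources) {
    for (kind in MODALITIES_MAP) {
      mp <- characterization_map(case$images[[src]], wt, kind, config$map_config)
      prefix <- if (config$per_sequence_maps) paste0(kind, "_", src) else kind
      out <- c(out, texture_block(mp, wt, config$Ng, prefix))
      if (!config$per_sequence_maps)
        out <- c(out, hist_block(mp, wt, prefix, "WT"))
    }
  }
  for (m in MODALITIES_RAW)
    for (reg in c("ED", "ET", "NCR"))
      out <- c(out, hist_block(case$images[[m]], rm_[[reg]], m, reg))
  vf <- volumetric_features(region_volumes(case$mask, case$brain_mask))
  names(vf) <- paste0("mask.volumetric.", VOLUMETRIC_NAMES)
  out <- c(out, vf, shape_feature_block(case$mask))
  bad <- !is.finite(out)
  if (any(bad))
    stop("assemble_case_features: non-finite feature(s): ",
         paste(names(out)[bad], collapse = ", "))
  out
}

#' Cohort feature table
#'
#' @param cohort a [cohort()].
#' @param config a [feature_config()].
#' @param verbose print per-case progress.
#' @return Data frame: rows = cases (rownames = case ids), columns = features.
#' @export
assemble_cohort_features <- function(cohort, config = feature_config(),
                                     verbose = FALSE) {
  rows <- lapply(cohort$cases, function(cs) {
    if (verbose) message("extracting ", cs$case_id)
    assemble_case_features(cs, config)
  })
  nm <- names(rows[[1]])
  for (r in rows)
    if (!identical(names(r), nm))
      stop("assemble_cohort_features: inconsistent feature catalogue across cases")
  tab <- as.data.frame(do.call(rbind, rows))
  rownames(tab) <- vapply(cohort$cases, function(cs) cs$case_id, "")
  tab
}

#' Fractal-derived feature subset
#'
#' Exactly the features whose source is a PTPSA, MBM or HE characterization
#' map (141 of the 516 default features); removing them gives the ablation
#' ("without fractal") design matrix.
#'
#' @param names character vector of feature names.
#' @return The fractal subset of `names`.
#' @export
fractal_feature_subset <- function(names) {
  src <- sub("\\..*$", "", names)
  base <- sub("_.*$", "", src)
  names[base %in% MODALITIES_MAP]
}
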