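#' End-to-end run configuration
#'
#' Single configuration object for the simulate -> extract -> model pipeline.
#' Every stage draws its randomness from named substreams of `master_seed`,
#' and every output file is accompanied by a JSON manifest recording the seed
#' and configuration, so each stage is independently reproducible.
#'
#' @param output_dir directory all stages write into.
#' @param cohort a [cohort_spec()]; @param phantom a [phantom_spec()].
#' @param features a [feature_config()]; @param model a [model_config()].
#' @param targets molecular targets to model.
#' @param master_seed integer master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(output_dir, cohort = cohort_spec(),
                       phantom = phantom_spec(),
                       features = feature_config(), model = model_config(),
                       targets = c("MGMT", "IDH", "CODEL", "ATRX", "TERT"),
                       master_seed = 1L) {
  list(output_dir = output_dir, cohort = cohort, phantom = phantom,
       features = features, model = model, targets = targets,
       master_seed = as.integer(master_seed))
}

write_manifest <- function(config, stage, dir, extra = list()) {
  manifest <- c(list(stage = stage, master_seed = config$master_seed,
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                extra)
  jsonlite::write_json(manifest, file.path(dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Simulate a cohort to disk
#'
#' Writes one directory per case (NIfTI volumes, mask, brain mask), the
#' cohort label/survival table as `cohort.csv`, and a manifest.
#'
#' @param config a [run_config()].
#' @return Invisibly, the generated [cohort()].
#' @export
run_simulate <- function(config) {
  config$cohort$seed <- derive_seed(config$master_seed, 21)
  co <- generate_cohort(config$cohort, config$phantom)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  for (cs in co$cases) write_case(cs, file.path(config$output_dir, cs$case_id))
  write.csv(co$label_table, file.path(config$output_dir, "cohort.csv"),
            row.names = FALSE)
  write_manifest(config, "simulate", config$output_dir,
                 list(n_cases = length(co$cases)))
  invisible(co)
}

#' Extract the cohort feature table to disk
#'
#' Writes `features.csv` (cases x features) plus a sidecar catalogue
#' (`feature_catalogue.csv`: name, source, region, family) and a manifest.
#' A corrupt case directory is logged and skipped; the manifest records any
#' skipped cases.
#'
#' @param config a [run_config()].
#' @param cohort optionally, an in-memory [cohort()] to bypass re-reading.
#' @return Invisibly, the feature table data frame.
#' @export
run_extract <- function(config, cohort = NULL) {
  if (is.null(cohort)) {
    lt <- load_cohort_table(file.path(config$output_dir, "cohort.csv"))
    cases <- list(); skipped <- character(0)
    for (id in lt$case_id) {
      dir <- file.path(config$output_dir, id)
      cs <- tryCatch({
        paths <- as.list(file.path(dir, paste0(MODALITIES_RAW, ".nii.gz")))
        names(paths) <- MODALITIES_RAW
        paths$mask <- file.path(dir, "mask.nii.gz")
        paths$brain_mask <- file.path(dir, "brain_mask.nii.gz")
        read_case(paths, case_id = id)
      }, error = function(e) {
        message("skipping ", id, ": ", conditionMessage(e)); NULL
      })
      if (is.null(cs)) skipped <- c(skipped, id) else cases[[id]] <- cs
    }
    cohort <- cohort(unname(cases))
  } else skipped <- character(0)
  tab <- assemble_cohort_features(cohort, config$features)
  write.csv(cbind(case_id = rownames(tab), tab),
            file.path(config$output_dir, "features.csv"), row.names = FALSE)
  nm <- colnames(tab)
  parts <- strsplit(nm, ".", fixed = TRUE)
  cat_tab <- data.frame(name = nm,
                        source = vapply(parts, `[`, "", 1),
                        region = vapply(parts, `[`, "", 2),
                        family = vapply(parts, `[`, "", 3))
  write.csv(cat_tab, file.path(config$output_dir, "feature_catalogue.csv"),
            row.names = FALSE)
  write_manifest(config, "extract", config$output_dir,
                 list(n_features = ncol(tab), skipped = skipped))
  invisible(tab)
}

#' Run the molecular prediction models to disk
#'
#' For each requested target: repeated-partition runs with and without the
#' fractal features plus their ANOVA comparison; optionally the 3-class
#' IDH/co-deletion model; writes per-repetition results and mean +/- SD
#' summaries as CSV with a manifest. Targets whose labels are entirely
#' missing are skipped with a warning.
#'
#' @param config a [run_config()].
#' @param features optionally, an in-memory feature table.
#' @param multiclass also fit the 3-class IDH/co-deletion model.
#' @return Invisibly, a list of per-target results.
#' @export
run_model <- function(config, features = NULL, multiclass = FALSE) {
  if (is.null(features)) {
    raw <- read.csv(file.path(config$output_dir, "features.csv"),
                    check.names = FALSE, colClasses = c(case_id = "character"))
    features <- raw[, -1, drop = FALSE]
    rownames(features) <- raw$case_id
  }
  lt <- load_cohort_table(file.path(config$output_dir, "cohort.csv"))
  lt <- lt[match(rownames(features), lt$case_id), , drop = FALSE]
  results <- list()
  all_runs <- list(); summaries <- list()
  for (target in config$targets) {
    labs <- lt[[target]]
    if (all(is.na(labs)) || length(unique(stats::na.omit(labs))) < 2) {
      warning("run_model: target ", target, " skipped (insufficient labels)")
      next
    }
    res <- run_repetitions(features, labs, config$model,
                           derive_seed(config$master_seed, match(target, TARGETS)),
                           variant = "both")
    res$anova <- compare_model_runs(
      res$runs$test_auc[res$runs$variant == "with_fractal"],
      res$runs$test_auc[res$runs$variant == "without_fractal"])
    results[[target]] <- res
    ru <- res$runs; ru$target <- target
    all_runs[[target]] <- ru
    sm <- summary(res); sm$target <- target
    summaries[[target]] <- sm
  }
  if (multiclass) {
    labs3 <- ifelse(is.na(lt$IDH) | is.na(lt$CODEL), NA,
             ifelse(lt$IDH == "negative", "IDH_WT",
             ifelse(lt$CODEL == "positive", "IDHmut_codel", "IDHmut_noncodel")))
    results$IDH_CODEL3 <- run_multiclass_repetitions(
      features, labs3, config$model, derive_seed(config$master_seed, 9))
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  if (length(all_runs) > 0) {
    write.csv(do.call(rbind, all_runs),
              file.path(config$output_dir, "model_runs.csv"), row.names = FALSE)
    write.csv(do.call(rbind, summaries),
              file.path(config$output_dir, "model_summary.csv"), row.names = FALSE)
  }
  write_manifest(config, "model", config$output_dir,
                 list(targets = names(results)))
  invisible(results)
}
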