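#' @useDynLib gliofract, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft rnorm rbinom rexp runif sd var median quantile
#'   pf pchisq qnorm predict oneway.test
#' @importFrom utils read.csv write.csv head
NULL

MODALITIES_RAW <- c("T1", "T1Gd", "T2", "FLAIR")
MODALITIES_MAP <- c("PTPSA", "MBM", "HE")
TARGETS <- c("MGMT", "IDH", "CODEL", "ATRX", "TERT")
BRATS_LABELS <- c(0L, 1L, 2L, 4L) # background, NCR/NET, ED, ET

#' 3D scalar image volume
#'
#' A minimal container for a co-registered, skull-stripped MRI volume (or a
#' derived characterization map) on an isotropic grid.
#'
#' @param data 3D numeric array, all dimensions at least 8, all values finite.
#' @param spacing numeric length-3, mm per axis (default 1 mm isotropic).
#' @param modality one of `T1`, `T1Gd`, `T2`, `FLAIR`, `PTPSA`, `MBM`, `HE`.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, spacing = c(1, 1, 1), modality = "T1") {
  if (is.null(dim(data)) || length(dim(data)) != 3)
    stop("volume_image: data must be a 3D array")
  data <- array(as.numeric(data), dim(data)) # plain array, no foreign attributes
  if (any(dim(data) < 8)) stop("volume_image: all dimensions must be >= 8")
  if (any(!is.finite(data))) stop("volume_image: data contains non-finite values")
  if (any(spacing <= 0)) stop("volume_image: spacing must be strictly positive")
  if (!modality %in% c(MODALITIES_RAW, MODALITIES_MAP))
    stop("volume_image: unknown modality '", modality, "'")
  structure(list(data = data, spacing = as.numeric(spacing), modality = modality),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s  %s  spacing %s mm\n", x$modality,
              paste(dim(x$data), collapse = "x"),
              paste(x$spacing, collapse = "x")))
  invisible(x)
}

#' Tumor sub-region segmentation mask
#'
#' Integer label field using the BraTS convention: 0 background,
#' 1 necrosis/non-enhancing tumor (NCR/NET), 2 peritumoral edema (ED),
#' 4 enhancing tumor (ET).
#'
#' @param labels 3D integer array containing only values 0, 1, 2, 4.
#' @return An object of class `segmentation_mask`.
#' @export
segmentation_mask <- function(labels) {
  if (is.null(dim(labels)) || length(dim(labels)) != 3)
    stop("segmentation_mask: labels must be a 3D array")
  labels <- array(as.integer(round(as.numeric(labels))), dim(labels))
  bad <- setdiff(unique(as.vector(labels)), BRATS_LABELS)
  if (length(bad) > 0)
    stop("segmentation_mask: unknown label value(s): ", paste(bad, collapse = ", "))
  structure(list(labels = labels,
                 label_map = c(`0` = "background", `1` = "NCR/NET",
                               `2` = "ED", `4` = "ET")),
            class = "segmentation_mask")
}

#' Single-case record: images, masks, labels, survival
#'
#' @param case_id character scalar.
#' @param images named list of [volume_image], one per raw modality.
#' @param mask a [segmentation_mask].
#' @param brain_mask binary 3D array of skull-stripped brain voxels, or `NULL`
#'   to default to the nonzero voxels of T1 (exact for skull-stripped input).
#' @param labels named character/NA vector over targets
#'   (`MGMT`, `IDH`, `CODEL`, `ATRX`, `TERT`), values `positive`, `negative`
#'   or `NA` (missing).
#' @param survival_months non-negative number or `NA`.
#' @param event 0/1 or `NA`.
#' @return An object of class `case_record`.
#' @export
case_record <- function(case_id, images, mask, brain_mask = NULL,
                        labels = NULL, survival_months = NA_real_, event = NA_integer_) {
  shapes <- lapply(images, function(v) dim(v$data))
  if (length(unique(vapply(shapes, paste, "", collapse = "x"))) != 1)
    stop("case_record: all modality volumes must share one shape (got ",
         paste(unique(vapply(shapes, paste, "", collapse = "x")), collapse = " vs "), ")")
  if (!identical(dim(mask$labels), shapes[[1]]))
    stop("case_record: mask shape differs from image shape")
  if (sum(mask$labels > 0) < 1) stop("case_record: case has no tumor voxels")
  if (is.null(brain_mask)) {
    t1 <- images[[intersect(c("T1", names(images)), names(images))[1]]]
    brain_mask <- (t1$data != 0) * 1L
  }
  if (!identical(dim(brain_mask), shapes[[1]]))
    stop("case_record: brain mask shape differs from image shape")
  lab <- stats::setNames(rep(NA_character_, length(TARGETS)), TARGETS)
  if (!is.null(labels)) lab[names(labels)] <- as.character(labels)
  structure(list(case_id = as.character(case_id), images = images, mask = mask,
                 brain_mask = brain_mask, labels = lab,
                 survival_months = as.numeric(survival_months),
                 event = as.integer(event)),
            class = "case_record")
}

#' Cohort of cases with a molecular label table
#'
#' @param cases list of [case_record]; case ids must be unique.
#' @return An object of class `cohort` with a `label_table` data frame whose
#'   row order matches `cases`.
#' @export
cohort <- function(cases) {
  ids <- vapply(cases, function(cs) cs$case_id, "")
  if (anyDuplicated(ids)) stop("cohort: duplicate case_id")
  lt <- data.frame(case_id = ids, stringsAsFactors = FALSE)
  for (t in TARGETS) lt[[t]] <- vapply(cases, function(cs) cs$labels[[t]], "")
  lt$survival_months <- vapply(cases, function(cs) cs$survival_months, 0.0)
  lt$event <- vapply(cases, function(cs) as.numeric(cs$event), 0.0)
  structure(list(cases = cases, label_table = lt), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d cases\n", length(x$cases)))
  invisible(x)
}

# parse a label token to "positive"/"negative"/NA
parse_label_token <- function(x) {
  x <- trimws(tolower(as.character(x)))
  out <- rep(NA_character_, length(x))
  pos <- x %in% c("positive", "pos", "1", "mutant", "mutated", "methylated",
                  "codeleted", "co-deleted", "yes", "true")
  neg <- x %in% c("negative", "neg", "0", "wt", "wild-type", "wildtype",
                  "unmethylated", "un-methylated", "non-codeleted", "no", "false")
  mis <- is.na(x) | x %in% c("", "na", "nan", "missing", "unknown")
  bad <- !(pos | neg | mis)
  if (any(bad))
    stop("load_cohort_table: unparseable label token(s): ",
         paste(unique(x[bad]), collapse = ", "))
  out[pos] <- "positive"; out[neg] <- "negative"
  out
}

#' Read a case from NIfTI volumes and masks
#'
#' @param paths named list/vector: one path per raw modality (`T1`, `T1Gd`,
#'   `T2`, `FLAIR`), plus `mask` and optionally `brain_mask`.
#' @param labels,survival_months,event forwarded to [case_record()].
#' @param case_id identifier; defaults to the basename of the mask directory.
#' @return A [case_record].
#' @export
read_case <- function(paths, labels = NULL, survival_months = NA_real_,
                      event = NA_integer_, case_id = NULL) {
  paths <- as.list(paths)
  mods <- intersect(MODALITIES_RAW, names(paths))
  if (length(mods) == 0) stop("read_case: no raw modality paths given")
  images <- lapply(mods, function(m) {
    arr <- as.array(RNifti::readNifti(paths[[m]]))
    if (length(dim(arr)) > 3) arr <- array(arr, dim(arr)[1:3])
    volume_image(arr, modality = m)
  })
  names(images) <- mods
  mask <- segmentation_mask(round(as.array(RNifti::readNifti(paths$mask))))
  bm <- NULL
  if (!is.null(paths$brain_mask)) {
    raw <- RNifti::readNifti(paths$brain_mask)
    bm <- array(as.integer(as.numeric(raw) != 0), dim(raw))
  }
  if (is.null(case_id)) case_id <- basename(dirname(paths$mask))
  case_record(case_id, images, mask, brain_mask = bm, labels = labels,
              survival_months = survival_months, event = event)
}

#' Write a case to NIfTI files in a directory
#'
#' @param case a [case_record].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_case <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (m in names(case$images)) {
    p <- file.path(dir, paste0(m, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(case$images[[m]]$data,
                                       pixdim = case$images[[m]]$spacing), p)
    paths[m] <- p
  }
  p <- file.path(dir, "mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(case$mask$labels, datatype = "int16"), p)
  paths["mask"] <- p
  p <- file.path(dir, "brain_mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(case$brain_mask, datatype = "int16"), p)
  paths["brain_mask"] <- p
  invisible(paths)
}

#' Derive binary region masks from a segmentation
#'
#' Whole tumor (WT) is the union of all tumor labels; ED, ET, NCR are the
#' edema, enhancing-tumor and necrosis/non-enhancing labels. Empty regions are
#' returned as all-zero grids.
#'
#' @param mask a [segmentation_mask].
#' @return Named list of binary integer 3D arrays `WT`, `ED`, `ET`, `NCR`.
#' @export
derive_region_masks <- function(mask) {
  l <- mask$labels
  list(WT = (l == 1L | l == 2L | l == 4L) * 1L,
       ED = (l == 2L) * 1L,
       ET = (l == 4L) * 1L,
       NCR = (l == 1L) * 1L)
}

#' Load a cohort label table from CSV
#'
#' Expected columns: `case_id`, one column per molecular target (`MGMT`,
#' `IDH`, `CODEL`, `ATRX`, `TERT`), optionally `survival_months` and `event`.
#' Label tokens are normalized to `positive` / `negative` / `NA`.
#'
#' @param path CSV file path.
#' @return Data frame with normalized labels; attribute `counts` holds the
#'   per-target positive/negative/missing tallies.
#' @export
load_cohort_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = c(case_id = "character"))
  if (nrow(df) == 0) {
    out <- data.frame(case_id = character(0))
    attr(out, "counts") <- NULL
    return(out)
  }
  if (anyDuplicated(df$case_id))
    stop("load_cohort_table: duplicate case_id: ",
         paste(unique(df$case_id[duplicated(df$case_id)]), collapse = ", "))
  for (t in intersect(TARGETS, names(df))) df[[t]] <- parse_label_token(df[[t]])
  counts <- sapply(intersect(TARGETS, names(df)), function(t) {
    c(positive = sum(df[[t]] == "positive", na.rm = TRUE),
      negative = sum(df[[t]] == "negative", na.rm = TRUE),
      missing = sum(is.na(df[[t]])))
  })
  attr(df, "counts") <- counts
  df
}

#' Cases usable for one target (missing labels excluded)
#'
#' @param label_table data frame as returned by [load_cohort_table()] or the
#'   `label_table` of a [cohort].
#' @param target one of the molecular targets.
#' @return Data frame restricted to labeled cases for `target`.
#' @export
labeled_cases <- function(label_table, target) {
  stopifnot(target %in% names(label_table))
  label_table[!is.na(label_table[[target]]), , drop = FALSE]
}
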