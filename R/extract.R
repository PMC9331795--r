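#' Extract the full radiomic feature vector for one patient-week
#'
#' Computes the 104 features (12 shape + 17 first-order + 75 second-order)
#' for each of the two ROIs (CTV and PG) on one image, returning the
#' 208-entry vector in registry order with registry ids
#' (`"{roi}_{family}_{name}"`). Any ROI failure aborts the patient-week with
#' an error naming the ROI.
#'
#' @param image numeric 3D intensity array.
#' @param ctv,pg logical 3D masks on the image grid.
#' @param spacing_mm per-axis voxel spacing in mm.
#' @param settings list from [extraction_settings()].
#' @return Named numeric vector of length 208 with attributes `flags`
#'   (degenerate-fallback feature ids) and `settings`.
#' @export
extract_all <- function(image, ctv, pg, spacing_mm = c(1, 1, 1),
                        settings = extraction_settings()) {
  rois <- list(CTV = ctv, PG = pg)
  out <- numeric(0)
  flags <- character(0)
  for (roi in names(rois)) {
    v <- tryCatch(
      extract_roi(image, rois[[roi]], spacing_mm, settings),
      error = function(e) stop(sprintf("ROI %s: %s", roi, conditionMessage(e)),
                               call. = FALSE))
    ids <- paste(roi, names(v), sep = "_")
    fl <- attr(v, "flags")
    if (length(fl)) flags <- c(flags, paste(roi, fl, sep = "_"))
    out <- c(out, stats::setNames(as.numeric(v), ids))
  }
  reg <- feature_registry()
  if (!identical(names(out), reg$id))
    stop("internal error: extracted ids do not match the registry")
  attr(out, "flags") <- flags
  attr(out, "settings") <- settings
  out
}

## 104 features for a single ROI; names are "{family}_{name}".
extract_roi <- function(image, mask, spacing_mm, settings) {
  mask <- array(as.logical(mask), dim(mask))
  if (!identical(dim(image), dim(mask)))
    stop("mask grid does not match image grid")
  if (!any(mask)) stop("mask is empty")
  sh <- shape_features(mask, spacing_mm)
  fo <- first_order_features(image, mask, spacing_mm, settings)
  q <- quantize(image, mask, settings, spacing_mm)
  so <- second_order_features(texture_matrices(q, settings))
  v <- c(stats::setNames(as.numeric(sh), paste0("shape_", names(sh))),
         stats::setNames(as.numeric(fo), paste0("firstorder_", names(fo))),
         as.numeric(so) |> stats::setNames(names(so)))
  flags <- c(if (length(attr(sh, "flags")))
               paste0("shape_", attr(sh, "flags")),
             if (length(attr(fo, "flags")))
               paste0("firstorder_", attr(fo, "flags")),
             attr(so, "flags"))
  attr(v, "flags") <- flags
  v
}

#' Extract features for every patient and week of a cohort
#'
#' @param cohort list of `patient_timeline` objects (see [simulate_cohort()]
#'   or [read_cohort_nifti()]).
#' @param settings list from [extraction_settings()].
#' @param weeks integer vector of weeks to extract; default all available.
#' @return A `cohort_features` object: list with `features` (list by patient
#'   of lists by week of 208-vectors), `patient_id`, `true_class` (NA when
#'   unknown), `weeks`, `settings`.
#' @export
extract_cohort_features <- function(cohort, settings = extraction_settings(),
                                    weeks = NULL) {
  stopifnot(length(cohort) > 0)
  weeks <- weeks %||% seq_along(cohort[[1]]$weeks)
  feats <- lapply(cohort, function(pt) {
    wl <- lapply(weeks, function(w) {
      rec <- pt$weeks[[w]]
      if (is.null(rec))
        stop(sprintf("patient %s: missing week %d", pt$patient_id, w))
      extract_all(rec$image, rec$ctv, rec$pg, pt$spacing_mm, settings)
    })
    names(wl) <- as.character(weeks)
    wl
  })
  structure(list(
    features = feats,
    patient_id = vapply(cohort, function(p) p$patient_id, character(1)),
    true_class = vapply(cohort, function(p)
      as.integer(p$true_class %||% NA_integer_), integer(1)),
    weeks = weeks, settings = settings
  ), class = "cohort_features")
}
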