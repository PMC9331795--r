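#' Radiomic feature registry
#'
#' The fixed inventory of the 104 features computed per region of interest
#' (ROI): 12 shape, 17 first-order and 75 second-order features, the latter
#' split into 14 GLDM, 24 GLCM, 16 GLRLM, 16 GLSZM and 5 NGTDM features.
#' Feature ids are `"{roi}_{family}_{name}"` so the 208-column per-patient
#' table (104 features x 2 ROIs) is unambiguous and column order is stable
#' across every stage of the pipeline.
#'
#' @param rois character vector of ROI labels; default `c("CTV", "PG")`.
#' @return A data.frame with columns `id`, `roi`, `family`, `name`, one row
#'   per feature, in canonical (registry) order.
#' @examples
#' reg <- feature_registry()
#' nrow(reg)            # 208
#' table(reg$family)[1] # per-family counts
#' @export
feature_registry <- function(rois = c("CTV", "PG")) {
  fam <- family_feature_names()
  one_roi <- do.call(rbind, lapply(names(fam), function(f) {
    data.frame(family = f, name = fam[[f]], stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, lapply(rois, function(r) {
    cbind(data.frame(roi = r, stringsAsFactors = FALSE), one_roi)
  }))
  out$id <- paste(out$roi, out$family, out$name, sep = "_")
  out[, c("id", "roi", "family", "name")]
}

## Canonical per-family feature names, in registry order.
family_feature_names <- function() {
  list(
    shape = c(
      "MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
      "Sphericity", "Maximum3DDiameter", "MajorAxisLength", "MinorAxisLength",
      "LeastAxisLength", "Elongation", "Flatness", "Maximum2DDiameterSlice"),
    firstorder = c(
      "Energy", "TotalEnergy", "Entropy", "Minimum", "Percentile10",
      "Percentile90", "Maximum", "Mean", "Median", "InterquartileRange",
      "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
      "RootMeanSquared", "Skewness", "Kurtosis", "Variance"),
    gldm = c(
      "SmallDependenceEmphasis", "LargeDependenceEmphasis",
      "GrayLevelNonUniformity", "DependenceNonUniformity",
      "DependenceNonUniformityNormalized", "GrayLevelVariance",
      "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
      "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
      "SmallDependenceHighGrayLevelEmphasis",
      "LargeDependenceLowGrayLevelEmphasis",
      "LargeDependenceHighGrayLevelEmphasis"),
    glcm = c(
      "Autocorrelation", "ClusterProminence", "ClusterShade",
      "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
      "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn", "Idn",
      "Imc1", "Imc2", "InverseVariance", "JointAverage", "JointEnergy",
      "JointEntropy", "MaximumProbability", "MCC", "SumAverage",
      "SumEntropy", "SumSquares"),
    glrlm = c(
      "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
      "RunLengthNonUniformityNormalized", "RunPercentage",
      "GrayLevelVariance", "RunVariance", "RunEntropy",
      "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
      "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
      "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis"),
    glszm = c(
      "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
      "SizeZoneNonUniformityNormalized", "ZonePercentage",
      "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
      "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
      "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
      "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis"),
    ngtdm = c(
      "Coarseness", "Contrast", "Busyness", "Complexity", "Strength")
  )
}

#' Default extraction settings
#'
#' Discretization and texture-matrix settings used throughout the pipeline.
#' CBCT gray values are not calibrated Hounsfield units, so the discretization
#' is always explicit: by default a fixed bin width of 25 intensity units
#' (set `n_bins` to a positive integer to switch to fixed-bin-count mode).
#' Texture matrices use voxel distance 1, the 13 unique 3D directions for
#' GLCM/GLRLM (features averaged over directions), 26-connectivity for GLSZM
#' zones, and GLDM dependence tolerance `alpha = 0`.
#'
#' @param bin_width fixed bin width in intensity units (ignored when `n_bins`
#'   is given).
#' @param n_bins optional fixed number of gray-level bins.
#' @param distance neighbourhood distance in voxels for GLCM/GLDM/NGTDM.
#' @param gldm_alpha gray-level difference tolerance for GLDM dependence.
#' @param connectivity zone connectivity for GLSZM, 6 or 26.
#' @return A list of settings, used by [extract_all()] and the matrix
#'   constructors.
#' @export
extraction_settings <- function(bin_width = 25, n_bins = NULL, distance = 1L,
                                gldm_alpha = 0, connectivity = 26L) {
  stopifnot(is.null(n_bins) || n_bins >= 1, distance >= 1,
            connectivity %in% c(6L, 26L), gldm_alpha >= 0)
  if (is.null(n_bins) && (!is.numeric(bin_width) || bin_width <= 0))
    stop("bin_width must be positive")
  list(bin_width = bin_width, n_bins = n_bins, distance = as.integer(distance),
       gldm_alpha = gldm_alpha, connectivity = as.integer(connectivity))
}
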