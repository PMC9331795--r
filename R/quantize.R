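#' Discretize a masked 3D image into gray levels
#'
#' Bins in-mask intensities into integer gray levels 1..Ng. In the default
#' fixed-bin-width mode, bin edges are anchored at multiples of the bin width
#' (level 1 is the bin containing the in-mask minimum and Ng the index of the
#' bin containing the maximum), so a constant region always maps to a single
#' level. Empty interior bins between 1 and Ng are retained, not compacted,
#' because level arithmetic in the GLCM marginals and NGTDM depends on level
#' spacing. Voxels outside the mask carry no level (NA).
#'
#' @param image numeric 3D array of intensities.
#' @param mask logical (or 0/1) 3D array on the same grid.
#' @param settings list from [extraction_settings()].
#' @param spacing_mm per-axis voxel spacing in mm (carried through for
#'   downstream consumers).
#' @return An object of class `quantized_volume`: list with `levels` (integer
#'   array, NA outside the mask), `Ng`, `mask`, `spacing_mm`, `settings`.
#' @examples
#' img <- array(rep(0:99, length.out = 125), c(5, 5, 5))
#' q <- quantize(img, array(TRUE, c(5, 5, 5)), extraction_settings(bin_width = 25))
#' q$Ng  # 4
#' @export
quantize <- function(image, mask, settings = extraction_settings(),
                     spacing_mm = c(1, 1, 1)) {
  mask <- array(as.logical(mask), dim(mask))
  if (!identical(dim(image), dim(mask)))
    stop("image and mask must share the same grid")
  if (!any(mask)) stop("mask is empty")
  vals <- image[mask]
  if (anyNA(vals)) stop("NA intensities inside the mask")
  if (!is.null(settings$n_bins)) {
    nb <- as.integer(settings$n_bins)
    rng <- range(vals)
    if (rng[2] == rng[1]) {
      lev <- rep(1L, length(vals))
      Ng <- 1L
    } else {
      w <- (rng[2] - rng[1]) / nb
      lev <- pmin(as.integer(floor((vals - rng[1]) / w)) + 1L, nb)
      Ng <- nb
    }
  } else {
    w <- settings$bin_width
    if (!is.numeric(w) || w <= 0) stop("bin width must be positive")
    base <- floor(min(vals) / w)
    lev <- as.integer(floor(vals / w) - base) + 1L
    Ng <- max(lev)
  }
  levels <- array(NA_integer_, dim(image))
  levels[mask] <- lev
  structure(list(levels = levels, Ng = Ng, mask = mask,
                 spacing_mm = spacing_mm, settings = settings),
            class = "quantized_volume")
}
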