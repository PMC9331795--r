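#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cor.test oneway.test rnorm runif quantile sd median
#'   predict var
#' @importFrom utils read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Linear index of voxel coordinates (n x 3 integer matrix) in an array of
## dimension `dm` (column-major, 1-based).
lin_index <- function(coords, dm) {
  coords[, 1L] + (coords[, 2L] - 1L) * dm[1L] +
    (coords[, 3L] - 1L) * dm[1L] * dm[2L]
}

in_bounds <- function(coords, dm) {
  coords[, 1L] >= 1L & coords[, 1L] <= dm[1L] &
    coords[, 2L] >= 1L & coords[, 2L] <= dm[2L] &
    coords[, 3L] >= 1L & coords[, 3L] <= dm[3L]
}

## Voxel coordinates (n x 3) of TRUE entries in a logical 3D array.
mask_coords <- function(mask) {
  w <- which(mask)
  dm <- dim(mask)
  k <- w - 1L
  x <- k %% dm[1L]
  k <- k %/% dm[1L]
  y <- k %% dm[2L]
  z <- k %/% dm[2L]
  cbind(x + 1L, y + 1L, z + 1L)
}

## The 13 unique 3D direction offsets (one representative per +/- pair),
## used for GLCM and GLRLM at voxel distance 1.
offsets13 <- function() {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] == 0), ]
  ## keep one of each +/- pair: first nonzero component positive
  keep <- apply(offs, 1, function(d) {
    nz <- d[d != 0]
    nz[length(nz)] > 0  # last nonzero positive -> unique half-space
  })
  unname(offs[keep, , drop = FALSE])
}

## All 26 neighbour offsets (Chebyshev distance 1).
offsets26 <- function() {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  unname(offs[!(offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] == 0), ,
              drop = FALSE])
}

## For a direction offset `d`, linear indices of all voxels v such that v + d
## is also inside the grid; returns list(from, to) of linear indices.
pair_indices <- function(dm, d) {
  lo <- pmax(1L, 1L - d)
  hi <- pmin(dm, dm - d)
  if (any(lo > hi)) return(list(from = integer(0), to = integer(0)))
  xr <- lo[1L]:hi[1L]; yr <- lo[2L]:hi[2L]; zr <- lo[3L]:hi[3L]
  from <- as.vector(outer(outer(xr, (yr - 1L) * dm[1L], `+`),
                          (zr - 1L) * dm[1L] * dm[2L], `+`))
  dlin <- d[1L] + d[2L] * dm[1L] + d[3L] * dm[1L] * dm[2L]
  list(from = from, to = from + dlin)
}

## Replace non-finite entries by a fallback value, recording which names were
## substituted; returns the vector with a "flags" attribute.
sanitize_features <- function(x, fallbacks = NULL) {
  flags <- character(0)
  if (!is.null(fallbacks)) {
    for (nm in names(fallbacks)) {
      if (nm %in% names(x) && !is.finite(x[[nm]])) {
        x[[nm]] <- fallbacks[[nm]]
        flags <- c(flags, nm)
      }
    }
  }
  bad <- !is.finite(x)
  if (any(bad)) {
    flags <- c(flags, names(x)[bad])
    x[bad] <- 0
  }
  attr(x, "flags") <- unique(flags)
  x
}

## xlogx with the 0 log 0 = 0 convention, base 2.
xlog2x <- function(p) ifelse(p > 0, p * log2(p), 0)

## Maximum pairwise Euclidean distance between rows of a coordinate matrix,
## computed in blocks to bound memory.
max_pairwise_dist <- function(pts, block = 2000L) {
  n <- nrow(pts)
  if (n < 2L) return(0)
  sq <- rowSums(pts^2)
  best <- 0
  starts <- seq(1L, n, by = block)
  for (a in starts) {
    ia <- a:min(n, a + block - 1L)
    for (b in starts) {
      if (b < a) next
      ib <- b:min(n, b + block - 1L)
      d2 <- outer(sq[ia], sq[ib], `+`) - 2 * tcrossprod(pts[ia, , drop = FALSE],
                                                        pts[ib, , drop = FALSE])
      m <- max(d2)
      if (m > best) best <- m
    }
  }
  sqrt(max(best, 0))
}
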