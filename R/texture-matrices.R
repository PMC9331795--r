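#' Gray level co-occurrence matrices (GLCM)
#'
#' Counts in-mask voxel pairs of gray levels at a fixed voxel distance along
#' each of the 13 unique 3D direction offsets. Each direction's matrix is
#' symmetrized (both orderings of every pair are counted) and normalized to
#' sum to 1. Directions without a single valid in-mask pair are recorded in
#' `errors` and omitted from the stack.
#'
#' @param q a `quantized_volume` from [quantize()].
#' @param distance pair distance in voxels (offsets are scaled by it).
#' @param directions integer matrix of direction offsets (rows), default the
#'   13 unique 3D offsets.
#' @return Object of class `glcm_stack`: list with `matrices` (list of Ng x Ng
#'   probability matrices, one per retained direction), `directions`, `Ng`,
#'   `errors`.
#' @export
glcm <- function(q, distance = 1L, directions = offsets13()) {
  stopifnot(inherits(q, "quantized_volume"), distance >= 1)
  dm <- dim(q$levels)
  Ng <- q$Ng
  lev <- q$levels
  mats <- list()
  errs <- character(0)
  for (k in seq_len(nrow(directions))) {
    d <- directions[k, ] * as.integer(distance)
    pr <- pair_indices(dm, d)
    a <- lev[pr$from]; b <- lev[pr$to]
    keep <- !is.na(a) & !is.na(b)
    if (!any(keep)) {
      errs <- c(errs, sprintf("no valid pair for direction (%d,%d,%d)",
                              d[1], d[2], d[3]))
      next
    }
    counts <- tabulate((b[keep] - 1L) * Ng + a[keep], nbins = Ng * Ng)
    M <- matrix(counts, Ng, Ng)
    M <- M + t(M)
    mats[[length(mats) + 1L]] <- M / sum(M)
  }
  if (length(mats) == 0L) stop("no direction produced a valid GLCM")
  structure(list(matrices = mats, directions = directions, Ng = Ng,
                 errors = errs),
            class = "glcm_stack")
}

#' Gray level run length matrices (GLRLM)
#'
#' For each of the 13 unique 3D directions, counts maximal runs of identical
#' gray level along that direction, restricted to the mask. Every in-mask
#' voxel belongs to exactly one run per direction, so
#' `sum(j * P(i, j | theta))` equals the in-mask voxel count for every
#' direction.
#'
#' @inheritParams glcm
#' @return Object of class `glrlm_stack`: list with `matrices` (list of
#'   Ng x maxRunLength count matrices), `Nr` (total runs per direction),
#'   `directions`, `Ng`.
#' @export
glrlm <- function(q, directions = offsets13()) {
  stopifnot(inherits(q, "quantized_volume"))
  dm <- dim(q$levels)
  Ng <- q$Ng
  lev <- q$levels
  co <- mask_coords(q$mask)
  cur_lin <- lin_index(co, dm)
  cur_lev <- lev[cur_lin]
  mats <- list()
  for (k in seq_len(nrow(directions))) {
    d <- directions[k, ]
    prev <- sweep(co, 2L, d)
    ok <- in_bounds(prev, dm)
    prev_same <- logical(nrow(co))
    if (any(ok)) {
      pl <- lev[lin_index(prev[ok, , drop = FALSE], dm)]
      prev_same[ok] <- !is.na(pl) & pl == cur_lev[ok]
    }
    starts <- co[!prev_same, , drop = FALSE]
    slev <- cur_lev[!prev_same]
    ns <- nrow(starts)
    len <- rep(1L, ns)
    active <- seq_len(ns)
    pos <- starts
    while (length(active) > 0L) {
      nxt <- sweep(pos[active, , drop = FALSE], 2L, d, `+`)
      okb <- in_bounds(nxt, dm)
      same <- logical(length(active))
      if (any(okb)) {
        nl <- lev[lin_index(nxt[okb, , drop = FALSE], dm)]
        same[okb] <- !is.na(nl) & nl == slev[active[okb]]
      }
      active <- active[same]
      if (length(active) == 0L) break
      len[active] <- len[active] + 1L
      pos[active, ] <- nxt[same, , drop = FALSE]
    }
    maxj <- max(len)
    counts <- tabulate((len - 1L) * Ng + slev, nbins = Ng * maxj)
    mats[[k]] <- matrix(counts, Ng, maxj)
  }
  structure(list(matrices = mats, Nr = vapply(mats, sum, numeric(1)),
                 directions = directions, Ng = Ng),
            class = "glrlm_stack")
}

#' Gray level size zone matrix (GLSZM)
#'
#' Zones are connected components (default 26-connectivity) of in-mask voxels
#' sharing the same gray level; `P(i, j)` counts zones of level i and size j.
#' `sum(j * P(i, j))` equals the in-mask voxel count.
#'
#' @inheritParams glcm
#' @param connectivity 6 or 26.
#' @return Object of class `glszm_matrix`: list with `P` (Ng x maxZoneSize
#'   count matrix), `Nz` (total zones), `Np` (in-mask voxels), `Ng`.
#' @export
glszm <- function(q, connectivity = 26L) {
  stopifnot(inherits(q, "quantized_volume"), connectivity %in% c(6L, 26L))
  dm <- dim(q$levels)
  Ng <- q$Ng
  lev <- q$levels
  co <- mask_coords(q$mask)
  n <- nrow(co)
  vox_lin <- lin_index(co, dm)
  id_of <- integer(prod(dm))
  id_of[vox_lin] <- seq_len(n)
  offs <- if (connectivity == 26L) offsets13() else
    matrix(c(1L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 1L), 3, 3, byrow = TRUE)
  cur_lev <- lev[vox_lin]
  eFrom <- integer(0); eTo <- integer(0)
  for (k in seq_len(nrow(offs))) {
    d <- offs[k, ]
    nb <- sweep(co, 2L, d, `+`)
    ok <- in_bounds(nb, dm)
    if (!any(ok)) next
    nbl <- lin_index(nb[ok, , drop = FALSE], dm)
    nid <- id_of[nbl]
    valid <- nid > 0L
    a <- which(ok)[valid]
    b <- nid[valid]
    same <- cur_lev[a] == cur_lev[b]
    eFrom <- c(eFrom, a[same]); eTo <- c(eTo, b[same])
  }
  if (length(eFrom) > 0L) {
    g <- igraph::make_graph(rbind(eFrom, eTo), n = n, directed = FALSE)
    comp <- igraph::components(g)
    membership <- comp$membership
  } else {
    membership <- seq_len(n)
  }
  zl <- vapply(split(cur_lev, membership), `[`, integer(1), 1L)
  zs <- tabulate(membership)
  zs <- zs[zs > 0L]
  maxj <- max(zs)
  counts <- tabulate((zs - 1L) * Ng + zl, nbins = Ng * maxj)
  structure(list(P = matrix(counts, Ng, maxj), Nz = length(zs), Np = n,
                 Ng = Ng),
            class = "glszm_matrix")
}

#' Gray level dependence matrix (GLDM)
#'
#' For every in-mask voxel, the dependence is the number of in-mask neighbours
#' within Chebyshev distance `distance` whose gray level differs from the
#' centre by at most `alpha`. `P(i, j)` counts voxels of level i with
#' dependence j - 1 (the `+1` keeps the size index positive so that
#' small-dependence emphasis terms are defined); `sum(P)` equals the in-mask
#' voxel count.
#'
#' @inheritParams glcm
#' @param alpha gray-level difference tolerance.
#' @return Object of class `gldm_matrix`: list with `P` (Ng x maxDependence
#'   count matrix), `Nz` (in-mask voxels), `Ng`.
#' @export
gldm <- function(q, alpha = 0, distance = 1L) {
  stopifnot(inherits(q, "quantized_volume"), distance >= 1)
  dm <- dim(q$levels)
  Ng <- q$Ng
  lev <- q$levels
  co <- mask_coords(q$mask)
  vox_lin <- lin_index(co, dm)
  cur_lev <- lev[vox_lin]
  dep <- integer(nrow(co))
  offs <- neighbour_offsets(as.integer(distance))
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(co, 2L, offs[k, ], `+`)
    ok <- in_bounds(nb, dm)
    if (!any(ok)) next
    nl <- lev[lin_index(nb[ok, , drop = FALSE], dm)]
    hit <- !is.na(nl) & abs(nl - cur_lev[ok]) <= alpha
    dep[ok] <- dep[ok] + as.integer(hit)
  }
  j <- dep + 1L
  maxj <- max(j)
  counts <- tabulate((j - 1L) * Ng + cur_lev, nbins = Ng * maxj)
  structure(list(P = matrix(counts, Ng, maxj), Nz = nrow(co), Ng = Ng),
            class = "gldm_matrix")
}

#' Neighbouring gray tone difference matrix (NGTDM)
#'
#' For each gray level i: `n_i` counts in-mask voxels of level i, `p_i` their
#' proportion, and `s_i` the summed absolute difference between i and the mean
#' level of each such voxel's in-mask neighbours (within Chebyshev distance
#' `distance`). A voxel with no in-mask neighbour contributes 0 to `s_i` but
#' is still counted in `n_i`, so `sum(n_i)` equals the in-mask voxel count.
#'
#' @inheritParams gldm
#' @return Object of class `ngtdm_matrix`: list with `n`, `p`, `s` (length-Ng
#'   vectors), `Np`, `Ng`.
#' @export
ngtdm <- function(q, distance = 1L) {
  stopifnot(inherits(q, "quantized_volume"), distance >= 1)
  dm <- dim(q$levels)
  Ng <- q$Ng
  lev <- q$levels
  co <- mask_coords(q$mask)
  vox_lin <- lin_index(co, dm)
  cur_lev <- lev[vox_lin]
  nsum <- numeric(nrow(co))
  ncnt <- integer(nrow(co))
  offs <- neighbour_offsets(as.integer(distance))
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(co, 2L, offs[k, ], `+`)
    ok <- in_bounds(nb, dm)
    if (!any(ok)) next
    nl <- lev[lin_index(nb[ok, , drop = FALSE], dm)]
    hit <- !is.na(nl)
    idx <- which(ok)[hit]
    nsum[idx] <- nsum[idx] + nl[hit]
    ncnt[idx] <- ncnt[idx] + 1L
  }
  diffv <- numeric(nrow(co))
  has <- ncnt > 0L
  diffv[has] <- abs(cur_lev[has] - nsum[has] / ncnt[has])
  n_i <- tabulate(cur_lev, nbins = Ng)
  s_i <- vapply(seq_len(Ng), function(i) sum(diffv[cur_lev == i]), numeric(1))
  structure(list(n = n_i, p = n_i / sum(n_i), s = s_i, Np = nrow(co),
                 Ng = Ng),
            class = "ngtdm_matrix")
}

## neighbour offsets within Chebyshev distance `d` (excluding the centre)
neighbour_offsets <- function(d) {
  offs <- as.matrix(expand.grid(dx = -d:d, dy = -d:d, dz = -d:d))
  unname(offs[rowSums(offs != 0L) > 0L, , drop = FALSE])
}

#' Build all five texture-matrix families for one ROI
#'
#' @param q a `quantized_volume`.
#' @param settings list from [extraction_settings()].
#' @return A list of class `texture_matrices` with elements `glcm`, `glrlm`,
#'   `glszm`, `gldm`, `ngtdm` and the voxel count `Np`.
#' @export
texture_matrices <- function(q, settings = extraction_settings()) {
  structure(list(
    glcm  = glcm(q, distance = settings$distance),
    glrlm = glrlm(q),
    glszm = glszm(q, connectivity = settings$connectivity),
    gldm  = gldm(q, alpha = settings$gldm_alpha, distance = settings$distance),
    ngtdm = ngtdm(q, distance = settings$distance),
    Np = sum(q$mask), Ng = q$Ng
  ), class = "texture_matrices")
}

#' Dump a texture matrix family to CSV for inspection
#'
#' @param m one of the matrix objects produced by [glcm()], [glrlm()],
#'   [glszm()], [gldm()] or [ngtdm()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  if (inherits(m, "glcm_stack") || inherits(m, "glrlm_stack")) {
    out <- do.call(rbind, lapply(seq_along(m$matrices), function(k) {
      M <- m$matrices[[k]]
      data.frame(direction = k,
                 i = rep(seq_len(nrow(M)), ncol(M)),
                 j = rep(seq_len(ncol(M)), each = nrow(M)),
                 value = as.vector(M))
    }))
  } else if (inherits(m, "ngtdm_matrix")) {
    out <- data.frame(i = seq_len(m$Ng), n = m$n, p = m$p, s = m$s)
  } else {
    M <- m$P
    out <- data.frame(i = rep(seq_len(nrow(M)), ncol(M)),
                      j = rep(seq_len(ncol(M)), each = nrow(M)),
                      value = as.vector(M))
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
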