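#' Configuration for the synthetic longitudinal cohort generator
#'
#' The generator emulates a weekly CBCT cohort of head-and-neck patients: a
#' CTV-like ellipsoidal ROI and a two-lobe parotid-gland ROI carved into a
#' smooth background volume, with class-dependent volume trajectories
#' (Class 1 exceeds a >20 % volume change by week 4, Class 2 stays below)
#' and class-dependent interior texture drift from week 2 onward. Intensity
#' units are arbitrary (CBCT gray values are not calibrated HU), which is why
#' discretization settings are always explicit downstream.
#'
#' A null regime is supported for calibration experiments: when the two
#' volume drops are equal (and below the threshold), class labels are still
#' drawn but carry no volumetric signal; combined with
#' `texture_effect_size = 0` the cohort is entirely effect-free.
#'
#' @param n_patients cohort size.
#' @param class1_fraction proportion of Class-1 (significant change)
#'   patients; the default reproduces a 19/40 (~48 %) split.
#' @param weeks number of weekly acquisitions including the baseline
#'   (minimum 5).
#' @param grid_shape voxels per axis.
#' @param spacing_mm per-axis voxel spacing in mm.
#' @param class1_volume_drop mean fractional CTV volume loss reached by
#'   week 4 for Class 1 (> 0.20).
#' @param class2_volume_drop same for Class 2 (< 0.20), or equal to
#'   `class1_volume_drop` for the null regime.
#' @param texture_effect_size standardized magnitude of the class-dependent
#'   texture drift (0 disables it).
#' @param noise_sd intensity noise standard deviation (arbitrary units).
#' @param n_informative number of planted informative columns in
#'   feature-table mode.
#' @param seed integer seed; the same config yields bit-identical cohorts.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_patients = 40L, class1_fraction = 19 / 40,
                       weeks = 5L, grid_shape = c(36L, 36L, 24L),
                       spacing_mm = c(2, 2, 3), class1_volume_drop = 0.35,
                       class2_volume_drop = 0.08, texture_effect_size = 1,
                       noise_sd = 20, n_informative = 19L, seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              class1_fraction = class1_fraction, weeks = as.integer(weeks),
              grid_shape = as.integer(grid_shape), spacing_mm = spacing_mm,
              class1_volume_drop = class1_volume_drop,
              class2_volume_drop = class2_volume_drop,
              texture_effect_size = texture_effect_size,
              noise_sd = noise_sd, n_informative = as.integer(n_informative),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_patients < 4) stop("n_patients must be at least 4")
  if (cfg$class1_fraction <= 0 || cfg$class1_fraction >= 1)
    stop("class1_fraction must be in (0, 1)")
  if (cfg$weeks < 5) stop("weeks must be at least 5")
  if (length(cfg$grid_shape) != 3 || any(cfg$grid_shape < 16))
    stop("grid too small to carve both ROIs (need at least 16 voxels per axis)")
  if (any(cfg$spacing_mm <= 0)) stop("spacing_mm must be positive")
  null_regime <- isTRUE(all.equal(cfg$class1_volume_drop,
                                  cfg$class2_volume_drop))
  if (!null_regime) {
    if (cfg$class1_volume_drop <= 0.20)
      stop("class1_volume_drop must exceed 0.20")
    if (cfg$class2_volume_drop >= 0.20)
      stop("class2_volume_drop must stay below 0.20")
  } else if (cfg$class1_volume_drop >= 0.20) {
    stop("null-regime volume drops must stay below 0.20")
  }
  if (cfg$texture_effect_size < 0) stop("texture_effect_size must be >= 0")
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  if (cfg$n_informative < 0 || cfg$n_informative > 208)
    stop("n_informative must be in 0..208")
  invisible(cfg)
}

## Separable smoothing with a Gaussian kernel (sigma in voxels), edge
## renormalized.
smooth3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    d <- dim(a)
    ## banded convolution matrix, rows renormalized at the edges
    B <- matrix(0, d[1], d[1])
    for (off in -r:r) {
      idx <- seq_len(d[1])
      ok <- idx + off >= 1 & idx + off <= d[1]
      B[cbind(idx[ok], idx[ok] + off)] <- k[off + r + 1]
    }
    B <- B / rowSums(B)
    sm <- B %*% matrix(a, d[1], d[2] * d[3])
    arr <- aperm(array(as.numeric(sm), d), order(perm))
  }
  arr
}

## Ellipsoid mask: centre and radii in mm (physical space).
ellipsoid_mask <- function(grid_shape, spacing_mm, centre_mm, radii_mm) {
  x <- (seq_len(grid_shape[1]) - 0.5) * spacing_mm[1]
  y <- (seq_len(grid_shape[2]) - 0.5) * spacing_mm[2]
  z <- (seq_len(grid_shape[3]) - 0.5) * spacing_mm[3]
  dx2 <- ((x - centre_mm[1]) / radii_mm[1])^2
  dy2 <- ((y - centre_mm[2]) / radii_mm[2])^2
  dz2 <- ((z - centre_mm[3]) / radii_mm[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

#' Simulate a longitudinal CBCT-like cohort
#'
#' Generates `n_patients` timelines of weekly (image, CTV mask, PG mask)
#' records on a shared grid. The CTV is an ellipsoid and the PG a two-lobe
#' union (both glands treated as one ROI); weekly shrinkage rescales the
#' semi-axes so the fractional volume loss follows a class-dependent ramp
#' reaching its target at week 4 (Class 1 > 20 %, Class 2 < 20 %, asserted
#' per patient). Interior texture drifts between weeks through a
#' class-dependent interior mean shift and noise correlation-length change
#' scaled by `texture_effect_size`. Deterministic for a fixed seed.
#'
#' @param config a `sim_config`.
#' @return List of `patient_timeline` objects, each with `patient_id`,
#'   `true_class`, `spacing_mm` and `weeks` (list of records with `image`,
#'   `ctv`, `pg`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  n1 <- round(n * config$class1_fraction)
  classes <- sample(c(rep(1L, n1), rep(2L, n - n1)))
  gs <- config$grid_shape
  sp <- config$spacing_mm
  fov <- gs * sp
  null_regime <- isTRUE(all.equal(config$class1_volume_drop,
                                  config$class2_volume_drop))
  ramp <- c(0, 1 / 3, 2 / 3, 1, rep(1.15, max(0, config$weeks - 4)))
  es <- config$texture_effect_size
  cohort <- vector("list", n)
  for (p in seq_len(n)) {
    cl <- classes[p]
    ## per-patient geometry (mm)
    ctv_centre <- fov / 2 + runif(3, -0.04, 0.04) * fov
    ctv_radii <- c(0.21, 0.19, 0.22) * fov * runif(3, 0.9, 1.1)
    pg_off <- c(0.30, 0, 0) * fov
    pg_centre_l <- ctv_centre - pg_off + runif(3, -0.02, 0.02) * fov
    pg_centre_r <- ctv_centre + pg_off + runif(3, -0.02, 0.02) * fov
    pg_radii <- c(0.09, 0.10, 0.14) * fov * runif(3, 0.9, 1.1)
    ## class-dependent volume trajectories (CTV carries the class rule)
    if (null_regime) {
      ctv_drop <- config$class1_volume_drop
      pg_drop <- min(0.9 * ctv_drop, 0.12)
    } else if (cl == 1L) {
      ctv_drop <- min(max(rnorm(1, config$class1_volume_drop, 0.04),
                          0.26), 0.50)
      pg_drop <- min(max(rnorm(1, 0.12, 0.03), 0.04), 0.18)
    } else {
      ctv_drop <- min(max(rnorm(1, config$class2_volume_drop, 0.03),
                          0.01), 0.15)
      pg_drop <- min(max(rnorm(1, 0.05, 0.02), 0.01), 0.12)
    }
    base_mu <- 60 + rnorm(1, 0, 5)
    ctv_mu <- base_mu + 55
    pg_mu <- base_mu + 35
    wk <- vector("list", config$weeks)
    for (w in seq_len(config$weeks)) {
      s_ctv <- (1 - ctv_drop * ramp[w])^(1 / 3)
      s_pg <- (1 - pg_drop * ramp[w])^(1 / 3)
      ctv <- ellipsoid_mask(gs, sp, ctv_centre, ctv_radii * s_ctv)
      pg <- ellipsoid_mask(gs, sp, pg_centre_l, pg_radii * s_pg) |
        ellipsoid_mask(gs, sp, pg_centre_r, pg_radii * s_pg)
      if (!any(ctv) || !any(pg))
        stop("grid too small to carve both ROIs")
      ## class-dependent texture drift: interior mean shift and noise
      ## correlation length move with the treatment week
      drift <- if (cl == 1L) es * ramp[w] else 0.2 * es * ramp[w]
      mu_shift <- 0.6 * config$noise_sd * drift
      sigma_n <- 1.0 + 0.15 * ramp[w] + 0.5 * drift
      img <- array(base_mu, gs)
      img <- img + smooth3d(array(rnorm(prod(gs), 0, config$noise_sd * 0.5),
                                  gs), 1.5) * 1.5
      img[ctv] <- ctv_mu - base_mu + img[ctv] + mu_shift
      img[pg] <- pg_mu - base_mu + img[pg] + 0.7 * mu_shift
      tex <- smooth3d(array(rnorm(prod(gs), 0, config$noise_sd), gs),
                      sigma_n)
      ## rescale so the interior noise sd stays comparable across weeks
      tex <- tex * (config$noise_sd / max(sd(tex), 1e-9)) * 0.8
      img <- img + tex
      wk[[w]] <- list(image = img, ctv = ctv, pg = pg)
    }
    tl <- structure(list(patient_id = sprintf("P%03d", p),
                         true_class = cl, spacing_mm = sp, weeks = wk),
                    class = "patient_timeline")
    if (!null_regime && assign_class(tl) != cl)
      stop("internal error: realized volume trajectory violates class rule")
    cohort[[p]] <- tl
  }
  cohort
}

#' Simulate a delta-feature table directly
#'
#' Table-level stand-in for the extract-then-delta pipeline: 208 registry
#' columns of exchangeable noise (percentage-change units, sd 10), with
#' `n_informative` planted columns whose class-conditional means differ by
#' `texture_effect_size` standard deviations (alternating sign). Optionally,
#' some planted columns are duplicated into noise columns at a stated
#' pairwise correlation to exercise correlation-bias reduction.
#'
#' @param config a `sim_config` (`n_patients`, `class1_fraction`,
#'   `texture_effect_size`, `n_informative`, `seed` are used).
#' @param duplicate number of planted columns to duplicate.
#' @param duplicate_r target pairwise correlation of each duplicate with its
#'   source column.
#' @return A `delta_table` data.frame (`patient_id`, `label`, 208 feature
#'   columns) with attributes `planted` (informative column ids, duplicates
#'   included) and `week = 2`.
#' @export
simulate_feature_table <- function(config = sim_config(), duplicate = 0L,
                                   duplicate_r = 0.95) {
  validate_sim_config(config)
  if (duplicate > config$n_informative)
    stop("cannot duplicate more columns than are informative")
  set.seed(config$seed)
  n <- config$n_patients
  ids <- feature_registry()$id
  p <- length(ids)
  n1 <- round(n * config$class1_fraction)
  y <- sample(c(rep(1L, n1), rep(2L, n - n1)))
  sdcol <- 10
  X <- matrix(rnorm(n * p, 0, sdcol), n, p, dimnames = list(NULL, ids))
  info <- sort(sample(p, config$n_informative))
  if (config$n_informative > 0) {
    sgn <- rep(c(1, -1), length.out = config$n_informative)
    shift <- config$texture_effect_size * sdcol
    for (k in seq_along(info)) {
      X[y == 1L, info[k]] <- X[y == 1L, info[k]] + sgn[k] * shift
    }
  }
  dup_ids <- character(0)
  if (duplicate > 0) {
    noise_cols <- setdiff(seq_len(p), info)
    tgt <- sample(noise_cols, duplicate)
    for (k in seq_len(duplicate)) {
      src <- X[, info[k]]
      lam <- sqrt(1 / duplicate_r^2 - 1)
      X[, tgt[k]] <- src + rnorm(n, 0, sd(src) * lam)
    }
    dup_ids <- ids[tgt]
  }
  out <- cbind(data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                          label = y, stringsAsFactors = FALSE),
               as.data.frame(X))
  attr(out, "planted") <- c(ids[info], dup_ids)
  attr(out, "duplicates") <- dup_ids
  attr(out, "week") <- 2L
  class(out) <- c("delta_table", "data.frame")
  out
}
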