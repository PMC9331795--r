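## Shared fixtures, built in code at test time.

## Random quantized volume: small grid, random mask, levels 1..Ng present.
random_qvol <- function(seed, dims = NULL, Ng = 3, mask_p = 0.75) {
  set.seed(seed)
  dims <- dims %||% sample(3:6, 3, replace = TRUE)
  img <- array(runif(prod(dims), 0, Ng * 25 - 1e-6), dims)
  msk <- array(runif(prod(dims)) < mask_p, dims)
  if (!any(msk)) msk[1, 1, 1] <- TRUE
  quantize(img, msk, extraction_settings(bin_width = 25))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Solid ellipsoid-pair phantom for extraction tests: compact CTV and PG on
## a small grid, intensities with texture.
tiny_phantom <- function(seed = 1, dims = c(20, 20, 14), spacing = c(2, 2, 3)) {
  set.seed(seed)
  fov <- dims * spacing
  ctv <- artpredict:::ellipsoid_mask(dims, spacing, fov / 2, 0.18 * fov)
  pg <- artpredict:::ellipsoid_mask(dims, spacing,
                                    fov * c(0.22, 0.5, 0.5), 0.12 * fov) |
    artpredict:::ellipsoid_mask(dims, spacing,
                                fov * c(0.78, 0.5, 0.5), 0.12 * fov)
  img <- array(rnorm(prod(dims), 80, 20), dims)
  img[ctv] <- img[ctv] + 50
  img[pg] <- img[pg] + 30
  list(image = img, ctv = ctv, pg = pg, spacing = spacing)
}

## Small simulated cohort (shared across tests; small grid for speed).
small_sim_config <- function(seed = 7, n_patients = 6,
                             class1_fraction = 0.5, ...) {
  sim_config(n_patients = n_patients, class1_fraction = class1_fraction,
             grid_shape = c(24, 24, 16), spacing_mm = c(2, 2, 3),
             seed = seed, ...)
}

## Separable two-class table: one planted feature with a wide margin plus
## exchangeable noise columns, 208 registry columns.
separable_table <- function(seed = 1, n = 16, margin = 6) {
  set.seed(seed)
  ids <- feature_registry()$id
  y <- rep(c(1L, 2L), each = n / 2)
  X <- matrix(rnorm(n * length(ids)), n, length(ids),
              dimnames = list(NULL, ids))
  X[, 5] <- ifelse(y == 1L, margin, -margin) + rnorm(n, 0, 0.1)
  out <- cbind(data.frame(patient_id = sprintf("P%03d", 1:n), label = y),
               as.data.frame(X))
  class(out) <- c("delta_table", "data.frame")
  out
}

## Null feature table with a reduced column count (for calibration
## experiments at tractable size): first `p` registry columns, pure noise.
null_table <- function(seed, n = 20, p = 60) {
  set.seed(seed)
  ids <- feature_registry()$id[seq_len(p)]
  y <- rep(c(1L, 2L), length.out = n)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, ids))
  out <- cbind(data.frame(patient_id = sprintf("P%03d", 1:n), label = y),
               as.data.frame(X))
  class(out) <- c("delta_table", "data.frame")
  out
}
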