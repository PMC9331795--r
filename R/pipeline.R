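#' Pipeline run configuration
#'
#' Validated configuration for an end-to-end run: simulate (or load) a
#' cohort, extract features, build weekly delta tables, select features and
#' evaluate. Persisted verbatim into every report for reproducibility; all
#' randomness flows from the single `seed`.
#'
#' @param mode `"simulate"`, `"nifti-cohort"` or `"feature-table"`.
#' @param input manifest JSON path (`nifti-cohort`), feature-table CSV path
#'   (`feature-table`), or NULL (`simulate`).
#' @param sim a [sim_config()] (simulate mode).
#' @param settings extraction settings from [extraction_settings()].
#' @param class_threshold volume-change class threshold; default 0.20.
#' @param cbr_threshold,K,s_max selection parameters (see
#'   [loocv_subset_search()]).
#' @param n_perm permutations for the significance test.
#' @param week which delta week drives the headline model; default 2.
#' @param seed master seed.
#' @param out_dir output directory for run artifacts.
#' @return A validated `run_config` list.
#' @export
run_config <- function(mode = c("simulate", "nifti-cohort", "feature-table"),
                       input = NULL, sim = sim_config(),
                       settings = extraction_settings(),
                       class_threshold = 0.20, cbr_threshold = 0.7,
                       K = 25L, s_max = 30L, n_perm = 1000L, week = 2L,
                       seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode != "simulate" && (is.null(input) || !file.exists(input)))
    stop(sprintf("mode '%s' requires an existing input path", mode))
  if (class_threshold <= 0 || class_threshold >= 1)
    stop("class_threshold must be in (0, 1)")
  if (n_perm < 1) stop("n_perm must be at least 1")
  if (!week %in% 2:5) stop("week must be in 2..5")
  structure(list(mode = mode, input = input, sim = sim, settings = settings,
                 class_threshold = class_threshold,
                 cbr_threshold = cbr_threshold, K = as.integer(K),
                 s_max = as.integer(s_max), n_perm = as.integer(n_perm),
                 week = as.integer(week), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full early-prediction pipeline
#'
#' Executes simulate/load, feature extraction, delta-table construction,
#' RFE-CBR + LOOCV subset search, permutation significance and (image modes)
#' per-week stability; writes every intermediate table plus a JSON report
#' when `out_dir` is set.
#'
#' @param config a [run_config()].
#' @return List of run artifacts: `tables` (delta tables by week),
#'   `search` (`subset_search`), `permutation`, `stability`, `anova`,
#'   `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  tables <- NULL
  stability <- NULL
  if (config$mode == "feature-table") {
    tab <- read_delta_table(config$input)
    tables <- stats::setNames(list(tab), as.character(config$week))
  } else {
    cohort <- if (config$mode == "simulate") {
      sim <- config$sim
      sim$seed <- config$seed
      simulate_cohort(sim)
    } else {
      read_cohort_nifti(config$input)
    }
    labels <- vapply(cohort, assign_class, integer(1),
                     threshold = config$class_threshold)
    feats <- extract_cohort_features(cohort, config$settings)
    tables <- stats::setNames(
      lapply(2:5, function(w) delta_table(feats, w, labels = labels)),
      as.character(2:5))
  }
  main <- tables[[as.character(config$week)]]
  search <- loocv_subset_search(main, cbr_threshold = config$cbr_threshold,
                                K = config$K, s_max = config$s_max)
  perm <- permutation_test(main, subset = search$optimal_subset,
                           n_perm = config$n_perm, mode = "fixed",
                           seed = config$seed)
  if (length(tables) > 1) {
    stability <- weekly_stability(tables, search$optimal_subset)
  }
  anova_tab <- per_feature_anova(main)
  artifacts <- list(tables = tables, search = search, permutation = perm,
                    stability = stability, anova = anova_tab,
                    config = config)
  if (!is.null(config$out_dir)) write_report(artifacts, config$out_dir)
  artifacts
}

#' Write run artifacts to a report directory
#'
#' Emits the delta tables (CSV + JSON sidecars), per-fold predictions, the
#' consensus ranking, the per-feature ANOVA table and a versioned JSON
#' report with metrics, the accuracy-vs-subset-size curve, the optimal
#' subset, the permutation p-value and the full configuration.
#'
#' @param artifacts list from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(artifacts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (w in names(artifacts$tables)) {
    write_delta_table(artifacts$tables[[w]],
                      file.path(dir, sprintf("delta_week%s.csv", w)))
  }
  search <- artifacts$search
  write_ranking_csv(search$consensus, file.path(dir, "consensus_ranking.csv"))
  rep <- search$report
  write.csv(data.frame(patient = seq_along(rep$labels), label = rep$labels,
                       prediction = rep$predictions,
                       decision = rep$decision %||% NA_real_),
            file.path(dir, "fold_predictions.csv"), row.names = FALSE)
  write.csv(artifacts$anova, file.path(dir, "per_feature_anova.csv"),
            row.names = FALSE)
  if (!is.null(artifacts$stability))
    write.csv(artifacts$stability, file.path(dir, "weekly_stability.csv"),
              row.names = FALSE)
  cfg <- artifacts$config
  report <- list(
    schema_version = "1.0",
    config = list(mode = cfg$mode, week = cfg$week, seed = cfg$seed,
                  class_threshold = cfg$class_threshold,
                  cbr_threshold = cfg$cbr_threshold, K = cfg$K,
                  s_max = cfg$s_max, n_perm = cfg$n_perm,
                  settings = cfg$settings),
    metrics = list(weighted_accuracy = rep$weighted_accuracy,
                   sensitivity = rep$sensitivity,
                   specificity = rep$specificity, f1 = rep$f1,
                   auc = rep$auc),
    optimal_size = search$optimal_size,
    optimal_subset = search$optimal_subset,
    accuracy_curve = search$accuracy_curve,
    permutation_p = artifacts$permutation$p_value)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write a simulated cohort as NIfTI files with a JSON manifest
#'
#' Per patient and week, writes `image_wk{w}.nii.gz`, `ctv_wk{w}.nii.gz`
#' and `pg_wk{w}.nii.gz` plus a cohort manifest recording ids, classes,
#' spacing and relative paths.
#'
#' @param cohort list of `patient_timeline` objects.
#' @param dir output directory.
#' @return Manifest path, invisibly.
#' @export
write_cohort_nifti <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(cohort, function(pt) {
    pdir <- file.path(dir, pt$patient_id)
    dir.create(pdir, showWarnings = FALSE)
    weeks <- lapply(seq_along(pt$weeks), function(w) {
      rec <- pt$weeks[[w]]
      paths <- file.path(pt$patient_id,
                         sprintf(c("image_wk%d.nii.gz", "ctv_wk%d.nii.gz",
                                   "pg_wk%d.nii.gz"), w))
      RNifti::writeNifti(RNifti::asNifti(rec$image, pixdim = pt$spacing_mm),
                         file.path(dir, paths[1]))
      RNifti::writeNifti(RNifti::asNifti(array(as.integer(rec$ctv),
                                               dim(rec$ctv)),
                                         pixdim = pt$spacing_mm),
                         file.path(dir, paths[2]))
      RNifti::writeNifti(RNifti::asNifti(array(as.integer(rec$pg),
                                               dim(rec$pg)),
                                         pixdim = pt$spacing_mm),
                         file.path(dir, paths[3]))
      list(week = w, image = paths[1], ctv = paths[2], pg = paths[3])
    })
    list(patient_id = pt$patient_id, true_class = pt$true_class,
         spacing_mm = pt$spacing_mm, weeks = weeks)
  })
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(schema_version = "1.0", patients = manifest),
                       mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}

#' Read a cohort from a NIfTI manifest
#'
#' Validates that every mask is binary and shares its image's grid (shape
#' and spacing within 1e-6 mm); a patient missing its week-4 record is
#' excluded with a logged reason.
#'
#' @param manifest path to a manifest JSON written by [write_cohort_nifti()].
#' @return List of `patient_timeline` objects (attribute `excluded` names
#'   skipped patients).
#' @export
read_cohort_nifti <- function(manifest) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  m <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  dir <- dirname(manifest)
  excluded <- character(0)
  cohort <- list()
  for (pm in m$patients) {
    weeks <- vector("list", length(pm$weeks))
    ok <- TRUE
    for (wm in pm$weeks) {
      paths <- file.path(dir, c(wm$image, wm$ctv, wm$pg))
      if (!all(file.exists(paths))) {
        if (wm$week == 4) {
          excluded <- c(excluded,
                        sprintf("%s: missing week-4 file", pm$patient_id))
          ok <- FALSE
          break
        }
        next
      }
      img <- RNifti::readNifti(paths[1])
      sp_img <- RNifti::pixdim(img)
      read_mask <- function(path, what) {
        msk <- RNifti::readNifti(path)
        if (!identical(dim(msk), dim(img)))
          stop(sprintf("%s %s: mask grid %s does not match image grid %s",
                       pm$patient_id, what,
                       paste(dim(msk), collapse = "x"),
                       paste(dim(img), collapse = "x")))
        if (any(abs(RNifti::pixdim(msk) - sp_img) > 1e-6))
          stop(sprintf("%s %s: mask spacing differs from image spacing",
                       pm$patient_id, what))
        v <- as.array(msk)
        if (!all(v %in% c(0, 1)))
          stop(sprintf("%s %s: mask is not binary", pm$patient_id, what))
        array(v > 0, dim(v))
      }
      weeks[[wm$week]] <- list(image = array(as.numeric(img), dim(img)),
                               ctv = read_mask(paths[2], "ctv"),
                               pg = read_mask(paths[3], "pg"))
    }
    if (!ok) next
    cohort[[length(cohort) + 1L]] <-
      structure(list(patient_id = pm$patient_id,
                     true_class = pm$true_class %||% NA_integer_,
                     spacing_mm = unlist(pm$spacing_mm),
                     weeks = weeks),
                class = "patient_timeline")
  }
  attr(cohort, "excluded") <- excluded
  cohort
}
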