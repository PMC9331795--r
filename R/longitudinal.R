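#' Assign a patient's volumetric-change class
#'
#' Class 1 (significant change) iff the absolute relative change in voxel
#' volume between week 1 and week 4 exceeds `threshold` (strict inequality)
#' for the CTV and/or the PG ROI; otherwise Class 2. Voxel-count volume in
#' mm^3 is used; relative position change is ignored. Shrinkage and growth
#' both count (the absolute change is compared).
#'
#' @param timeline a `patient_timeline` object.
#' @param threshold relative volume change defining significance;
#'   default 0.20.
#' @return Integer class label, 1 or 2.
#' @examples
#' \dontrun{
#' cls <- assign_class(cohort[[1]])
#' }
#' @export
assign_class <- function(timeline, threshold = 0.20) {
  w1 <- timeline$weeks[[1]]
  w4 <- if (length(timeline$weeks) >= 4) timeline$weeks[[4]] else NULL
  if (is.null(w1) || is.null(w4))
    stop("weeks 1 and 4 are required for class assignment")
  voxvol <- prod(timeline$spacing_mm)
  rel <- function(roi) {
    v1 <- sum(w1[[roi]]) * voxvol
    v4 <- sum(w4[[roi]]) * voxvol
    if (v1 <= 0) stop(sprintf("empty week-1 %s mask", roi))
    abs(v4 - v1) / v1
  }
  if (rel("ctv") > threshold || rel("pg") > threshold) 1L else 2L
}

#' Build a delta-radiomics feature table for one week
#'
#' Each cell is the percentage change of a feature against its week-1
#' baseline: `100 * (f_week - f_week1) / f_week1`. Near-zero baselines
#' (|f_week1| < 1e-12) are imputed as 0 and flagged rather than dropped, so
#' the number of patients stays fixed.
#'
#' @param feats a `cohort_features` object from [extract_cohort_features()].
#' @param week which week the deltas reference (2..5).
#' @param labels optional integer class labels per patient; defaults to the
#'   cohort's `true_class`.
#' @return A `delta_table`: data.frame with `patient_id`, `label` and the 208
#'   registry feature columns, plus attributes `week` and `flagged_cells`.
#' @export
delta_table <- function(feats, week, labels = NULL) {
  stopifnot(inherits(feats, "cohort_features"))
  week <- as.integer(week)
  if (!week %in% 2:5) stop("week must be in 2..5")
  ids <- feature_registry()$id
  n <- length(feats$features)
  labels <- labels %||% feats$true_class
  flagged <- character(0)
  rows <- lapply(seq_len(n), function(k) {
    f1 <- feats$features[[k]][["1"]]
    fw <- feats$features[[k]][[as.character(week)]]
    if (is.null(f1) || is.null(fw))
      stop(sprintf("patient %s: missing features for week 1 or %d",
                   feats$patient_id[k], week))
    base <- as.numeric(f1)[match(ids, names(f1))]
    cur <- as.numeric(fw)[match(ids, names(fw))]
    d <- 100 * (cur - base) / base
    tiny <- abs(base) < 1e-12
    if (any(tiny)) {
      flagged <<- c(flagged, paste(feats$patient_id[k], ids[tiny], sep = ":"))
      d[tiny] <- 0
    }
    d
  })
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab) <- ids
  out <- cbind(data.frame(patient_id = feats$patient_id,
                          label = as.integer(labels),
                          stringsAsFactors = FALSE), tab)
  attr(out, "week") <- week
  attr(out, "flagged_cells") <- flagged
  class(out) <- c("delta_table", "data.frame")
  out
}

## Feature-column matrix and labels from a delta table (or any data.frame
## with a label column and feature columns).
table_xy <- function(table) {
  stopifnot(is.data.frame(table), "label" %in% names(table))
  drop <- intersect(c("patient_id", "label"), names(table))
  X <- as.matrix(table[, setdiff(names(table), drop), drop = FALSE])
  storage.mode(X) <- "double"
  list(X = X, y = as.integer(table$label))
}

#' Write / read a delta-feature table as CSV with a JSON sidecar
#'
#' @param table a `delta_table`.
#' @param path CSV path; metadata (week, flags) goes to `<path>.json`.
#' @return `path` invisibly (writer); a `delta_table` (reader).
#' @export
write_delta_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  meta <- list(week = attr(table, "week"),
               flagged_cells = attr(table, "flagged_cells") %||% character(0))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_delta_table
#' @export
read_delta_table <- function(path) {
  tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- feature_registry()$id
  missing_cols <- setdiff(ids, names(tab))
  if (length(missing_cols) > 0)
    stop(sprintf("feature table lacks %d registry columns (first: %s)",
                 length(missing_cols), missing_cols[1]))
  tab <- tab[, c(intersect(c("patient_id", "label"), names(tab)), ids)]
  metapath <- paste0(path, ".json")
  if (file.exists(metapath)) {
    meta <- jsonlite::read_json(metapath, simplifyVector = TRUE)
    attr(tab, "week") <- meta$week
    attr(tab, "flagged_cells") <- meta$flagged_cells
  }
  class(tab) <- c("delta_table", "data.frame")
  tab
}
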