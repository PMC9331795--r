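#' Classification metrics from LOOCV predictions
#'
#' Positive class is Class 1 (significant volumetric change), so sensitivity
#' measures detection of patients needing plan adaptation. Weighted accuracy
#' is balanced accuracy, the mean of sensitivity and specificity. AUC is the
#' trapezoidal area under the ROC over the pooled LOOCV decision values
#' (omitted with a flag when decision values are missing).
#'
#' @param predictions integer predicted labels in {1, 2}.
#' @param decision numeric decision values (larger = more Class-1-like), or
#'   NULL.
#' @param labels integer true labels in {1, 2}.
#' @return An `eval_report`: list with `weighted_accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `f1`, `auc`, `confusion`, `n`,
#'   `predictions`, `decision`, `labels`, `flags`.
#' @examples
#' ## a 19/21 split with TP = 18, FN = 1, TN = 18, FP = 3
#' y <- rep(c(1L, 2L), c(19L, 21L))
#' pred <- c(rep(1L, 18), 2L, rep(1L, 3), rep(2L, 18))
#' compute_metrics(pred, NULL, y)$weighted_accuracy  # 0.902
#' @export
compute_metrics <- function(predictions, decision = NULL, labels) {
  stopifnot(length(predictions) == length(labels))
  labels <- as.integer(labels)
  predictions <- as.integer(predictions)
  tp <- sum(predictions == 1L & labels == 1L)
  fn <- sum(predictions == 2L & labels == 1L)
  tn <- sum(predictions == 2L & labels == 2L)
  fp <- sum(predictions == 1L & labels == 2L)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (isTRUE(prec + sens > 0)) 2 * prec * sens / (prec + sens) else
    NA_real_
  flags <- character(0)
  auc <- NA_real_
  if (!is.null(decision) && !anyNA(decision) &&
      length(unique(labels)) == 2) {
    roc <- pROC::roc(response = labels, predictor = as.numeric(decision),
                     levels = c(2L, 1L), direction = "<", quiet = TRUE)
    auc <- as.numeric(pROC::auc(roc))
  } else {
    flags <- c(flags, "auc_omitted")
  }
  structure(list(
    weighted_accuracy = (sens + spec) / 2,
    sensitivity = sens, specificity = spec, precision = prec, f1 = f1,
    auc = auc, confusion = c(TP = tp, FN = fn, TN = tn, FP = fp),
    n = length(labels), predictions = predictions,
    decision = if (is.null(decision)) NULL else as.numeric(decision),
    labels = labels, flags = flags
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("LOOCV evaluation (n = %d)\n",
                     "  weighted accuracy : %.3f\n",
                     "  sensitivity       : %.3f\n",
                     "  specificity       : %.3f\n",
                     "  F1                : %.3f\n",
                     "  AUC               : %s\n"),
              x$n, x$weighted_accuracy, x$sensitivity, x$specificity, x$f1,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  invisible(x)
}

## LOOCV predictions with a fixed feature subset; z-scoring and the model
## fit use training rows only.
loocv_predict <- function(X, y, subset, cost = 1) {
  n <- nrow(X)
  preds <- integer(n)
  dec <- numeric(n)
  Xs <- X[, subset, drop = FALSE]
  for (i in seq_len(n)) {
    tr <- Xs[-i, , drop = FALSE]
    ctr <- colMeans(tr)
    sc <- apply(tr, 2, sd)
    fit <- svm_fit(zscore(tr, ctr, sc), y[-i], cost = cost)
    pr <- svm_predict(fit, zscore(Xs[i, , drop = FALSE], ctr, sc))
    preds[i] <- pr$class
    dec[i] <- pr$decision
  }
  list(predictions = preds, decision = dec)
}

#' LOOCV feature selection and incremental subset search
#'
#' The full early-prediction procedure on one delta-feature table: for every
#' leave-one-out fold, features are ranked by RFE-CBR on the training rows
#' only (n fold rankings for n patients); then, starting from a null set and
#' adding one ranked feature at a time, the LOOCV weighted accuracy is
#' evaluated for every subset size up to `s_max`, and the smallest size
#' achieving the maximum is the optimal size. The reported optimal subset is
#' the top of the cross-fold consensus ranking (the most frequently shared
#' features of all folds) at that size.
#'
#' Two curve modes are provided. The default, `"fold"`, scans each fold's
#' own ranking when predicting that fold's held-out row, so the held-out
#' sample never influences the subset it is evaluated on; on effect-free
#' data the optimal accuracy then stays near chance. Mode `"consensus"`
#' scans the global consensus subset for every fold; because the consensus
#' pools rankings from folds that trained on the held-out row, it is
#' optimistically biased under the null and is retained only for
#' sensitivity analysis.
#'
#' @param table a `delta_table` (or data.frame with `label` and feature
#'   columns).
#' @param cbr_threshold correlation level for CBR; default 0.7.
#' @param K consensus top-window size; default 25.
#' @param s_max maximum subset size scanned; default 30.
#' @param cost SVM cost parameter.
#' @param curve_mode `"fold"` (nested, default) or `"consensus"`.
#' @return Object of class `subset_search`: list with `consensus`
#'   (`ranked_features`), `fold_rankings`, `accuracy_curve` (by subset
#'   size), `optimal_size`, `optimal_subset` (feature ids), `report`
#'   (`eval_report` at the optimum).
#' @export
loocv_subset_search <- function(table, cbr_threshold = 0.7, K = 25L,
                                s_max = 30L, cost = 1,
                                curve_mode = c("fold", "consensus")) {
  curve_mode <- match.arg(curve_mode)
  xy <- table_xy(table)
  X <- xy$X; y <- xy$y
  n <- nrow(X)
  if (n < 4) stop("need at least 4 samples")
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (any(table(y) < 2)) stop("a LOOCV training fold would lose a class")
  fold_rankings <- lapply(seq_len(n), function(i) {
    rank_features(X[-i, , drop = FALSE], y[-i],
                  cbr_threshold = cbr_threshold, cost = cost)
  })
  cons <- consensus_ranking(fold_rankings, K = K)
  s_max <- min(s_max, ncol(X))
  curve <- numeric(s_max)
  evals <- vector("list", s_max)
  for (s in seq_len(s_max)) {
    if (curve_mode == "consensus") {
      pr <- loocv_predict(X, y, cons$ranking[seq_len(s)], cost = cost)
    } else {
      preds <- integer(n); dec <- numeric(n)
      for (i in seq_len(n)) {
        subset_i <- fold_rankings[[i]]$ranking[seq_len(s)]
        tr <- X[-i, subset_i, drop = FALSE]
        ctr <- colMeans(tr); sc <- apply(tr, 2, sd)
        fit <- svm_fit(zscore(tr, ctr, sc), y[-i], cost = cost)
        p1 <- svm_predict(fit, zscore(X[i, subset_i, drop = FALSE],
                                      ctr, sc))
        preds[i] <- p1$class; dec[i] <- p1$decision
      }
      pr <- list(predictions = preds, decision = dec)
    }
    evals[[s]] <- pr
    curve[s] <- compute_metrics(pr$predictions, pr$decision,
                                y)$weighted_accuracy
  }
  opt <- which.max(curve)  # first maximum = smallest optimal size
  report <- compute_metrics(evals[[opt]]$predictions, evals[[opt]]$decision,
                            y)
  structure(list(consensus = cons, fold_rankings = fold_rankings,
                 accuracy_curve = curve, optimal_size = opt,
                 optimal_subset = cons$ranking[seq_len(opt)],
                 report = report,
                 settings = list(cbr_threshold = cbr_threshold, K = K,
                                 s_max = s_max, cost = cost,
                                 curve_mode = curve_mode)),
            class = "subset_search")
}

#' Permutation significance of the classification performance
#'
#' Permutes the class labels `n_perm` times and recomputes the LOOCV
#' weighted accuracy per permutation; the p-value is the fraction of
#' permutations whose accuracy reaches the observed one. In the default
#' `"fixed"` mode the supplied feature subset is held fixed and the observed
#' statistic is the LOOCV weighted accuracy on that subset; in `"full"` mode
#' the whole ranking + consensus + subset-search procedure is rerun per
#' permutation and the statistic is the optimal-subset accuracy. The
#' comparison uses `>=` by default (conservative); set `strict = TRUE` for
#' the strict "outperformed" reading.
#'
#' @param table a `delta_table`.
#' @param subset feature ids ("fixed" mode).
#' @param n_perm number of permutations; the study-scale default is 1000.
#' @param mode `"fixed"` or `"full"`.
#' @param seed integer seed for the permutation stream.
#' @param strict logical; count only strictly better permutations.
#' @param cost SVM cost parameter.
#' @param ... further arguments to [loocv_subset_search()] ("full" mode).
#' @return List with `p_value`, `observed`, `perm_accuracy`, `n_perm`,
#'   `mode`.
#' @export
permutation_test <- function(table, subset = NULL, n_perm = 1000L,
                             mode = c("fixed", "full"), seed = 1L,
                             strict = FALSE, cost = 1, ...) {
  mode <- match.arg(mode)
  if (n_perm < 1) stop("n_perm must be at least 1")
  xy <- table_xy(table)
  X <- xy$X; y <- xy$y
  stat <- if (mode == "fixed") {
    if (is.null(subset)) stop("fixed mode needs a feature subset")
    function(yy) {
      pr <- loocv_predict(X, yy, subset, cost = cost)
      compute_metrics(pr$predictions, pr$decision, yy)$weighted_accuracy
    }
  } else {
    function(yy) {
      tab2 <- table
      tab2$label <- yy
      loocv_subset_search(tab2, cost = cost, ...)$report$weighted_accuracy
    }
  }
  observed <- stat(y)
  set.seed(seed)
  perm_acc <- vapply(seq_len(n_perm), function(b) {
    repeat {
      yy <- sample(y)
      if (length(unique(yy)) == 2 && all(table(yy) >= 2)) break
    }
    stat(yy)
  }, numeric(1))
  hits <- if (strict) sum(perm_acc > observed) else sum(perm_acc >= observed)
  list(p_value = hits / n_perm, observed = observed,
       perm_accuracy = perm_acc, n_perm = as.integer(n_perm), mode = mode)
}

#' Per-week model stability
#'
#' Refits the LOOCV classifier on each week's delta table restricted to a
#' fixed feature subset, reporting accuracy, sensitivity and specificity per
#' treatment week. Missing weeks are omitted with a flag.
#'
#' @param tables named list of `delta_table`s, names = week numbers
#'   ("2".."5").
#' @param subset feature ids to use (e.g. the week-2 optimal subset).
#' @param cost SVM cost parameter.
#' @return data.frame with one row per available week: `week`, `cbct`,
#'   `weighted_accuracy`, `sensitivity`, `specificity`, `f1`, `auc`.
#' @export
weekly_stability <- function(tables, subset, cost = 1) {
  weeks <- sort(as.integer(names(tables)))
  rows <- lapply(weeks, function(w) {
    tab <- tables[[as.character(w)]]
    if (is.null(tab)) return(NULL)
    xy <- table_xy(tab)
    pr <- loocv_predict(xy$X, xy$y, subset, cost = cost)
    m <- compute_metrics(pr$predictions, pr$decision, xy$y)
    data.frame(week = w - 1L, cbct = w,
               weighted_accuracy = m$weighted_accuracy,
               sensitivity = m$sensitivity, specificity = m$specificity,
               f1 = m$f1, auc = m$auc)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  attr(out, "missing_weeks") <- setdiff(2:5, weeks)
  out
}

#' Per-feature one-way ANOVA between the two classes
#'
#' Fixed-effects one-way ANOVA p-value per feature column (no multiplicity
#' correction). Columns with zero variance in both classes are flagged
#' undefined (NA).
#'
#' @param table a `delta_table`.
#' @return data.frame with `feature`, `F`, `p`.
#' @export
per_feature_anova <- function(table) {
  xy <- table_xy(table)
  if (length(unique(xy$y)) != 2 || any(table(xy$y) < 2))
    stop("two classes with at least 2 samples each are required")
  g <- factor(xy$y)
  res <- apply(xy$X, 2, function(col) {
    if (all(tapply(col, g, function(v) var(v) == 0 || is.na(var(v))))) {
      return(c(NA_real_, NA_real_))
    }
    tst <- oneway.test(col ~ g, var.equal = TRUE)
    c(unname(tst$statistic), tst$p.value)
  })
  data.frame(feature = colnames(xy$X), F = res[1, ], p = res[2, ],
             row.names = NULL)
}

#' Pearson correlation between features and ROI volume changes
#'
#' Pearson r with a two-sided p-value for every (feature, volume-delta)
#' pair; used to check that selected features carry information beyond the
#' volume trajectory itself. Constant columns give a flagged NA.
#'
#' @param table a `delta_table`.
#' @param volume_deltas data.frame or matrix of per-patient ROI volume
#'   percentage changes (matched rows), e.g. columns `CTV`, `PG`.
#' @return data.frame with `feature`, `roi_volume`, `r`, `p`.
#' @export
feature_volume_correlation <- function(table, volume_deltas) {
  xy <- table_xy(table)
  vd <- as.matrix(volume_deltas)
  if (nrow(vd) != nrow(xy$X)) stop("row mismatch between table and volumes")
  out <- list()
  for (v in colnames(vd)) {
    res <- apply(xy$X, 2, function(col) {
      if (sd(col) < 1e-12 || sd(vd[, v]) < 1e-12)
        return(c(NA_real_, NA_real_))
      ct <- cor.test(col, vd[, v], method = "pearson")
      c(unname(ct$estimate), ct$p.value)
    })
    out[[v]] <- data.frame(feature = colnames(xy$X), roi_volume = v,
                           r = res[1, ], p = res[2, ], row.names = NULL)
  }
  do.call(rbind, out)
}

#' Comparison classifiers under the same LOOCV design
#'
#' Alternative classifiers behind the linear-SVM interface, for side-by-side
#' evaluation on a fixed subset: k-nearest neighbours, Gaussian-kernel SVM,
#' linear discriminant analysis and random-forest-style bagged trees are
#' deliberately not part of the headline procedure.
#'
#' @param table a `delta_table`.
#' @param subset feature ids.
#' @param method one of `"svm_linear"`, `"svm_gaussian"`, `"knn"`, `"lda"`.
#' @param ... method parameters (`k` for knn, `cost`/`gamma` for SVMs).
#' @return An `eval_report`.
#' @export
loocv_classifier <- function(table, subset,
                             method = c("svm_linear", "svm_gaussian",
                                        "knn", "lda"), ...) {
  method <- match.arg(method)
  dots <- list(...)
  xy <- table_xy(table)
  X <- xy$X[, subset, drop = FALSE]; y <- xy$y
  n <- nrow(X)
  preds <- integer(n); dec <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tr <- X[-i, , drop = FALSE]
    ctr <- colMeans(tr); sc <- apply(tr, 2, sd)
    trz <- zscore(tr, ctr, sc)
    tez <- zscore(X[i, , drop = FALSE], ctr, sc)
    ytr <- factor(y[-i], levels = c(1L, 2L))
    if (method == "svm_linear") {
      fit <- svm_fit(trz, y[-i], cost = dots$cost %||% 1)
      pr <- svm_predict(fit, tez)
      preds[i] <- pr$class; dec[i] <- pr$decision
    } else if (method == "svm_gaussian") {
      fit <- e1071::svm(trz, ytr, kernel = "radial",
                        cost = dots$cost %||% 1,
                        gamma = dots$gamma %||% (1 / ncol(trz)),
                        scale = FALSE)
      pr <- predict(fit, tez, decision.values = TRUE)
      dv <- as.numeric(attr(pr, "decision.values"))
      if (colnames(attr(pr, "decision.values"))[1] == "2/1") dv <- -dv
      preds[i] <- as.integer(as.character(pr)); dec[i] <- dv
    } else if (method == "knn") {
      k <- dots$k %||% 3L
      d <- sqrt(rowSums(sweep(trz, 2L, as.numeric(tez))^2))
      nb <- y[-i][order(d)[seq_len(k)]]
      preds[i] <- if (mean(nb == 1L) >= 0.5) 1L else 2L
      dec[i] <- mean(nb == 1L)
    } else {
      mu1 <- colMeans(trz[y[-i] == 1L, , drop = FALSE])
      mu2 <- colMeans(trz[y[-i] == 2L, , drop = FALSE])
      S <- stats::cov(trz) + diag(1e-6, ncol(trz))
      wv <- solve(S, mu1 - mu2)
      thr <- sum(wv * (mu1 + mu2)) / 2
      sc1 <- sum(wv * as.numeric(tez)) - thr
      preds[i] <- if (sc1 > 0) 1L else 2L
      dec[i] <- sc1
    }
  }
  compute_metrics(preds, dec, y)
}
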