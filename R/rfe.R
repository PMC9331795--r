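## Linear soft-margin SVM helpers (libsvm, via e1071's compiled trainer).
## Cost 1, class-frequency-inverse weights, no internal scaling (callers
## z-score with training statistics). The trainer is invoked through the
## registered C routine to keep the inner RFE loop fast; equivalence with
## e1071::svm() is asserted in the test suite.

.svm_native <- new.env(parent = emptyenv())

svm_fit <- function(X, y, cost = 1) {
  sym <- .svm_native$svmtrain
  if (is.null(sym)) {
    ## the routine e1071's own svm() dispatches to
    sym <- get("R_svmtrain", envir = asNamespace("e1071"))
    .svm_native$svmtrain <- sym
  }
  y <- as.integer(y)
  n1 <- sum(y == 1L); n2 <- sum(y == 2L)
  cw <- c(length(y) / (2 * n1), length(y) / (2 * n2))
  nr <- nrow(X)
  err <- paste(rep(" ", 255), collapse = "")
  cret <- .C(sym,
             as.double(t(X)), as.integer(nr), as.integer(ncol(X)),
             as.double(y), as.integer(0), as.integer(0),
             as.integer(0),            # type: C-classification
             as.integer(0),            # kernel: linear
             as.integer(3), as.double(1 / ncol(X)), as.double(0),
             as.double(cost), as.double(0.5),
             as.integer(c(1L, 2L)), as.double(cw), as.integer(2L),
             as.double(40), as.double(0.001), as.double(0.1),
             as.integer(1), as.integer(0), as.integer(0), as.integer(0),
             nclasses = integer(1), nr = integer(1), index = integer(nr),
             labels = integer(2), nSV = integer(2), rho = double(1),
             coefs = double(nr), sigma = double(1), probA = double(1),
             probB = double(1), cresults = double(0), ctotal1 = double(1),
             ctotal2 = double(1), error = err)
  if (cret$error != err) stop(trimws(cret$error))
  nsv <- cret$nr
  idx <- cret$index[seq_len(nsv)]
  alpha <- cret$coefs[seq_len(nsv)]
  structure(list(w = drop(crossprod(alpha, X[idx, , drop = FALSE])),
                 rho = cret$rho[1], labels = cret$labels[1:2]),
            class = "linsvm")
}

## squared components of the hyperplane normal vector
svm_w2 <- function(fit) {
  as.numeric(fit$w)^2
}

svm_predict <- function(fit, Xnew) {
  raw <- as.numeric(Xnew %*% fit$w - fit$rho)
  ## f > 0 predicts the first training label; orient so larger = class 1
  dv <- if (fit$labels[1] == 1L) raw else -raw
  list(class = ifelse(dv > 0, 1L, 2L), decision = dv)
}

## z-score columns with supplied statistics; zero-sd columns map to 0
zscore <- function(X, centre, scale) {
  scale[scale < 1e-12] <- 1
  sweep(sweep(X, 2L, centre), 2L, scale, `/`)
}

## connected clusters (single linkage) of |r| >= threshold among the columns
## listed in `surviving`, given the full correlation matrix
cbr_clusters <- function(absR, surviving, threshold) {
  sub <- absR[surviving, surviving, drop = FALSE]
  adj <- sub >= threshold
  diag(adj) <- FALSE
  if (!any(adj)) return(list())
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  cl <- split(surviving, comp$membership)
  cl[lengths(cl) >= 2]
}

#' Rank features by SVM-RFE with correlation bias reduction
#'
#' Backward elimination with a linear soft-margin SVM: at every iteration the
#' classifier is refitted on the surviving features and the squared
#' hyperplane-normal components `w_i^2` serve as the ranking criterion; the
#' single lowest-criterion feature is eliminated and the final ranking is the
#' reverse elimination order (best first). Correlation bias reduction (CBR):
#' groups of highly correlated features dilute each other's weights, so for
#' every single-linkage cluster of surviving features with pairwise
#' `|Pearson r| >= cbr_threshold`, each member's criterion is recomputed from
#' a refit that excludes its cluster-mates. `cbr_threshold >= 1` disables the
#' correction (plain SVM-RFE).
#'
#' Features are z-scored with statistics of the data supplied here, so pass
#' training-fold rows only. Constant columns are moved to the tail of the
#' ranking with a warning. Criterion ties eliminate the larger column index
#' first, making the ranking deterministic.
#'
#' @param X numeric matrix (samples x features) with column names.
#' @param y integer labels in {1, 2}, at least two samples per class.
#' @param cbr_threshold correlation level defining a cluster; default 0.7.
#' @param cost SVM cost parameter.
#' @return Object of class `ranked_features`: list with `ranking` (feature
#'   ids, best first), `criterion` (w^2 at elimination, in ranking order),
#'   `cbr_threshold`, `dropped_constant`.
#' @export
rank_features <- function(X, y, cbr_threshold = 0.7, cost = 1) {
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  y <- as.integer(y)
  if (length(unique(y)) < 2 || any(table(y) < 2))
    stop("need at least two samples per class")
  if (anyNA(X)) stop("missing values in feature matrix")
  ids <- colnames(X)
  sds <- apply(X, 2, sd)
  const <- sds < 1e-12
  if (any(const)) {
    warning(sprintf("%d constant feature column(s) moved to ranking tail",
                    sum(const)))
  }
  keep <- which(!const)
  Xz <- zscore(X[, keep, drop = FALSE], colMeans(X[, keep, drop = FALSE]),
               sds[keep])
  p <- length(keep)
  ranking <- character(0)
  crit_out <- numeric(0)
  if (p > 0) {
    absR <- if (cbr_threshold < 1 && p > 1) abs(suppressWarnings(cor(Xz)))
            else NULL
    surviving <- seq_len(p)
    elim <- integer(0)
    elim_crit <- numeric(0)
    while (length(surviving) > 1) {
      fit <- svm_fit(Xz[, surviving, drop = FALSE], y, cost = cost)
      w2 <- svm_w2(fit)
      if (!is.null(absR)) {
        clusters <- cbr_clusters(absR, surviving, cbr_threshold)
        for (cl in clusters) {
          for (f in cl) {
            others <- setdiff(surviving, setdiff(cl, f))
            refit <- svm_fit(Xz[, others, drop = FALSE], y, cost = cost)
            w2[match(f, surviving)] <- svm_w2(refit)[match(f, others)]
          }
        }
      }
      lo <- which(w2 <= min(w2) + 1e-12)
      victim_pos <- lo[which.max(surviving[lo])]
      elim <- c(elim, surviving[victim_pos])
      elim_crit <- c(elim_crit, w2[victim_pos])
      surviving <- surviving[-victim_pos]
    }
    order_best_first <- c(surviving, rev(elim))
    ranking <- colnames(Xz)[order_best_first]
    crit_out <- c(NA_real_, rev(elim_crit))
  }
  ranking <- c(ranking, ids[const])
  crit_out <- c(crit_out, rep(NA_real_, sum(const)))
  structure(list(ranking = ranking, criterion = crit_out,
                 cbr_threshold = cbr_threshold,
                 dropped_constant = ids[const]),
            class = "ranked_features")
}

#' Consensus ranking across cross-validation folds
#'
#' Orders the feature universe by how frequently each feature is shared among
#' the folds' top-ranked features: primary key, the number of folds in which
#' the feature appears within the top-K window (descending); secondary, the
#' mean rank across folds (ascending); tertiary, the feature id
#' (lexicographic), which makes the consensus deterministic.
#'
#' @param fold_rankings list of `ranked_features` over the same universe.
#' @param K top-window size; default 25.
#' @return A `ranked_features` object (criterion = top-K frequency).
#' @export
consensus_ranking <- function(fold_rankings, K = 25L) {
  if (length(fold_rankings) == 0) stop("no fold rankings supplied")
  universe <- sort(fold_rankings[[1]]$ranking)
  rankmat <- vapply(fold_rankings, function(r) {
    if (!identical(sort(r$ranking), universe))
      stop("fold rankings must share one feature universe")
    match(universe, r$ranking)
  }, numeric(length(universe)))
  rankmat <- matrix(rankmat, nrow = length(universe))
  topk <- rowSums(rankmat <= K)
  meanrank <- rowMeans(rankmat)
  ord <- order(-topk, meanrank, universe)
  structure(list(ranking = universe[ord], criterion = topk[ord],
                 cbr_threshold = fold_rankings[[1]]$cbr_threshold,
                 K = as.integer(K)),
            class = "ranked_features")
}

#' Serialize a ranking to CSV for audit
#'
#' @param ranking a `ranked_features` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ranking_csv <- function(ranking, path) {
  write.csv(data.frame(rank = seq_along(ranking$ranking),
                       feature = ranking$ranking,
                       criterion = ranking$criterion),
            path, row.names = FALSE)
  invisible(path)
}
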