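make_xy <- function(seed, n = 24, p = 30, planted = NULL, margin = 3) {
  set.seed(seed)
  y <- rep(c(1L, 2L), length.out = n)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%03d", seq_len(p))))
  for (j in planted) X[, j] <- ifelse(y == 1L, margin, -margin) + rnorm(n)
  list(X = X, y = y)
}

test_that("the internal linear-SVM trainer matches e1071::svm exactly", {
  for (s in 1:10) {
    set.seed(s)
    n <- sample(10:40, 1); p <- sample(2:40, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- c(1L, 2L, sample(1:2, n - 2, replace = TRUE))
    X[, 1] <- X[, 1] + ifelse(y == 1L, 1, -1)
    fit <- artpredict:::svm_fit(X, y)
    yf <- factor(y, levels = c(1, 2))
    cw <- as.numeric(length(y) / (2 * table(yf)))
    names(cw) <- levels(yf)
    ref <- e1071::svm(X, yf, kernel = "linear", cost = 1, scale = FALSE,
                      class.weights = cw)
    wref <- as.numeric(crossprod(ref$coefs, ref$SV))
    w <- fit$w
    if (fit$labels[1] != ref$labels[1]) w <- -w
    expect_equal(unname(w), wref, tolerance = 1e-10)
    Xt <- matrix(rnorm(8 * p), 8, p)
    expect_equal(artpredict:::svm_predict(fit, Xt)$class,
                 as.integer(as.character(predict(ref, Xt))))
  }
})

test_that("ranking is a deterministic permutation of the feature ids", {
  d <- make_xy(1, planted = 3)
  r1 <- rank_features(d$X, d$y)
  r2 <- rank_features(d$X, d$y)
  expect_identical(r1, r2)
  expect_setequal(r1$ranking, colnames(d$X))
  expect_length(r1$ranking, ncol(d$X))
})

test_that("a strongly separating feature is ranked first in almost all runs", {
  hits <- vapply(1:50, function(s) {
    d <- make_xy(s, n = 20, p = 51, planted = 7, margin = 4)
    rank_features(d$X, d$y)$ranking[1] == "f007"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("cbr_threshold = 1 reproduces plain SVM-RFE", {
  d <- make_xy(3, planted = c(2, 9))
  ## duplicate feature 2 so clusters would exist if CBR were active
  d$X[, 15] <- d$X[, 2] + rnorm(nrow(d$X), 0, 0.05)
  r_plain <- rank_features(d$X, d$y, cbr_threshold = 1)
  r_cbr_off <- rank_features(d$X, d$y, cbr_threshold = 1.0)
  expect_identical(r_plain$ranking, r_cbr_off$ranking)
})

test_that("CBR protects duplicated informative features from weight dilution", {
  worst_rank <- function(seed, cbr) {
    set.seed(seed)
    n <- 40; p <- 50
    y <- rep(c(1L, 2L), each = n / 2)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("f%03d", seq_len(p))))
    X[, 1] <- ifelse(y == 1L, 0.5, -0.5) + rnorm(n)
    X[, 2] <- X[, 1] + rnorm(n, 0, sqrt(1 / 0.99^2 - 1) * sd(X[, 1]))
    r <- rank_features(X, y, cbr_threshold = if (cbr) 0.7 else 1)
    max(match(c("f001", "f002"), r$ranking))
  }
  seeds <- 1:50
  with_cbr <- vapply(seeds, worst_rank, numeric(1), cbr = TRUE)
  without <- vapply(seeds, worst_rank, numeric(1), cbr = FALSE)
  ## with CBR both copies typically stay near the top; without, the pair is
  ## demoted markedly more often
  expect_lt(median(with_cbr), median(without))
  expect_lte(median(with_cbr), 5)
})

test_that("orthonormal-limit elimination follows the class-mean difference", {
  ## constructed data: independent standardized features whose class-mean
  ## separations are graded; elimination order must track the separation
  set.seed(8)
  n <- 60
  y <- rep(c(1L, 2L), each = n / 2)
  seps <- c(0.2, 0.6, 1.2, 2.4)
  X <- sapply(seps, function(s) ifelse(y == 1L, s / 2, -s / 2) +
                rnorm(n, 0, 0.2))
  colnames(X) <- sprintf("f%d", 1:4)
  r <- rank_features(X, y, cbr_threshold = 1)
  expect_identical(r$ranking, c("f4", "f3", "f2", "f1"))
})

test_that("constant columns are warned about and ranked last", {
  d <- make_xy(5, planted = 2)
  d$X[, 4] <- 1.5
  expect_warning(r <- rank_features(d$X, d$y), "constant")
  expect_equal(r$ranking[length(r$ranking)], "f004")
})

test_that("degenerate labels error", {
  d <- make_xy(6)
  expect_error(rank_features(d$X, rep(1L, nrow(d$X))), "class")
})

test_that("consensus ranking follows (frequency, mean rank, id) keys", {
  mk <- function(ids) structure(list(ranking = ids, criterion = NULL,
                                     cbr_threshold = 0.7),
                                class = "ranked_features")
  ids <- sprintf("f%02d", 1:6)
  ## identical rankings: consensus equals them
  cons <- consensus_ranking(list(mk(ids), mk(ids), mk(ids)), K = 3)
  expect_identical(cons$ranking, ids)
  ## f02 tops 39 of 40 folds within K; it must head the consensus
  folds <- c(replicate(39, mk(c("f02", "f01", "f03", "f04", "f05", "f06")),
                       simplify = FALSE),
             list(mk(c("f06", "f05", "f04", "f03", "f01", "f02"))))
  cons2 <- consensus_ranking(folds, K = 2)
  expect_equal(cons2$ranking[1], "f02")
  expect_error(consensus_ranking(list()), "no fold rankings")
})
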