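## Second-order (texture-matrix) features: 24 GLCM + 16 GLRLM + 16 GLSZM +
## 14 GLDM + 5 NGTDM = 75 per ROI. GLCM and GLRLM features are computed per
## direction and averaged over the 13 directions; GLSZM/GLDM/NGTDM are
## direction-free. Degenerate expressions on flat regions (single gray
## level) are replaced by documented fallbacks and flagged: GLCM Correlation
## and MCC -> 1, entropic/variance-type terms -> 0, NGTDM Coarseness -> 1e6.

glcm_features_one <- function(P) {
  Ng <- nrow(P)
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  px <- rowSums(P)
  mux <- sum(seq_len(Ng) * px)
  sigx <- sqrt(sum((seq_len(Ng) - mux)^2 * px))
  ## symmetric matrix: x and y marginals coincide
  muy <- mux; sigy <- sigx
  k_sum <- 2:(2 * Ng)
  pxy_sum <- vapply(k_sum, function(k) sum(P[i + j == k]), numeric(1))
  k_diff <- 0:(Ng - 1)
  pxy_diff <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), numeric(1))
  DA <- sum(k_diff * pxy_diff)
  autoc <- sum(P * i * j)
  contrast <- sum(P * (i - j)^2)
  corr <- if (sigx > 0) (autoc - mux * muy) / (sigx * sigy) else NA_real_
  HX <- -sum(xlog2x(px))
  HXY <- -sum(xlog2x(P))
  pxpy <- outer(px, px)
  HXY1 <- -sum(P * ifelse(pxpy > 0, log2(pxpy), 0))
  HXY2 <- -sum(xlog2x(pxpy))
  imc1 <- if (max(HX, HX) > 0) (HXY - HXY1) / HX else NA_real_
  imc2v <- 1 - exp(-2 * (HXY2 - HXY))
  imc2 <- sqrt(max(imc2v, 0))
  ## MCC: second largest eigenvalue of Q over levels with nonzero marginal
  nz <- which(px > 0)
  mcc <- if (length(nz) > 1) {
    Pn <- P[nz, nz, drop = FALSE]
    Q <- (Pn / px[nz]) %*% (t(Pn) / px[nz])
    evq <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(evq[2], 0))
  } else NA_real_
  offd <- abs(i - j) > 0
  c(
    Autocorrelation = autoc,
    ClusterProminence = sum((i + j - mux - muy)^4 * P),
    ClusterShade = sum((i + j - mux - muy)^3 * P),
    ClusterTendency = sum((i + j - mux - muy)^2 * P),
    Contrast = contrast,
    Correlation = corr,
    DifferenceAverage = DA,
    DifferenceEntropy = -sum(xlog2x(pxy_diff)),
    DifferenceVariance = sum((k_diff - DA)^2 * pxy_diff),
    Id = sum(P / (1 + abs(i - j))),
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + ((i - j) / Ng)^2)),
    Idn = sum(P / (1 + abs(i - j) / Ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(P[offd] / (i[offd] - j[offd])^2),
    JointAverage = mux,
    JointEnergy = sum(P^2),
    JointEntropy = HXY,
    MaximumProbability = max(P),
    MCC = mcc,
    SumAverage = sum(k_sum * pxy_sum),
    SumEntropy = -sum(xlog2x(pxy_sum)),
    SumSquares = sum((i - mux)^2 * P)
  )
}

glcm_features <- function(stack) {
  vals <- vapply(stack$matrices, glcm_features_one, numeric(24))
  out <- rowMeans(vals)
  sanitize_features(out, fallbacks = list(Correlation = 1, MCC = 1,
                                          Imc1 = 0, Imc2 = 0))
}

glrlm_features_one <- function(P, Np) {
  Ng <- nrow(P); Nrl <- ncol(P)
  i <- matrix(seq_len(Ng), Ng, Nrl)
  j <- matrix(seq_len(Nrl), Ng, Nrl, byrow = TRUE)
  Nr <- sum(P)
  pn <- P / Nr
  mu_i <- sum(pn * i)
  mu_j <- sum(pn * j)
  c(
    ShortRunEmphasis = sum(P / j^2) / Nr,
    LongRunEmphasis = sum(P * j^2) / Nr,
    GrayLevelNonUniformity = sum(rowSums(P)^2) / Nr,
    GrayLevelNonUniformityNormalized = sum(rowSums(P)^2) / Nr^2,
    RunLengthNonUniformity = sum(colSums(P)^2) / Nr,
    RunLengthNonUniformityNormalized = sum(colSums(P)^2) / Nr^2,
    RunPercentage = Nr / Np,
    GrayLevelVariance = sum(pn * (i - mu_i)^2),
    RunVariance = sum(pn * (j - mu_j)^2),
    RunEntropy = -sum(xlog2x(pn)),
    LowGrayLevelRunEmphasis = sum(P / i^2) / Nr,
    HighGrayLevelRunEmphasis = sum(P * i^2) / Nr,
    ShortRunLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / Nr,
    ShortRunHighGrayLevelEmphasis = sum(P * i^2 / j^2) / Nr,
    LongRunLowGrayLevelEmphasis = sum(P * j^2 / i^2) / Nr,
    LongRunHighGrayLevelEmphasis = sum(P * i^2 * j^2) / Nr
  )
}

glrlm_features <- function(stack, Np) {
  vals <- vapply(stack$matrices, glrlm_features_one, numeric(16), Np = Np)
  sanitize_features(rowMeans(vals))
}

glszm_features <- function(m) {
  P <- m$P
  Ng <- nrow(P); Ns <- ncol(P)
  i <- matrix(seq_len(Ng), Ng, Ns)
  j <- matrix(seq_len(Ns), Ng, Ns, byrow = TRUE)
  Nz <- sum(P)
  pn <- P / Nz
  mu_i <- sum(pn * i)
  mu_j <- sum(pn * j)
  out <- c(
    SmallAreaEmphasis = sum(P / j^2) / Nz,
    LargeAreaEmphasis = sum(P * j^2) / Nz,
    GrayLevelNonUniformity = sum(rowSums(P)^2) / Nz,
    GrayLevelNonUniformityNormalized = sum(rowSums(P)^2) / Nz^2,
    SizeZoneNonUniformity = sum(colSums(P)^2) / Nz,
    SizeZoneNonUniformityNormalized = sum(colSums(P)^2) / Nz^2,
    ZonePercentage = Nz / m$Np,
    GrayLevelVariance = sum(pn * (i - mu_i)^2),
    ZoneVariance = sum(pn * (j - mu_j)^2),
    ZoneEntropy = -sum(xlog2x(pn)),
    LowGrayLevelZoneEmphasis = sum(P / i^2) / Nz,
    HighGrayLevelZoneEmphasis = sum(P * i^2) / Nz,
    SmallAreaLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / Nz,
    SmallAreaHighGrayLevelEmphasis = sum(P * i^2 / j^2) / Nz,
    LargeAreaLowGrayLevelEmphasis = sum(P * j^2 / i^2) / Nz,
    LargeAreaHighGrayLevelEmphasis = sum(P * i^2 * j^2) / Nz
  )
  sanitize_features(out)
}

gldm_features <- function(m) {
  P <- m$P
  Ng <- nrow(P); Nd <- ncol(P)
  i <- matrix(seq_len(Ng), Ng, Nd)
  j <- matrix(seq_len(Nd), Ng, Nd, byrow = TRUE)
  Nz <- sum(P)
  pn <- P / Nz
  mu_i <- sum(pn * i)
  mu_j <- sum(pn * j)
  out <- c(
    SmallDependenceEmphasis = sum(P / j^2) / Nz,
    LargeDependenceEmphasis = sum(P * j^2) / Nz,
    GrayLevelNonUniformity = sum(rowSums(P)^2) / Nz,
    DependenceNonUniformity = sum(colSums(P)^2) / Nz,
    DependenceNonUniformityNormalized = sum(colSums(P)^2) / Nz^2,
    GrayLevelVariance = sum(pn * (i - mu_i)^2),
    DependenceVariance = sum(pn * (j - mu_j)^2),
    DependenceEntropy = -sum(xlog2x(pn)),
    LowGrayLevelEmphasis = sum(P / i^2) / Nz,
    HighGrayLevelEmphasis = sum(P * i^2) / Nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / Nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * i^2 / j^2) / Nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * j^2 / i^2) / Nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * i^2 * j^2) / Nz
  )
  sanitize_features(out)
}

ngtdm_features <- function(m) {
  p <- m$p; s <- m$s; n <- m$n
  Ng <- m$Ng
  Nvp <- sum(n)
  nz <- which(p > 0)
  Ngp <- length(nz)
  iv <- seq_len(Ng)
  coars_den <- sum(p * s)
  coarseness <- if (coars_den > 0) 1 / coars_den else NA_real_
  contrast <- if (Ngp > 1) {
    (sum(outer(p[nz], p[nz]) * outer(iv[nz], iv[nz], `-`)^2) /
       (Ngp * (Ngp - 1))) * (sum(s) / Nvp)
  } else 0
  pi_ <- p[nz]; si <- s[nz]; ii <- iv[nz]
  busy_den <- sum(abs(outer(ii * pi_, ii * pi_, `-`)))
  busyness <- if (busy_den > 0) coars_den / busy_den else 0
  complexity <- sum(abs(outer(ii, ii, `-`)) *
                      (outer(pi_ * si, pi_ * si, `+`) /
                         outer(pi_, pi_, `+`))) / Nvp
  strength <- if (sum(s) > 0)
    sum(outer(pi_, pi_, `+`) * outer(ii, ii, `-`)^2) / sum(s) else 0
  out <- c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
           Complexity = complexity, Strength = strength)
  sanitize_features(out, fallbacks = list(Coarseness = 1e6))
}

#' Second-order texture features
#'
#' Computes the 75 second-order features from the five texture-matrix
#' families of one ROI, in registry order (GLDM, GLCM, GLRLM, GLSZM, NGTDM).
#'
#' @param m a `texture_matrices` object from [texture_matrices()].
#' @return Named numeric vector of 75 features (names prefixed by family)
#'   with a `flags` attribute naming degenerate fallbacks.
#' @export
second_order_features <- function(m) {
  stopifnot(inherits(m, "texture_matrices"))
  parts <- list(
    gldm = gldm_features(m$gldm),
    glcm = glcm_features(m$glcm),
    glrlm = glrlm_features(m$glrlm, Np = m$Np),
    glszm = glszm_features(m$glszm),
    ngtdm = ngtdm_features(m$ngtdm)
  )
  out <- unlist(lapply(names(parts), function(f) {
    v <- parts[[f]]
    names(v) <- paste(f, names(v), sep = "_")
    v
  }))
  flags <- unlist(lapply(names(parts), function(f) {
    fl <- attr(parts[[f]], "flags")
    if (length(fl)) paste(f, fl, sep = "_") else character(0)
  }))
  attr(out, "flags") <- unname(flags)
  out
}
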