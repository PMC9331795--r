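## Independent brute-force oracles for the texture matrices and anchored
## feature formulas. These deliberately use naive per-voxel loops, separate
## from the package's vectorized implementations.

oracle_glcm_one <- function(lev, d) {
  dm <- dim(lev)
  Ng <- max(lev, na.rm = TRUE)
  M <- matrix(0, Ng, Ng)
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    q <- c(x, y, z) + d
    if (any(q < 1) || any(q > dm)) next
    b <- lev[q[1], q[2], q[3]]
    if (is.na(b)) next
    M[a, b] <- M[a, b] + 1
    M[b, a] <- M[b, a] + 1
  }
  if (sum(M) == 0) return(NULL)
  M / sum(M)
}

oracle_glrlm_one <- function(lev, d) {
  dm <- dim(lev)
  Ng <- max(lev, na.rm = TRUE)
  runs <- list()
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    pv <- c(x, y, z) - d
    if (!any(pv < 1) && !any(pv > dm)) {
      pl <- lev[pv[1], pv[2], pv[3]]
      if (!is.na(pl) && pl == a) next  # not a run start
    }
    len <- 1
    cur <- c(x, y, z) + d
    while (!any(cur < 1) && !any(cur > dm)) {
      b <- lev[cur[1], cur[2], cur[3]]
      if (is.na(b) || b != a) break
      len <- len + 1
      cur <- cur + d
    }
    runs[[length(runs) + 1]] <- c(a, len)
  }
  rr <- do.call(rbind, runs)
  M <- matrix(0, Ng, max(rr[, 2]))
  for (k in seq_len(nrow(rr))) M[rr[k, 1], rr[k, 2]] <- M[rr[k, 1], rr[k, 2]] + 1
  M
}

oracle_glszm <- function(lev, connectivity = 26) {
  dm <- dim(lev)
  Ng <- max(lev, na.rm = TRUE)
  seen <- array(FALSE, dm)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(offs != 0) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  zones <- list()
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    if (is.na(lev[x, y, z]) || seen[x, y, z]) next
    a <- lev[x, y, z]
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(stack) > 0) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (k in seq_len(nrow(offs))) {
        q <- v + offs[k, ]
        if (any(q < 1) || any(q > dm)) next
        if (seen[q[1], q[2], q[3]]) next
        b <- lev[q[1], q[2], q[3]]
        if (is.na(b) || b != a) next
        seen[q[1], q[2], q[3]] <- TRUE
        stack[[length(stack) + 1]] <- q
      }
    }
    zones[[length(zones) + 1]] <- c(a, size)
  }
  zz <- do.call(rbind, zones)
  M <- matrix(0, Ng, max(zz[, 2]))
  for (k in seq_len(nrow(zz))) M[zz[k, 1], zz[k, 2]] <- M[zz[k, 1], zz[k, 2]] + 1
  M
}

oracle_gldm <- function(lev, alpha = 0, distance = 1) {
  dm <- dim(lev)
  Ng <- max(lev, na.rm = TRUE)
  deps <- list()
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    dep <- 0
    for (dx in -distance:distance) for (dy in -distance:distance)
      for (dz in -distance:distance) {
        if (dx == 0 && dy == 0 && dz == 0) next
        q <- c(x + dx, y + dy, z + dz)
        if (any(q < 1) || any(q > dm)) next
        b <- lev[q[1], q[2], q[3]]
        if (!is.na(b) && abs(b - a) <= alpha) dep <- dep + 1
      }
    deps[[length(deps) + 1]] <- c(a, dep + 1)
  }
  dd <- do.call(rbind, deps)
  M <- matrix(0, Ng, max(dd[, 2]))
  for (k in seq_len(nrow(dd))) M[dd[k, 1], dd[k, 2]] <- M[dd[k, 1], dd[k, 2]] + 1
  M
}

oracle_ngtdm <- function(lev, distance = 1) {
  dm <- dim(lev)
  Ng <- max(lev, na.rm = TRUE)
  n_i <- numeric(Ng); s_i <- numeric(Ng)
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    nb <- c()
    for (dx in -distance:distance) for (dy in -distance:distance)
      for (dz in -distance:distance) {
        if (dx == 0 && dy == 0 && dz == 0) next
        q <- c(x + dx, y + dy, z + dz)
        if (any(q < 1) || any(q > dm)) next
        b <- lev[q[1], q[2], q[3]]
        if (!is.na(b)) nb <- c(nb, b)
      }
    n_i[a] <- n_i[a] + 1
    if (length(nb) > 0) s_i[a] <- s_i[a] + abs(a - mean(nb))
  }
  list(n = n_i, p = n_i / sum(n_i), s = s_i)
}

## Direct evaluation of the anchored printed formulas, by explicit loops
## over matrix entries (independent of the package's vectorized versions).

oracle_gldm_gln <- function(P) {
  Nz <- sum(P)
  sum(sapply(seq_len(nrow(P)), function(i) sum(P[i, ])^2)) / Nz
}
oracle_gldm_sdlgle <- function(P) {
  acc <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P)))
    acc <- acc + P[i, j] / (i^2 * j^2)
  acc / sum(P)
}
oracle_gldm_lgle <- function(P) {
  acc <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P)))
    acc <- acc + P[i, j] / i^2
  acc / sum(P)
}
oracle_glcm_marginal_mu <- function(P) {
  mu <- 0
  for (i in seq_len(nrow(P))) mu <- mu + i * sum(P[i, ])
  mu
}
oracle_glcm_correlation <- function(P) {
  Ng <- nrow(P)
  mux <- oracle_glcm_marginal_mu(P)
  muy <- oracle_glcm_marginal_mu(t(P))
  sx <- sqrt(sum(sapply(seq_len(Ng), function(i) (i - mux)^2 * sum(P[i, ]))))
  sy <- sqrt(sum(sapply(seq_len(Ng), function(j) (j - muy)^2 * sum(P[, j]))))
  acc <- 0
  for (i in seq_len(Ng)) for (j in seq_len(Ng))
    acc <- acc + P[i, j] * i * j
  (acc - mux * muy) / (sx * sy)
}
oracle_glcm_cluster_prominence <- function(P) {
  Ng <- nrow(P)
  mux <- oracle_glcm_marginal_mu(P)
  muy <- oracle_glcm_marginal_mu(t(P))
  acc <- 0
  for (i in seq_len(Ng)) for (j in seq_len(Ng))
    acc <- acc + (i + j - mux - muy)^4 * P[i, j]
  acc
}
oracle_glcm_difference_variance <- function(P) {
  Ng <- nrow(P)
  pd <- numeric(Ng)  # index k + 1, k = 0..Ng-1
  for (i in seq_len(Ng)) for (j in seq_len(Ng))
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
  DA <- sum((0:(Ng - 1)) * pd)
  sum(((0:(Ng - 1)) - DA)^2 * pd)
}
oracle_glcm_maxprob <- function(P) max(P)
oracle_glrlm_srlgle <- function(P) {
  acc <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P)))
    acc <- acc + P[i, j] / (i^2 * j^2)
  acc / sum(P)
}
oracle_glrlm_lglre <- function(P) {
  acc <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P)))
    acc <- acc + P[i, j] / i^2
  acc / sum(P)
}
oracle_glrlm_lrlgle <- function(P) {
  acc <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P)))
    acc <- acc + P[i, j] * j^2 / i^2
  acc / sum(P)
}
oracle_glszm_gln <- function(P) {
  Nz <- sum(P)
  sum(sapply(seq_len(nrow(P)), function(i) sum(P[i, ])^2)) / Nz
}
oracle_fo_energy <- function(x, c = 0) sum((x + c)^2)
oracle_fo_kurtosis <- function(x) {
  n <- length(x)
  m <- mean(x)
  (sum((x - m)^4) / n) / (sum((x - m)^2) / n)^2
}
oracle_fo_iqr <- function(x) {
  unname(quantile(x, 0.75, type = 7) - quantile(x, 0.25, type = 7))
}

## Direction-averaged oracle for one GLCM feature
oracle_glcm_avg <- function(stack, fn) {
  mean(vapply(stack$matrices, fn, numeric(1)))
}
oracle_glrlm_avg <- function(stack, fn) {
  mean(vapply(stack$matrices, fn, numeric(1)))
}
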