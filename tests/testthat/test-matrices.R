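test_that("GLCM matches hand-checkable micro-examples", {
  ## 1x1x2 mask with equal levels and the axial direction: P(a,a) = 1
  img <- array(c(10, 10), c(1, 1, 2))
  msk <- array(TRUE, c(1, 1, 2))
  q <- quantize(img, msk)
  st <- glcm(q, directions = matrix(c(0L, 0L, 1L), 1))
  expect_equal(length(st$matrices), 1L)
  expect_equal(st$matrices[[1]][1, 1], 1)

  ## 2x2x1 checkerboard: exhaustive pair enumeration per direction
  img <- array(c(0, 30, 30, 0), c(2, 2, 1))
  q <- quantize(array(img, c(2, 2, 1)), array(TRUE, c(2, 2, 1)))
  st <- glcm(q)
  ## independent enumeration
  kept <- 0
  for (k in seq_len(nrow(st$directions))) {
    M <- oracle_glcm_one(q$levels, st$directions[k, ])
    if (is.null(M)) next
    kept <- kept + 1
    expect_equal(st$matrices[[kept]], M)
  }
  expect_equal(kept, length(st$matrices))
})

test_that("all five matrix families equal brute-force enumeration on random volumes", {
  ## a quick cross-section; the acceptance suite runs the full 50-seed sweep
  for (seed in 1:15) {
    q <- random_qvol(seed)
    st <- glcm(q)
    kept <- 0
    for (k in seq_len(nrow(st$directions))) {
      M <- oracle_glcm_one(q$levels, st$directions[k, ])
      if (is.null(M)) next
      kept <- kept + 1
      expect_equal(st$matrices[[kept]], M,
                   info = sprintf("glcm seed %d dir %d", seed, k))
    }
    rl <- glrlm(q)
    for (k in seq_len(nrow(rl$directions))) {
      expect_equal(rl$matrices[[k]],
                   oracle_glrlm_one(q$levels, rl$directions[k, ]),
                   info = sprintf("glrlm seed %d dir %d", seed, k))
    }
    sz <- glszm(q)
    expect_equal(sz$P, oracle_glszm(q$levels), info = paste("glszm", seed))
    dl <- gldm(q)
    expect_equal(dl$P, oracle_gldm(q$levels), info = paste("gldm", seed))
    ng <- ngtdm(q)
    orc <- oracle_ngtdm(q$levels)
    expect_equal(ng$n, as.integer(orc$n), info = paste("ngtdm n", seed))
    expect_equal(ng$s, orc$s, tolerance = 1e-12, info = paste("ngtdm s", seed))
  }
})

test_that("conservation invariants hold exactly on random volumes", {
  for (seed in 51:60) {
    q <- random_qvol(seed)
    np <- sum(q$mask)
    st <- glcm(q)
    for (M in st$matrices) {
      expect_equal(sum(M), 1, tolerance = 1e-10)
      expect_equal(M, t(M))
      expect_true(all(M >= 0))
    }
    rl <- glrlm(q)
    for (M in rl$matrices) {
      expect_equal(sum(sweep(M, 2, seq_len(ncol(M)), `*`)), np)
    }
    sz <- glszm(q)
    expect_equal(sum(sweep(sz$P, 2, seq_len(ncol(sz$P)), `*`)), np)
    expect_equal(sum(gldm(q)$P), np)
    expect_equal(sum(ngtdm(q)$n), np)
    expect_equal(sum(ngtdm(q)$p), 1, tolerance = 1e-12)
  }
})

test_that("zone and dependence structure is right on a uniform cube", {
  img <- array(5, c(3, 3, 3))
  msk <- array(TRUE, c(3, 3, 3))
  q <- quantize(img, msk)
  sz <- glszm(q)
  ## a single 27-voxel zone at level 1
  expect_equal(sz$Nz, 1L)
  expect_equal(sz$P[1, 27], 1)
  expect_equal(sum(sz$P), 1)
  ## GLDM with alpha = 0: every voxel at its maximal (all-neighbour) dependence
  dl <- gldm(q, alpha = 0)
  ## every voxel's dependence equals its in-grid neighbour count
  dep_of <- function(v) prod(pmin(v + 1, 3) - pmax(v - 1, 1) + 1) - 1
  co <- expand.grid(1:3, 1:3, 1:3)
  expected <- tabulate(apply(co, 1, dep_of) + 1, nbins = 27)
  expect_equal(dl$P[1, ], expected)
  expect_equal(sum(dl$P), 27)
})

test_that("direction-averaged GLCM/GLRLM features are invariant under axis permutations and flips", {
  for (seed in 1:10) {
    set.seed(seed)
    dims <- c(5, 5, 5)
    img <- array(runif(prod(dims), 0, 74), dims)
    msk <- array(runif(prod(dims)) < 0.8, dims)
    msk[2, 2, 2] <- TRUE
    q1 <- quantize(img, msk)
    f1 <- artpredict:::glcm_features(glcm(q1))
    r1 <- artpredict:::glrlm_features(glrlm(q1), Np = sum(msk))
    ## rotate 90 degrees about z (permute x/y + flip), and permute axes
    img2 <- aperm(img[dims[1]:1, , , drop = FALSE], c(2, 1, 3))
    msk2 <- aperm(msk[dims[1]:1, , , drop = FALSE], c(2, 1, 3))
    q2 <- quantize(img2, msk2)
    expect_equal(artpredict:::glcm_features(glcm(q2)), f1, tolerance = 1e-10)
    expect_equal(artpredict:::glrlm_features(glrlm(q2), Np = sum(msk2)), r1,
                 tolerance = 1e-10)
    img3 <- aperm(img, c(3, 1, 2))
    msk3 <- aperm(msk, c(3, 1, 2))
    q3 <- quantize(img3, msk3)
    expect_equal(artpredict:::glcm_features(glcm(q3)), f1, tolerance = 1e-10)
  }
})
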