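test_that("a symmetric single-entry GLCM gives the degenerate closed forms", {
  ## P(a,a) = 1: maximum probability 1, cluster prominence 0,
  ## correlation falls back to 1 (flagged)
  img <- array(c(10, 10), c(1, 1, 2))
  q <- quantize(img, array(TRUE, c(1, 1, 2)))
  st <- glcm(q, directions = matrix(c(0L, 0L, 1L), 1))
  f <- artpredict:::glcm_features(st)
  expect_equal(unname(f["MaximumProbability"]), 1)
  expect_equal(unname(f["ClusterProminence"]), 0)
  expect_equal(unname(f["Correlation"]), 1)
  expect_true("Correlation" %in% attr(f, "flags"))
})

test_that("anchored second-order formulas match direct symbolic evaluation", {
  for (seed in 1:10) {
    q <- random_qvol(seed, dims = c(4, 4, 4), Ng = 4)
    tm <- texture_matrices(q)
    so <- second_order_features(tm)
    tol <- 1e-9
    rel <- function(id, expected) {
      expect_equal(unname(so[id]), expected, tolerance = tol,
                   info = paste(id, "seed", seed))
    }
    rel("gldm_GrayLevelNonUniformity", oracle_gldm_gln(tm$gldm$P))
    rel("gldm_SmallDependenceLowGrayLevelEmphasis",
        oracle_gldm_sdlgle(tm$gldm$P))
    rel("gldm_LowGrayLevelEmphasis", oracle_gldm_lgle(tm$gldm$P))
    rel("glcm_Correlation",
        oracle_glcm_avg(tm$glcm, oracle_glcm_correlation))
    rel("glcm_ClusterProminence",
        oracle_glcm_avg(tm$glcm, oracle_glcm_cluster_prominence))
    rel("glcm_DifferenceVariance",
        oracle_glcm_avg(tm$glcm, oracle_glcm_difference_variance))
    rel("glcm_MaximumProbability",
        oracle_glcm_avg(tm$glcm, oracle_glcm_maxprob))
    rel("glrlm_ShortRunLowGrayLevelEmphasis",
        oracle_glrlm_avg(tm$glrlm, oracle_glrlm_srlgle))
    rel("glrlm_LowGrayLevelRunEmphasis",
        oracle_glrlm_avg(tm$glrlm, oracle_glrlm_lglre))
    rel("glrlm_LongRunLowGrayLevelEmphasis",
        oracle_glrlm_avg(tm$glrlm, oracle_glrlm_lrlgle))
    rel("glszm_GrayLevelNonUniformity", oracle_glszm_gln(tm$glszm$P))
  }
})

test_that("family cardinalities and finiteness hold on random fixtures", {
  q <- random_qvol(99, dims = c(5, 5, 5), Ng = 5)
  so <- second_order_features(texture_matrices(q))
  fams <- sub("_.*", "", names(so))
  expect_equal(as.integer(table(fams)[c("gldm", "glcm", "glrlm", "glszm",
                                        "ngtdm")]),
               c(14L, 24L, 16L, 16L, 5L))
  expect_true(all(is.finite(so)))
})

test_that("a flat region yields flagged finite fallbacks across families", {
  img <- array(7, c(4, 4, 4))
  q <- quantize(img, array(TRUE, c(4, 4, 4)))
  so <- second_order_features(texture_matrices(q))
  expect_true(all(is.finite(so)))
  expect_equal(unname(so["glcm_Correlation"]), 1)
  expect_equal(unname(so["glcm_DifferenceVariance"]), 0)
  expect_equal(unname(so["ngtdm_Coarseness"]), 1e6)
  expect_true("glcm_Correlation" %in% attr(so, "flags"))
})
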