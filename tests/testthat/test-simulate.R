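test_that("config validation enforces the cohort invariants", {
  expect_error(sim_config(class1_volume_drop = 0.15), "exceed 0.20")
  expect_error(sim_config(class2_volume_drop = 0.25), "below 0.20")
  expect_error(sim_config(class1_fraction = 0), "class1_fraction")
  expect_error(sim_config(weeks = 4), "weeks")
  expect_error(sim_config(grid_shape = c(8, 8, 8)), "too small")
  expect_error(sim_config(n_informative = 300), "n_informative")
  ## null regime: equal sub-threshold drops are allowed
  expect_s3_class(sim_config(class1_volume_drop = 0.1,
                             class2_volume_drop = 0.1), "sim_config")
})

test_that("the default configuration reproduces the 19/21 class split", {
  cfg <- sim_config()
  expect_equal(cfg$n_patients, 40L)
  co <- simulate_cohort(small_sim_config(5, n_patients = 40,
                                         class1_fraction = 19 / 40))
  cls <- vapply(co, function(p) p$true_class, integer(1))
  expect_equal(sum(cls == 1L), 19L)
  expect_equal(sum(cls == 2L), 21L)
})

test_that("volume trajectories obey the class rule for every patient", {
  co <- simulate_cohort(small_sim_config(8, n_patients = 10))
  for (pt in co) {
    v <- vapply(pt$weeks, function(w) sum(w$ctv), numeric(1))
    rel4 <- abs(v[4] - v[1]) / v[1]
    vpg <- vapply(pt$weeks, function(w) sum(w$pg), numeric(1))
    rel4pg <- abs(vpg[4] - vpg[1]) / vpg[1]
    if (pt$true_class == 1L) {
      expect_true(rel4 > 0.20 || rel4pg > 0.20)
    } else {
      expect_lt(rel4, 0.20)
      expect_lt(rel4pg, 0.20)
    }
    ## masks nonempty each week, on the shared grid
    for (w in pt$weeks) {
      expect_true(any(w$ctv) && any(w$pg))
      expect_identical(dim(w$image), dim(w$ctv))
    }
  }
})

test_that("a fixed seed reproduces the cohort bit-identically", {
  cfg <- small_sim_config(99, n_patients = 4)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  t1 <- simulate_feature_table(sim_config(seed = 4))
  t2 <- simulate_feature_table(sim_config(seed = 4))
  expect_identical(t1, t2)
})

test_that("feature tables carry 208 registry columns and planted structure", {
  cfg <- sim_config(n_informative = 19, texture_effect_size = 1.5, seed = 2)
  tab <- simulate_feature_table(cfg)
  expect_equal(names(tab)[-(1:2)], feature_registry()$id)
  expect_equal(nrow(tab), 40)
  expect_equal(sum(tab$label == 1L), 19)
  planted <- attr(tab, "planted")
  expect_length(planted, 19)
  ## planted columns separate the classes, noise columns do not
  gap <- vapply(planted, function(id) {
    abs(mean(tab[tab$label == 1, id]) - mean(tab[tab$label == 2, id]))
  }, numeric(1))
  expect_gt(min(gap), 5)  # 1.5 SD shift with sd 10
  noise <- setdiff(feature_registry()$id, planted)[1:40]
  gapn <- vapply(noise, function(id) {
    abs(mean(tab[tab$label == 1, id]) - mean(tab[tab$label == 2, id]))
  }, numeric(1))
  expect_lt(stats::median(gapn), 5)
})

test_that("correlated duplicates reach the requested correlation", {
  cfg <- sim_config(n_informative = 5, texture_effect_size = 1.5, seed = 6)
  tab <- simulate_feature_table(cfg, duplicate = 3, duplicate_r = 0.95)
  dup <- attr(tab, "duplicates")
  planted <- attr(tab, "planted")
  expect_length(dup, 3)
  expect_length(planted, 8)
  src <- setdiff(planted, dup)[1:3]
  for (k in 1:3) {
    r <- cor(tab[[src[k]]], tab[[dup[k]]])
    expect_gt(abs(r), 0.85)
  }
})

test_that("texture drift is class-dependent and detectable at week 2", {
  ## larger effect for a clean signal at small n
  co <- simulate_cohort(small_sim_config(77, n_patients = 12,
                                         texture_effect_size = 2))
  fx <- extract_cohort_features(co, weeks = c(1, 2))
  tab <- delta_table(fx, 2)
  ## the interior mean shift moves CTV first-order means apart by class
  d1 <- tab[tab$label == 1, "CTV_firstorder_Mean"]
  d2 <- tab[tab$label == 2, "CTV_firstorder_Mean"]
  expect_gt(abs(mean(d1) - mean(d2)), 0.5)
})
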