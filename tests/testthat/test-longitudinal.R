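## Minimal timeline builder: only mask volumes matter for class assignment.
mask_of <- function(nvox, dims = c(12, 12, 8)) {
  m <- array(FALSE, dims)
  m[seq_len(nvox)] <- TRUE
  m
}
timeline_of <- function(v1_ctv, v4_ctv, v1_pg = 50, v4_pg = 50) {
  mk <- function(nc, np) list(image = array(0, c(12, 12, 8)),
                              ctv = mask_of(nc), pg = mask_of(np))
  structure(list(patient_id = "T", true_class = NA, spacing_mm = c(1, 1, 1),
                 weeks = list(mk(v1_ctv, v1_pg), mk(v1_ctv, v1_pg),
                              mk(v1_ctv, v1_pg), mk(v4_ctv, v4_pg),
                              mk(v4_ctv, v4_pg))),
            class = "patient_timeline")
}

test_that("class assignment follows the strict >20 % week-4 rule", {
  ## 100 -> 75 voxels: 25 % change, Class 1
  expect_equal(assign_class(timeline_of(100, 75)), 1L)
  ## both ROIs within 10 %: Class 2
  expect_equal(assign_class(timeline_of(100, 92, 50, 47)), 2L)
  ## exactly 20.0 %: strict inequality keeps Class 2
  expect_equal(assign_class(timeline_of(100, 80)), 2L)
  ## growth also counts
  expect_equal(assign_class(timeline_of(100, 130)), 1L)
  ## PG alone can trigger Class 1
  expect_equal(assign_class(timeline_of(100, 95, 50, 30)), 1L)
})

test_that("missing week 4 errors", {
  tl <- timeline_of(100, 75)
  tl$weeks <- tl$weeks[1:3]
  expect_error(assign_class(tl), "week")
})

test_that("delta tables are percentage changes against week 1", {
  co <- simulate_cohort(small_sim_config(31, n_patients = 4))
  fx <- extract_cohort_features(co, weeks = c(1, 2))
  tab <- delta_table(fx, 2)
  expect_s3_class(tab, "delta_table")
  expect_equal(names(tab)[-(1:2)], feature_registry()$id)
  ## spot-check one cell against the definition
  f1 <- fx$features[[2]][["1"]][["CTV_firstorder_Mean"]]
  f2 <- fx$features[[2]][["2"]][["CTV_firstorder_Mean"]]
  expect_equal(tab[2, "CTV_firstorder_Mean"], 100 * (f2 - f1) / f1)
  ## week 1 against itself is identically zero
  fx1 <- fx
  fx1$features <- lapply(fx1$features, function(w) list("1" = w[["1"]],
                                                        "2" = w[["1"]]))
  tab0 <- delta_table(fx1, 2)
  expect_true(all(abs(as.matrix(tab0[, -(1:2)])) < 1e-12))
})

test_that("class labels on simulated cohorts reproduce the generator truth", {
  co <- simulate_cohort(small_sim_config(41, n_patients = 8))
  expect_equal(vapply(co, assign_class, integer(1)),
               vapply(co, function(p) p$true_class, integer(1)))
})

test_that("near-zero baselines are imputed as zero and flagged", {
  co <- simulate_cohort(small_sim_config(51, n_patients = 4))
  fx <- extract_cohort_features(co, weeks = c(1, 2))
  ## force a zero baseline in one feature
  fx$features[[1]][["1"]][["CTV_firstorder_Mean"]] <- 0
  tab <- delta_table(fx, 2)
  expect_equal(tab[1, "CTV_firstorder_Mean"], 0)
  expect_true(any(grepl("CTV_firstorder_Mean",
                        attr(tab, "flagged_cells"))))
})

test_that("delta tables round-trip through CSV", {
  co <- simulate_cohort(small_sim_config(61, n_patients = 4))
  fx <- extract_cohort_features(co, weeks = c(1, 2))
  tab <- delta_table(fx, 2)
  path <- file.path(tempdir(), "delta.csv")
  write_delta_table(tab, path)
  tab2 <- read_delta_table(path)
  expect_equal(as.matrix(tab2[, -(1:2)]), as.matrix(tab[, -(1:2)]),
               tolerance = 1e-12)
  expect_equal(attr(tab2, "week"), 2)
  unlink(c(path, paste0(path, ".json")))
})
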