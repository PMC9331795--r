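#!/usr/bin/env Rscript

## Step 3 — feature selection and LOOCV evaluation on the week-2 deltas.
##
## Runs RFE-CBR per leave-one-out fold, builds the cross-fold consensus,
## scans the accuracy-vs-subset-size curve (nested, fold-wise), evaluates
## the optimal subset and attaches a permutation p-value. Works on the
## image-derived week-2 table if step 2 has been run, otherwise on the
## table-mode cohort from step 1.

suppressPackageStartupMessages(library(artpredict))

out_dir <- "results"
src <- file.path(out_dir, "delta_week2.csv")
if (!file.exists(src)) src <- file.path(out_dir,
                                        "feature_table_week2_planted.csv")
if (!file.exists(src)) stop("run analysis/01_simulate_cohort.R first")
cat("Input table:", src, "\n")
tab <- read_delta_table(src)

t0 <- Sys.time()
search <- loocv_subset_search(tab)
cat(sprintf("Subset search (%d folds, s_max %d) in %.1f min\n",
            nrow(tab), length(search$accuracy_curve),
            as.numeric(Sys.time() - t0, units = "mins")))

rep <- search$report
cat(sprintf(paste0("Optimal subset: %d features\n",
                   "  weighted accuracy %.3f | sensitivity %.3f | ",
                   "specificity %.3f | F1 %.3f | AUC %.3f\n"),
            search$optimal_size, rep$weighted_accuracy, rep$sensitivity,
            rep$specificity, rep$f1, rep$auc))
roi <- sub("_.*", "", search$optimal_subset)
cat(sprintf("  %d CTV features, %d PG features\n",
            sum(roi == "CTV"), sum(roi == "PG")))

perm <- permutation_test(tab, subset = search$optimal_subset,
                         n_perm = 1000L, seed = 1L)
cat(sprintf("Permutation test (n = %d): observed %.3f, p = %.3f\n",
            perm$n_perm, perm$observed, perm$p_value))

write_ranking_csv(search$consensus,
                  file.path(out_dir, "consensus_ranking.csv"))
jsonlite::write_json(list(
  optimal_size = search$optimal_size,
  optimal_subset = search$optimal_subset,
  accuracy_curve = search$accuracy_curve,
  metrics = list(weighted_accuracy = rep$weighted_accuracy,
                 sensitivity = rep$sensitivity,
                 specificity = rep$specificity,
                 f1 = rep$f1, auc = rep$auc),
  permutation_p = perm$p_value, n_perm = perm$n_perm),
  file.path(out_dir, "selection_report.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("Wrote consensus_ranking.csv and selection_report.json\n")
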