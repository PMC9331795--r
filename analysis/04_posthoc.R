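#!/usr/bin/env Rscript

## Step 4 — post-hoc analyses of the selected features.
##
## Per-week stability of the fixed optimal subset (weeks 2-5), per-feature
## one-way ANOVA between the classes, Pearson correlation of the selected
## features with the ROI volume changes, and per-feature box plots.
## Requires steps 2 and 3 (image-derived tables).

suppressPackageStartupMessages(library(artpredict))

out_dir <- "results"
sel_path <- file.path(out_dir, "selection_report.json")
if (!file.exists(sel_path)) stop("run analysis/03_select_and_evaluate.R first")
sel <- jsonlite::read_json(sel_path, simplifyVector = TRUE)
subset <- sel$optimal_subset

tabs <- list()
for (w in 2:5) {
  p <- file.path(out_dir, sprintf("delta_week%d.csv", w))
  if (file.exists(p)) tabs[[as.character(w)]] <- read_delta_table(p)
}
if (length(tabs) == 0) stop("run analysis/02_extract_features.R first")

stab <- weekly_stability(tabs, subset)
print(stab, row.names = FALSE)
write.csv(stab, file.path(out_dir, "weekly_stability.csv"),
          row.names = FALSE)

tab2 <- tabs[["2"]]
anova_tab <- per_feature_anova(tab2)
sel_anova <- anova_tab[anova_tab$feature %in% subset, ]
cat(sprintf("Selected features with ANOVA p < 0.05: %d of %d\n",
            sum(sel_anova$p < 0.05, na.rm = TRUE), nrow(sel_anova)))
write.csv(anova_tab, file.path(out_dir, "per_feature_anova.csv"),
          row.names = FALSE)

vol_path <- file.path(out_dir, "volume_deltas_week2.csv")
if (file.exists(vol_path)) {
  vol <- read.csv(vol_path)
  fvc <- feature_volume_correlation(tab2[, c("label", subset)],
                                    vol[, c("CTV", "PG")])
  cat(sprintf("Selected-feature |r| with ROI volume change: median %.2f, max %.2f\n",
              median(abs(fvc$r), na.rm = TRUE),
              max(abs(fvc$r), na.rm = TRUE)))
  write.csv(fvc, file.path(out_dir, "feature_volume_correlation.csv"),
            row.names = FALSE)
}

## box plots of the selected delta features by class
fig_dir <- file.path(out_dir, "figures")
dir.create(fig_dir, showWarnings = FALSE)
pdf(file.path(fig_dir, "selected_feature_boxplots.pdf"),
    width = 10, height = 7)
op <- par(mfrow = c(ceiling(length(subset) / 5), 5), mar = c(2, 3, 2, 1))
for (f in subset) {
  boxplot(tab2[[f]] ~ tab2$label, main = f, cex.main = 0.6,
          names = c("Class 1", "Class 2"), xlab = "", ylab = "")
}
par(op)
dev.off()
cat("Wrote weekly_stability.csv, per_feature_anova.csv and box plots\n")
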