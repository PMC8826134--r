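#!/usr/bin/env Rscript
# Stage 5 - cross-validation and variable diagnostics.
#
# Evaluates the selected architecture with (a) leave-one-bird-out CV and
# (b) spatial-block CV (variogram-guided block size, five folds), both
# with the fixed 20-epoch protocol; then quantifies each predictor's
# contribution by grouped permutation importance (relative AUC drop, %)
# and its marginal effect with ICE/partial-dependence curves.

suppressPackageStartupMessages(library(rotorrisk))
out <- "results/evaluation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tab <- read.table("results/features/feature_table.tsv", sep = "\t",
                  header = TRUE, check.names = FALSE)
feats <- as.matrix(tab[, feature_names()])
labels <- tab$label
model <- read_model("results/model/model.txt")
cfg <- model$config

cv_bird <- loo_bird_cv(feats, labels, tab$bird_id, cfg, epochs = 20)
write.table(cv_bird$per_fold, file.path(out, "cv_bird.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message(sprintf("bird CV:  mean train AUC %.3f (sd %.3f), mean test AUC %.3f (sd %.3f)",
                cv_bird$mean_train_auc, cv_bird$sd_train_auc,
                cv_bird$mean_test_auc, cv_bird$sd_test_auc))

dem <- read_ascii_grid("results/world/dem.asc")
env <- build_env_stack(
  dem,
  read_ascii_grid("results/world/landcover.asc"),
  read_ascii_grid("results/world/geology.asc"),
  read_ascii_grid("results/world/ibex.asc"),
  read_ascii_grid("results/world/chamois.asc"),
  read_ascii_grid("results/world/wind_100m.asc"))
bs <- estimate_block_size(env, seed = 4)
message(sprintf("variogram block-size suggestion: %.0f m (median of per-band ranges)",
                bs$recommended_m))
mask <- read_ascii_grid("results/world/region_mask.asc")
side <- max(bs$recommended_m, 10 * dem$cellsize)
blocks <- make_blocks(mask, side_m = side, n_folds = 5, seed = 4)
cv_block <- block_cv(feats, labels, tab$x, tab$y, blocks, cfg, epochs = 20)
write.table(cv_block$per_fold, file.path(out, "cv_block.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message(sprintf("block CV (%.0f m blocks): mean train AUC %.3f (sd %.3f), mean test AUC %.3f (sd %.3f)",
                side, cv_block$mean_train_auc, cv_block$sd_train_auc,
                cv_block$mean_test_auc, cv_block$sd_test_auc))

xz <- apply_normalizer(feats, model$norm_stats)
imp <- permutation_importance(model, xz, labels,
                              groups = importance_groups("headline"),
                              n_reps = 10, seed = 5)
write.table(imp, file.path(out, "importance.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message("permutation importance (relative AUC drop, %):")
for (i in seq_len(nrow(imp)))
  message(sprintf("  %-10s %6.1f", imp$group[i], imp$auc_drop_pct[i]))

idx <- withr::with_seed(6, sample(nrow(feats), min(1000, nrow(feats))))
for (v in c("slope", "northness", "windspeed", "ibex")) {
  ec <- ice_pd(model, feats[idx, ], v, model$norm_stats, n_grid = 25)
  write.table(data.frame(grid = ec$grid, pd = ec$pd),
              file.path(out, paste0("pd_", v, ".tsv")), sep = "\t",
              row.names = FALSE, quote = FALSE)
}
message("partial-dependence curves written for slope, northness, windspeed, ibex")
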