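#!/usr/bin/env Rscript
# Stage 6 - bagged probability maps and conflict products.
#
# Trains a bagged ensemble (bootstrap resamples of the training split,
# early stopping on the shared validation split), projects each member
# over the full study area, aggregates mean + 95% credible-interval maps,
# binarizes the mean map at the 95%-sensitivity threshold, and combines
# the result with a species-occurrence probability map and a 4-level
# potential-conflict map into the joint-probability and high-risk
# conflict maps with their area-share table. The occurrence and conflict
# maps are pipeline inputs (outputs of a companion habitat model); here
# they are stood in by synthetic surfaces derived from the ibex band.

suppressPackageStartupMessages(library(rotorrisk))
out <- "results/maps"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tab <- read.table("results/features/feature_table.tsv", sep = "\t",
                  header = TRUE, check.names = FALSE)
feats <- as.matrix(tab[, feature_names()])
labels <- tab$label
model <- read_model("results/model/model.txt")

B <- 10   # ensemble size for this driver; 30 in the full protocol
message("training the bagged ensemble (B = ", B, ") ...")
cfg <- model$config
cfg$max_epochs <- 30L
ens <- bagging_train(feats, labels, cfg, B = B, split_seed = 2, seed = 31)

dem <- read_ascii_grid("results/world/dem.asc")
env <- build_env_stack(
  dem,
  read_ascii_grid("results/world/landcover.asc"),
  read_ascii_grid("results/world/geology.asc"),
  read_ascii_grid("results/world/ibex.asc"),
  read_ascii_grid("results/world/chamois.asc"),
  read_ascii_grid("results/world/wind_100m.asc"))
members <- predict_raster(ens, env)
bag <- aggregate_bagged(members)
write_ascii_grid(bag$mean, file.path(out, "low_flight_mean.asc"))
write_ascii_grid(bag$lower, file.path(out, "low_flight_lower95.asc"))
write_ascii_grid(bag$upper, file.path(out, "low_flight_upper95.asc"))
ci_width <- bag$upper$values - bag$lower$values
message(sprintf("bagged mean map written; median 95%% CI width %.3f",
                median(ci_width, na.rm = TRUE)))

scores <- Reduce(`+`, lapply(ens$members, function(m)
  predict(m, apply_normalizer(feats, ens$norm_stats)))) / B
th <- threshold_at_sensitivity(labels, scores, target = 0.95)
message(sprintf("95%%-sensitivity threshold %.4f (achieved TPR %.1f%%)",
                th$threshold, 100 * th$achieved_tpr))
bin <- binarize(bag$mean, th$threshold)
write_ascii_grid(bin, file.path(out, "low_flight_binary.asc"))

# stand-in occurrence and potential-conflict inputs (synthetic: the ibex
# band doubles as a coarse habitat-suitability proxy)
occurrence <- env$ibex
conflict <- raster_map(env$ibex, function(v)
  ifelse(is.na(v), NA, findInterval(v, c(0.3, 0.55, 0.75, 0.9))))
joint <- joint_probability(bag$mean, occurrence)
write_ascii_grid(joint, file.path(out, "joint_probability.asc"))
hr <- high_risk_intersect(bin, conflict)
write_ascii_grid(hr$high_risk, file.path(out, "high_risk.asc"))
write.table(hr$area_shares, file.path(out, "area_shares.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message("area shares (% of region cells):")
print(hr$area_shares, row.names = FALSE)
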