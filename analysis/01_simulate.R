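#!/usr/bin/env Rscript
# Stage 1 - simulate the study system.
#
# Builds the synthetic world: a 3 km x 3 km alpine terrain at 25 m
# resolution, the co-registered environmental predictor stack, and GPS
# tracks for ten birds with a known logistic low-flight generating process
# plus realistic contamination (night fixes, perched fixes, bad GPS
# quality). Everything is written as plain text (ESRI ASCII grids and
# tab-separated tables) under results/world/.

suppressPackageStartupMessages(library(rotorrisk))
out <- "results/world"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- world_config(grid_rows = 120, grid_cols = 120,
                    n_birds = 10, fixes_per_bird = 2000,
                    burst_fraction = 0.2,
                    night_fraction = 0.05, perched_fraction = 0.05,
                    bad_quality_fraction = 0.05,
                    beta = default_beta(), seed = 20260921L)

dem <- generate_dem(cfg)
world <- generate_env_stack(cfg, dem)
tracks <- generate_tracks(cfg, world)

write_ascii_grid(world$dem, file.path(out, "dem.asc"))
write_ascii_grid(world$undulation, file.path(out, "undulation.asc"))
write_ascii_grid(world$region_mask, file.path(out, "region_mask.asc"))
write_ascii_grid(world$wind_100m, file.path(out, "wind_100m.asc"))
for (band in c("landcover", "geology", "ibex", "chamois"))
  write_ascii_grid(world$env[[band]], file.path(out, paste0(band, ".asc")))
write_tracks(tracks$fixes, file.path(out, "fixes.tsv"))
write_bird_meta(tracks$meta, file.path(out, "birds.tsv"))
# generating truth, for the recovery diagnostics in later stages
writeLines(c(sprintf("intercept\t%.17g", cfg$intercept),
             sprintf("%s\t%.17g", names(cfg$beta), cfg$beta)),
           file.path(out, "generating_beta.tsv"))
writeLines(sprintf("%.6f", tracks$truth$bayes_auc),
           file.path(out, "bayes_auc.txt"))
writeLines(c(sprintf("ref_lat\t%g", cfg$ref_lat),
             sprintf("ref_lon\t%g", cfg$ref_lon)),
           file.path(out, "world_meta.tsv"))

message(sprintf("world: %d x %d cells at %g m; %d raw fixes for %d birds",
                cfg$grid_rows, cfg$grid_cols, cfg$cell_size,
                nrow(tracks$fixes), cfg$n_birds))
message(sprintf("achievable (Bayes) AUC of the generating process: %.3f",
                tracks$truth$bayes_auc))
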