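#!/usr/bin/env Rscript
# Stage 2 - clean the raw GPS fixes.
#
# Reads the raw tracks and rasters written by 01_simulate.R and applies
# the full cleaning cascade: completeness, datum conversion to mean sea
# level, AGL computation, GPS-quality culling (HDOP >= 10 / error >= 30 m),
# the -50..4000 m AGL range, sunrise-to-sunset selection, the flight
# filter (speed < 2 m/s AND AGL < 100 m removed), the region mask, the
# eight-week post-release exclusion, one-fix-per-minute subsampling and
# the 100-fix minimum per bird. Writes the cleaned fixes and the
# per-stage audit report.

suppressPackageStartupMessages(library(rotorrisk))
wdir <- "results/world"
out <- "results/clean"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

fixes <- read_tracks(file.path(wdir, "fixes.tsv"))
meta <- read_bird_meta(file.path(wdir, "birds.tsv"))
dem <- read_ascii_grid(file.path(wdir, "dem.asc"))
und <- read_ascii_grid(file.path(wdir, "undulation.asc"))
mask <- read_ascii_grid(file.path(wdir, "region_mask.asc"))
wm <- read.table(file.path(wdir, "world_meta.tsv"), sep = "\t",
                 row.names = 1)
m_per_deg <- 111320
latlon <- function(x, y)
  list(lat = wm["ref_lat", 1] + y / m_per_deg,
       lon = wm["ref_lon", 1] + x / (m_per_deg * cos(wm["ref_lat", 1] * pi / 180)))

res <- clean_tracks(fixes, meta, dem, und, mask, latlon)
print(res$report)
write_cleaning_report(res$report, file.path(out, "cleaning_report.tsv"))
write.table(res$fixes, file.path(out, "fixes_clean.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

message(sprintf("retained %d fixes from %d birds (%.1f%% of raw)",
                nrow(res$fixes), length(unique(res$fixes$bird_id)),
                100 * nrow(res$fixes) / nrow(fixes)))
message(sprintf("%.1f%% of cleaned fixes are below the 200 m critical altitude",
                100 * mean(res$fixes$agl < 200)))
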