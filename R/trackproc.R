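#' @title GPS track cleaning
#' @description Turns raw GPS fixes into the modelling dataset through a
#'   fixed sequence of filters: completeness, altitude-datum conversion to
#'   mean sea level, above-ground-level (AGL) computation against the DEM,
#'   GPS-quality culling (HDOP >= 10 or position error >= 30 m), the
#'   -50..4000 m AGL plausibility range, sunrise-to-sunset daylight
#'   selection, a flight filter (drop fixes both slower than 2 m/s and
#'   lower than 100 m AGL), the study-region mask, exclusion of the first
#'   eight weeks after fledging, one-fix-per-minute subsampling of 1 Hz
#'   bursts, and a minimum of 100 surviving fixes per bird. Every stage's
#'   input/output counts are recorded in a cleaning report.
#' @name trackproc
NULL

#' Keep only fixes with both altitude and ground speed
#'
#' Devices that do not record both fields simultaneously cannot support
#' the flight filter, so their fixes are discarded up front.
#'
#' @param fixes fixes data.frame (columns `altitude_raw`, `ground_speed`).
#' @return filtered data.frame.
#' @export
require_complete <- function(fixes) {
  fixes[!is.na(fixes$altitude_raw) & !is.na(fixes$ground_speed), ,
        drop = FALSE]
}

#' Convert reported altitudes to mean sea level
#'
#' Fixes on the msl datum pass through; ellipsoidal heights have the local
#' geoid undulation subtracted. Adds an `altitude_msl` column.
#'
#' @param fixes fixes data.frame with `altitude_raw`, `altitude_datum`.
#' @param undulation geoid-undulation `grid_raster` (m); must cover every
#'   ellipsoid-datum fix.
#' @return data.frame with `altitude_msl` set.
#' @export
to_msl <- function(fixes, undulation = NULL) {
  alt <- fixes$altitude_raw
  ell <- fixes$altitude_datum == "ellipsoid"
  if (any(ell)) {
    if (is.null(undulation))
      stop("to_msl: ellipsoid-datum fixes present but no undulation raster")
    und <- raster_sample(undulation, fixes$x[ell], fixes$y[ell])
    if (anyNA(und))
      stop("to_msl: fix outside undulation raster coverage")
    alt[ell] <- alt[ell] - und
  }
  fixes$altitude_msl <- alt
  fixes
}

#' Flight altitude above ground level
#'
#' AGL = altitude (MSL) minus the DEM elevation of the containing cell
#' (half-open cell convention). Negative values are allowed at this stage;
#' implausible ones are removed later by [agl_range_filter()].
#'
#' @param fixes data.frame with `altitude_msl`, `x`, `y`.
#' @param dem elevation `grid_raster`; must cover every fix.
#' @return data.frame with `agl` set.
#' @export
compute_agl <- function(fixes, dem) {
  elev <- raster_sample(dem, fixes$x, fixes$y)
  if (anyNA(elev) && nrow(fixes) > 0)
    stop("compute_agl: fix outside DEM coverage")
  fixes$agl <- fixes$altitude_msl - elev
  fixes
}

#' GPS quality filter
#'
#' Removes fixes with HDOP >= 10 when HDOP is provided; otherwise removes
#' fixes with a manufacturer position error >= 30 m. When both fields are
#' present HDOP governs; fixes reporting neither pass unchanged.
#'
#' @param fixes fixes data.frame (`hdop`, `position_error` optional/NA).
#' @return filtered data.frame.
#' @export
quality_filter <- function(fixes) {
  has_hdop <- !is.na(fixes$hdop)
  has_err <- !is.na(fixes$position_error)
  bad <- (has_hdop & fixes$hdop >= 10) |
    (!has_hdop & has_err & fixes$position_error >= 30)
  fixes[!bad, , drop = FALSE]
}

#' AGL plausibility range
#'
#' Retains fixes with AGL within -50..4000 m (inclusive at both ends);
#' values outside are treated as altitude measurement errors.
#'
#' @param fixes data.frame with `agl` set.
#' @param lower,upper range bounds (m).
#' @return filtered data.frame.
#' @export
agl_range_filter <- function(fixes, lower = -50, upper = 4000) {
  fixes[fixes$agl >= lower & fixes$agl <= upper, , drop = FALSE]
}

#' Daylight filter (sunrise to sunset)
#'
#' Retains fixes with geometric solar altitude >= 0 at the fix time and
#' location ([solar_altitude()]).
#'
#' @param fixes data.frame with UTC `timestamp`, `x`, `y`.
#' @param latlon function of `(x, y)` returning `list(lat, lon)` — e.g.
#'   [world_latlon()] for the synthetic world.
#' @return filtered data.frame.
#' @export
daylight_filter <- function(fixes, latlon) {
  if (nrow(fixes) == 0) return(fixes)
  ll <- latlon(fixes$x, fixes$y)
  alt <- solar_altitude(fixes$timestamp, ll$lat, ll$lon)
  fixes[alt >= 0, , drop = FALSE]
}

#' Flight filter
#'
#' Removes fixes that are simultaneously slow (ground speed < 2 m/s) and
#' low (AGL < 100 m) — almost certainly perched birds. Fixes failing only
#' one criterion are kept.
#'
#' @param fixes data.frame with `ground_speed`, `agl`.
#' @param speed_min,agl_min thresholds (m/s, m).
#' @return filtered data.frame.
#' @export
flight_filter <- function(fixes, speed_min = 2, agl_min = 100) {
  perched <- fixes$ground_speed < speed_min & fixes$agl < agl_min
  fixes[!perched, , drop = FALSE]
}

#' Study-region filter
#'
#' Retains fixes whose containing cell has mask value 1.
#'
#' @param fixes data.frame with `x`, `y`.
#' @param region_mask 0/1 `grid_raster`.
#' @return filtered data.frame.
#' @export
region_filter <- function(fixes, region_mask) {
  if (nrow(fixes) == 0) return(fixes)
  v <- raster_sample(region_mask, fixes$x, fixes$y)
  fixes[!is.na(v) & v == 1, , drop = FALSE]
}

#' Post-release filter (first eight weeks excluded)
#'
#' Removes fixes recorded during the first eight weeks (exactly 56 days)
#' after each bird's fledging/release date, to avoid release-related
#' behavioural bias. A fix exactly at fledge + 56 days is retained.
#'
#' @param fixes data.frame with `bird_id`, `timestamp`.
#' @param meta data.frame with `bird_id`, `fledge_date` for every bird.
#' @return filtered data.frame.
#' @export
post_release_filter <- function(fixes, meta) {
  if (nrow(fixes) == 0) return(fixes)
  missing <- setdiff(unique(fixes$bird_id), meta$bird_id)
  if (length(missing))
    stop("post_release_filter: no fledge_date for bird(s): ",
         paste(missing, collapse = ", "))
  fl <- meta$fledge_date[match(fixes$bird_id, meta$bird_id)]
  cutoff <- as.POSIXct(as.numeric(as.POSIXct(fl, tz = "UTC")) + 56 * 86400,
                       origin = "1970-01-01", tz = "UTC")
  fixes[fixes$timestamp >= cutoff, , drop = FALSE]
}

#' One fix per minute
#'
#' Keeps, per bird and calendar UTC minute, only the earliest fix —
#' collapsing 1 Hz bursts so high-resolution devices do not dominate the
#' modelling dataset. Must run after all removals so the retained fix per
#' minute is a surviving one.
#'
#' @param fixes data.frame with `bird_id`, `timestamp`.
#' @return filtered data.frame, time order preserved per bird.
#' @export
subsample_per_minute <- function(fixes) {
  if (nrow(fixes) == 0) return(fixes)
  ord <- order(fixes$bird_id, fixes$timestamp)
  fixes <- fixes[ord, , drop = FALSE]
  minute <- floor(as.numeric(fixes$timestamp) / 60)
  keep <- !duplicated(data.frame(fixes$bird_id, minute))
  fixes[keep, , drop = FALSE]
}

#' Minimum-fix filter
#'
#' Drops birds with fewer than `min_fixes` (default 100) fixes surviving
#' all other filters.
#'
#' @param fixes data.frame with `bird_id`.
#' @param min_fixes retention threshold.
#' @return filtered data.frame; warns if no bird survives.
#' @export
min_fix_filter <- function(fixes, min_fixes = 100) {
  counts <- table(fixes$bird_id)
  keep_birds <- names(counts)[counts >= min_fixes]
  if (!length(keep_birds))
    warning("min_fix_filter: no bird reaches ", min_fixes, " fixes")
  fixes[fixes$bird_id %in% keep_birds, , drop = FALSE]
}

#' Full cleaning pipeline with per-stage audit
#'
#' Applies, in order: completeness, datum conversion + AGL computation,
#' quality, AGL range, daylight, flight, region, post-release, per-minute
#' subsampling and the minimum-fix rule, recording input/output counts for
#' every stage.
#'
#' @param fixes raw fixes data.frame (layout of [read_tracks()]).
#' @param meta per-bird metadata (`bird_id`, `fledge_date`).
#' @param dem elevation `grid_raster`.
#' @param undulation geoid-undulation `grid_raster` (needed only when
#'   ellipsoid-datum fixes are present).
#' @param region_mask 0/1 `grid_raster`, or `NULL` to skip the region stage.
#' @param latlon planar-to-geographic mapping for the daylight filter.
#' @param min_fixes per-bird retention threshold (default 100).
#' @return list with `fixes` (cleaned, with `altitude_msl` and `agl`) and
#'   `report` (a `cleaning_report` data.frame: stage, n_in, n_out, removed;
#'   attribute `birds_retained`).
#' @export
clean_tracks <- function(fixes, meta, dem, undulation = NULL,
                         region_mask = NULL, latlon, min_fixes = 100) {
  stages <- character(); n_in <- integer(); n_out <- integer()
  step <- function(name, before, after) {
    stages <<- c(stages, name)
    n_in <<- c(n_in, nrow(before)); n_out <<- c(n_out, nrow(after))
    after
  }
  f <- step("completeness", fixes, require_complete(fixes))
  f2 <- compute_agl(to_msl(f, undulation), dem)
  f <- step("datum_conversion", f, f2)
  f <- step("quality", f, quality_filter(f))
  f <- step("agl_range", f, agl_range_filter(f))
  f <- step("daylight", f, daylight_filter(f, latlon))
  f <- step("flight", f, flight_filter(f))
  f <- step("region", f,
            if (is.null(region_mask)) f else region_filter(f, region_mask))
  f <- step("post_release", f, post_release_filter(f, meta))
  f <- step("subsample", f, subsample_per_minute(f))
  f <- step("min_fixes", f, min_fix_filter(f, min_fixes))
  report <- structure(
    data.frame(stage = stages, n_in = n_in, n_out = n_out,
               removed = n_in - n_out),
    class = c("cleaning_report", "data.frame"))
  attr(report, "birds_retained") <- sort(unique(f$bird_id))
  list(fixes = f, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Cleaning report:\n")
  print.data.frame(x, row.names = FALSE)
  cat("birds retained:", length(attr(x, "birds_retained")), "\n")
  invisible(x)
}

#' Write a cleaning report as delimited text
#' @param report a `cleaning_report`.
#' @param path output file.
#' @export
write_cleaning_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
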