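#' @title Synthetic world generator
#' @description Generates a self-contained synthetic study system — terrain,
#'   environmental rasters, bird metadata and GPS tracks with a *known*
#'   low-flight generating process — so every downstream stage (cleaning,
#'   feature extraction, model training, cross-validation, risk mapping) is
#'   testable without any proprietary tracking data. The probability that a
#'   fix lies in the rotor-swept band (below 200 m above ground) is a
#'   logistic function of the encoded environmental features with a known
#'   coefficient vector, so parameter-recovery and calibration checks have
#'   an exact ground truth.
#' @name synthgen
NULL

#' Configuration of the synthetic world
#'
#' @param grid_rows,grid_cols grid dimensions (positive integers).
#' @param cell_size cell edge (m), default 25.
#' @param relief_amplitude total elevation range of the terrain (m).
#' @param smoothing_scale correlation length of the terrain field (m).
#' @param n_birds number of tracked birds.
#' @param fixes_per_bird clean (uncontaminated) fixes generated per bird.
#' @param burst_fraction share of birds on 1 Hz burst schedules, in \\[0,1\\].
#' @param night_fraction,perched_fraction,bad_quality_fraction contamination
#'   rates in \\[0,1\\]: extra fixes injected per bird as a fraction of
#'   `fixes_per_bird`, timestamped at night / perched (speed < 2 m/s and low
#'   AGL) / with HDOP >= 10 or position error >= 30 m.
#' @param post_release_fraction,out_of_region_fraction further contamination:
#'   fixes within eight weeks of fledging, and fixes outside the region mask.
#' @param beta coefficient vector for the low-flight logit, one weight per
#'   encoded feature (length 22, contract order of [feature_names()]).
#' @param intercept intercept of the low-flight logit.
#' @param ellipsoid_fraction share of birds reporting ellipsoidal altitude.
#' @param vertical_noise_sd GPS vertical noise (m, sd).
#' @param burst_length length of 1 Hz bursts (s).
#' @param region_margin width of the out-of-region border strip (cells).
#' @param ref_lat,ref_lon geographic anchor of the planar grid origin, used
#'   only by the daylight machinery.
#' @param base_date fledging-season anchor date (clean fixes start about ten
#'   weeks later, inside the alpine daylight season).
#' @param seed integer master seed; every generator is a pure function of
#'   (config, seed).
#' @return a validated `world_config` list.
#' @export
world_config <- function(grid_rows = 120, grid_cols = 120, cell_size = 25,
                         relief_amplitude = 1500, smoothing_scale = 500,
                         n_birds = 8, fixes_per_bird = 600,
                         burst_fraction = 0.25,
                         night_fraction = 0.05, perched_fraction = 0.05,
                         bad_quality_fraction = 0.05,
                         post_release_fraction = 0,
                         out_of_region_fraction = 0,
                         beta = default_beta(), intercept = 0,
                         ellipsoid_fraction = 0.5,
                         vertical_noise_sd = 5,
                         burst_length = 60,
                         region_margin = 3,
                         ref_lat = 46.5, ref_lon = 8.0,
                         base_date = as.Date("2020-03-05"),
                         seed = 1L) {
  cfg <- list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
              cell_size = cell_size, relief_amplitude = relief_amplitude,
              smoothing_scale = smoothing_scale, n_birds = as.integer(n_birds),
              fixes_per_bird = as.integer(fixes_per_bird),
              burst_fraction = burst_fraction,
              night_fraction = night_fraction,
              perched_fraction = perched_fraction,
              bad_quality_fraction = bad_quality_fraction,
              post_release_fraction = post_release_fraction,
              out_of_region_fraction = out_of_region_fraction,
              beta = beta, intercept = intercept,
              ellipsoid_fraction = ellipsoid_fraction,
              vertical_noise_sd = vertical_noise_sd,
              burst_length = as.integer(burst_length),
              region_margin = as.integer(region_margin),
              ref_lat = ref_lat, ref_lon = ref_lon,
              base_date = as.Date(base_date), seed = as.integer(seed))
  validate_world_config(cfg)
  structure(cfg, class = "world_config")
}

validate_world_config <- function(cfg) {
  if (cfg$grid_rows < 1 || cfg$grid_cols < 1)
    stop("world_config: grid dimensions must be positive")
  if (cfg$cell_size <= 0) stop("world_config: cell_size must be > 0")
  fr <- c(cfg$burst_fraction, cfg$night_fraction, cfg$perched_fraction,
          cfg$bad_quality_fraction, cfg$post_release_fraction,
          cfg$out_of_region_fraction, cfg$ellipsoid_fraction)
  if (any(fr < 0 | fr > 1)) stop("world_config: fractions must be in [0,1]")
  if (length(cfg$beta) != length(feature_names()))
    stop("world_config: beta must have one weight per encoded feature (",
         length(feature_names()), ")")
  if (cfg$n_birds < 1 || cfg$fixes_per_bird < 1)
    stop("world_config: n_birds and fixes_per_bird must be positive")
  invisible(cfg)
}

#' Default generating coefficients
#'
#' A strong, monotone coefficient vector on the contract feature order:
#' low flight is driven up by slope (the dominant effect), southern
#' exposure, wind and ibex occurrence — the qualitative pattern a soaring
#' scavenger shows — with small land-cover/geology offsets.
#' @return numeric vector of length 22, named by [feature_names()].
#' @export
default_beta <- function() {
  b <- stats::setNames(numeric(length(feature_names())), feature_names())
  b["slope"] <- 1.5
  b["northness"] <- -0.6       # south-facing slopes fly lower
  b["windspeed"] <- 0.5
  b["ibex"] <- 0.5
  b["chamois"] <- 0.2
  b["tpi"] <- -0.2
  b["slope_unev"] <- 0.1
  b["landcover_4"] <- 0.3      # scree
  b["landcover_8"] <- 0.3      # rock
  b["landcover_2"] <- -0.3     # forest
  b["geology_2"] <- 0.1
  b
}

# smooth periodic Gaussian random field on an nr x nc grid (FFT filtered
# white noise); scale_cells is the kernel sd in cells. Pure function of seed.
smooth_field <- function(nr, nc, scale_cells, seed) {
  noise <- withr::with_seed(seed, matrix(stats::rnorm(nr * nc), nr, nc))
  if (scale_cells <= 0) return(noise)
  fi <- stats::fft(noise)
  fr <- c(0:floor(nr / 2), -((ceiling(nr / 2) - 1):1)) / nr
  fc <- c(0:floor(nc / 2), -((ceiling(nc / 2) - 1):1)) / nc
  att <- exp(-2 * pi^2 * scale_cells^2 *
               (outer(fr^2, rep(1, nc)) + outer(rep(1, nr), fc^2)))
  sm <- Re(stats::fft(fi * att, inverse = TRUE)) / (nr * nc)
  (sm - mean(sm)) / max(stats::sd(sm), .Machine$double.eps)
}

# rescale a field to [0, amplitude]
scale_to_range <- function(m, amplitude) {
  rng <- range(m)
  if (diff(rng) == 0 || amplitude == 0) return(matrix(0, nrow(m), ncol(m)))
  (m - rng[1]) / diff(rng) * amplitude
}

#' Generate the synthetic digital elevation model
#'
#' A smoothed (spatially autocorrelated) random field, rescaled so its
#' total range equals `relief_amplitude` and offset to alpine elevations.
#' Identical config and seed give a bit-identical raster.
#'
#' @param cfg a [world_config()].
#' @param base_elevation elevation of the lowest cell (m).
#' @return elevation `grid_raster` (m).
#' @export
generate_dem <- function(cfg, base_elevation = 1500) {
  validate_world_config(cfg)
  f <- smooth_field(cfg$grid_rows, cfg$grid_cols,
                    cfg$smoothing_scale / cfg$cell_size, cfg$seed)
  grid_raster(scale_to_range(f, cfg$relief_amplitude) + base_elevation,
              cellsize = cfg$cell_size)
}

#' Generate the synthetic environmental world
#'
#' Builds, on the DEM grid: categorical land cover (10 classes) and geology
#' (4 classes) from smoothed fields; ibex and chamois occurrence
#' probabilities spatially correlated with elevation (so their effects are
#' learnable); wind speed on a 4x-coarser (100 m) grid for the resampling
#' stage; a smooth low-amplitude (+/- 60 m) geoid-undulation field; and a
#' region mask excluding a border strip. The full co-registered predictor
#' stack (including derived topographic bands and resampled wind) is
#' assembled with [build_env_stack()].
#'
#' @param cfg a [world_config()].
#' @param dem raster from [generate_dem()].
#' @return list with `env` (an `env_stack`), `wind_100m`, `undulation`,
#'   `region_mask` and `dem`.
#' @export
generate_env_stack <- function(cfg, dem) {
  validate_world_config(cfg)
  nr <- cfg$grid_rows; nc <- cfg$grid_cols
  sc <- cfg$smoothing_scale / cfg$cell_size
  zn <- if (stats::sd(dem$values) > 0)
    (dem$values - mean(dem$values)) / stats::sd(dem$values)
  else matrix(0, nr, nc)

  lc_f <- 0.7 * smooth_field(nr, nc, sc / 2, cfg$seed + 11L) + 0.3 * zn
  landcover <- matrix(as.numeric(cut(lc_f, stats::quantile(lc_f, 0:10 / 10),
                                     include.lowest = TRUE, labels = FALSE)),
                      nr, nc)
  ge_f <- smooth_field(nr, nc, sc, cfg$seed + 12L)
  geology <- matrix(as.numeric(cut(ge_f, stats::quantile(ge_f, 0:4 / 4),
                                   include.lowest = TRUE, labels = FALSE)),
                    nr, nc)
  ibex <- stats::plogis(1.2 * zn + 0.8 * smooth_field(nr, nc, sc / 2, cfg$seed + 13L))
  chamois <- stats::plogis(0.5 * zn + smooth_field(nr, nc, sc / 2, cfg$seed + 14L))

  nrw <- max(1L, ceiling(nr / 4)); ncw <- max(1L, ceiling(nc / 4))
  wind_vals <- scale_to_range(
    smooth_field(nrw, ncw, sc / 4, cfg$seed + 15L), 10) + 1
  wind_100m <- grid_raster(wind_vals, cellsize = cfg$cell_size * 4)

  undulation <- grid_raster(
    scale_to_range(smooth_field(nr, nc, 2 * sc, cfg$seed + 16L), 120) - 60,
    cellsize = cfg$cell_size)

  mask_vals <- matrix(0, nr, nc)
  m <- cfg$region_margin
  if (nr > 2 * m && nc > 2 * m)
    mask_vals[(m + 1):(nr - m), (m + 1):(nc - m)] <- 1
  region_mask <- grid_raster(mask_vals, cellsize = cfg$cell_size)

  g <- function(v) grid_raster(v, cellsize = cfg$cell_size)
  env <- build_env_stack(dem, g(landcover), g(geology), g(ibex), g(chamois),
                         wind_100m)
  list(env = env, wind_100m = wind_100m, undulation = undulation,
       region_mask = region_mask, dem = dem)
}

#' Planar-to-geographic mapping of the synthetic world
#'
#' The synthetic world lives in planar metres; the daylight filter needs
#' latitude/longitude. This returns the linearised mapping anchored at the
#' grid origin (`ref_lat`, `ref_lon`).
#'
#' @param cfg a [world_config()].
#' @return function of `(x, y)` returning `list(lat, lon)`.
#' @export
world_latlon <- function(cfg) {
  m_per_deg <- 111320
  function(x, y) {
    list(lat = cfg$ref_lat + y / m_per_deg,
         lon = cfg$ref_lon + x / (m_per_deg * cos(cfg$ref_lat * pi / 180)))
  }
}

# UTC timestamp for a given date and local *solar* time (hours) at lon
solar_time_utc <- function(date, local_hours, lon) {
  as.POSIXct(as.numeric(as.POSIXct(date, tz = "UTC")) +
               (local_hours - lon / 15) * 3600,
             origin = "1970-01-01", tz = "UTC")
}

#' Generate GPS tracks with a known low-flight generating process
#'
#' Per bird: a fledge date, then time-ordered fixes on either a sparse
#' (one fix per 1-15 min) or a 1 Hz burst schedule, placed on random valid
#' cells. The true low-flight probability at each fix is
#' `plogis(intercept + beta . features)`, with the continuous features
#' standardized by their world-wide mean/sd; the binary label is drawn from
#' it, true AGL is uniform on \\[0, 200) for label 1 and \\[200, 1500) for
#' label 0, and the reported altitude adds vertical GPS noise and (for
#' ellipsoid-datum birds) the geoid undulation. Contaminated fixes —
#' night-time, perched, bad-quality, early post-release and out-of-region —
#' are injected at the configured rates and flagged, so the cleaning
#' filters' per-stage removals can be audited exactly.
#'
#' @param cfg a [world_config()].
#' @param world result of [generate_env_stack()].
#' @return list with `fixes` (data.frame in the track interchange layout
#'   plus hidden truth columns `contam`, `true_prob`, `true_label`,
#'   `agl_true`), `meta` (bird_id, fledge_date), and `truth` (generating
#'   `beta`, `intercept`, standardization stats, per-clean-fix
#'   probabilities/labels and a Monte-Carlo `bayes_auc`).
#' @export
generate_tracks <- function(cfg, world) {
  validate_world_config(cfg)
  env <- world$env
  valid <- Reduce(`&`, lapply(env, function(b) !is.na(b$values)))
  valid <- valid & world$region_mask$values == 1
  valid_cells <- which(valid)
  if (!length(valid_cells)) stop("generate_tracks: no valid cells in world")
  margin_cells <- which(world$region_mask$values == 0 &
                          !is.na(env$elevation$values))

  # world-level standardization for the generating logit
  gen_stats <- fit_normalizer(
    encode_cells(env,
                 row(env$elevation$values)[valid_cells],
                 col(env$elevation$values)[valid_cells]))

  n_burst <- round(cfg$burst_fraction * cfg$n_birds)
  out <- withr::with_seed(cfg$seed + 1000L, {
    all_fixes <- list()
    meta <- data.frame(bird_id = sprintf("SB%02d", seq_len(cfg$n_birds)),
                       fledge_date = cfg$base_date +
                         sample(0:14, cfg$n_birds, replace = TRUE))
    for (b in seq_len(cfg$n_birds)) {
      bird <- meta$bird_id[b]
      fledge <- meta$fledge_date[b]
      is_burst <- b <= n_burst
      n <- cfg$fixes_per_bird

      # --- clean fixes -------------------------------------------------
      cells <- sample(valid_cells, n, replace = TRUE)
      rr <- row(valid)[cells]; cc <- col(valid)[cells]
      ctr <- cell_centres(env$elevation)
      x <- ctr$x[cells] + stats::runif(n, -0.49, 0.49) * cfg$cell_size
      y <- ctr$y[cells] + stats::runif(n, -0.49, 0.49) * cfg$cell_size
      feats <- apply_normalizer(encode_cells(env, rr, cc), gen_stats)
      eta <- cfg$intercept + drop(feats %*% cfg$beta)
      prob <- stats::plogis(eta)
      label <- stats::rbinom(n, 1, prob)
      agl <- ifelse(label == 1, stats::runif(n, 0, 200),
                    stats::runif(n, 200, 1500))
      ts <- schedule_times(n, fledge + 70, is_burst, cfg$burst_length,
                           world_latlon(cfg)(x[1], y[1])$lon)
      clean <- data.frame(
        bird_id = bird, timestamp = ts, x = x, y = y,
        agl_true = agl, ground_speed = stats::runif(n, 2.5, 18),
        contam = "none", true_prob = prob, true_label = label,
        stringsAsFactors = FALSE)

      # --- contamination ----------------------------------------------
      contam <- list(
        night = make_contam(cfg, env, valid_cells, round(cfg$night_fraction * n),
                            bird, fledge, "night"),
        perched = make_contam(cfg, env, valid_cells, round(cfg$perched_fraction * n),
                              bird, fledge, "perched"),
        quality = make_contam(cfg, env, valid_cells,
                              round(cfg$bad_quality_fraction * n),
                              bird, fledge, "quality"),
        post_release = make_contam(cfg, env, valid_cells,
                                   round(cfg$post_release_fraction * n),
                                   bird, fledge, "post_release"),
        out_of_region = make_contam(cfg, env, margin_cells,
                                    round(cfg$out_of_region_fraction * n),
                                    bird, fledge, "out_of_region"))
      fx <- rbind(clean, do.call(rbind, contam))

      # quality fields: odd birds report HDOP, even birds position error
      nfx <- nrow(fx)
      if (b %% 2 == 1) {
        fx$hdop <- stats::runif(nfx, 0.5, 5)
        fx$position_error <- NA_real_
        fx$hdop[fx$contam == "quality"] <- stats::runif(sum(fx$contam == "quality"), 10, 20)
      } else {
        fx$hdop <- NA_real_
        fx$position_error <- stats::runif(nfx, 1, 20)
        fx$position_error[fx$contam == "quality"] <-
          stats::runif(sum(fx$contam == "quality"), 30, 100)
      }

      # reported altitude: true MSL + vertical noise (+ undulation if
      # the bird's device reports ellipsoidal heights)
      elev <- raster_sample(env$elevation, fx$x, fx$y)
      alt_msl <- elev + fx$agl_true + stats::rnorm(nfx, 0, cfg$vertical_noise_sd)
      ell <- b <= round(cfg$ellipsoid_fraction * cfg$n_birds)  # deterministic split
      if (ell) {
        und <- raster_sample(world$undulation, fx$x, fx$y)
        fx$altitude_raw <- alt_msl + und
        fx$altitude_datum <- "ellipsoid"
      } else {
        fx$altitude_raw <- alt_msl
        fx$altitude_datum <- "msl"
      }
      fx <- fx[order(fx$timestamp), ]
      all_fixes[[b]] <- fx
    }
    list(fixes = do.call(rbind, all_fixes), meta = meta)
  })
  fixes <- out$fixes
  rownames(fixes) <- NULL

  clean_mask <- fixes$contam == "none"
  bayes <- bayes_auc(fixes$true_prob[clean_mask], n_draws = 20,
                     seed = cfg$seed + 2000L)
  truth <- list(beta = cfg$beta, intercept = cfg$intercept,
                gen_stats = gen_stats,
                prob = fixes$true_prob[clean_mask],
                label = fixes$true_label[clean_mask],
                bayes_auc = bayes)
  list(fixes = fixes, meta = out$meta, truth = truth)
}

# timestamps for one bird: sparse (1-15 min gaps) or 1 Hz bursts, kept
# inside the 07:00-17:00 local-solar daylight window
schedule_times <- function(n, start_date, is_burst, burst_length, lon) {
  times <- numeric(n)
  day <- 0; hours <- 7
  i <- 1
  while (i <= n) {
    if (is_burst) {
      run <- min(burst_length, n - i + 1)
      base <- as.numeric(solar_time_utc(start_date + day, hours, lon))
      times[i:(i + run - 1)] <- base + seq_len(run) - 1
      i <- i + run
      hours <- hours + run / 3600 + stats::runif(1, 5, 15) / 60
    } else {
      times[i] <- as.numeric(solar_time_utc(start_date + day, hours, lon))
      i <- i + 1
      hours <- hours + stats::runif(1, 1, 15) / 60
    }
    if (hours > 17) { hours <- 7; day <- day + 1 }
  }
  as.POSIXct(times, origin = "1970-01-01", tz = "UTC")
}

# one block of contaminated fixes of a given kind
make_contam <- function(cfg, env, cells_pool, n, bird, fledge, kind) {
  if (n <= 0 || !length(cells_pool)) return(NULL)
  cells <- sample(cells_pool, n, replace = TRUE)
  ctr <- cell_centres(env$elevation)
  x <- ctr$x[cells] + stats::runif(n, -0.49, 0.49) * cfg$cell_size
  y <- ctr$y[cells] + stats::runif(n, -0.49, 0.49) * cfg$cell_size
  lon <- world_latlon(cfg)(x, y)$lon
  day_offsets <- sample(0:40, n, replace = TRUE)
  hours <- stats::runif(n, 8, 16)                    # daylight by default
  base_date <- fledge + 70
  if (kind == "night") hours <- stats::runif(n, 0, 1.5)  # local solar midnight
  if (kind == "post_release") base_date <- fledge
  ts <- solar_time_utc(base_date, 0, 0) + day_offsets * 86400 +
    (hours - lon / 15) * 3600
  if (kind == "post_release")  # strictly inside the eight-week window
    ts <- solar_time_utc(fledge, 0, 0) + sample(0:54, n, replace = TRUE) * 86400 +
      (hours - lon / 15) * 3600
  speed <- stats::runif(n, 2.5, 18)
  agl <- stats::runif(n, 200, 1500)
  if (kind == "perched") {
    speed <- stats::runif(n, 0, 1.5)
    agl <- stats::runif(n, 0, 80)
  }
  data.frame(bird_id = bird, timestamp = as.POSIXct(ts, tz = "UTC"),
             x = x, y = y, agl_true = agl, ground_speed = speed,
             contam = kind, true_prob = NA_real_, true_label = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Monte-Carlo Bayes AUC of the generating process
#'
#' The discrimination achievable by the *true* probabilities: labels are
#' drawn from them, the rank-based AUC of probability-vs-label is computed,
#' and the result is averaged over draws. This is the ceiling against which
#' a trained classifier's AUC is judged.
#'
#' @param prob per-fix true probabilities.
#' @param n_draws Monte-Carlo label draws.
#' @param seed integer seed.
#' @return scalar in \\[0.5, 1\\].
#' @export
bayes_auc <- function(prob, n_draws = 20, seed = 1) {
  withr::with_seed(seed, {
    mean(vapply(seq_len(n_draws), function(i) {
      lab <- stats::rbinom(length(prob), 1, prob)
      if (length(unique(lab)) < 2) return(NA_real_)
      auc(lab, prob)
    }, numeric(1)), na.rm = TRUE)
  })
}

#' Write / read tracks in the delimited interchange format
#'
#' Tab-separated with header `bird_id, timestamp (ISO-8601 UTC), x, y,
#' altitude, altitude_datum, ground_speed_ms, hdop, position_error_m`;
#' empty fields allowed for hdop/position_error.
#'
#' @param fixes fixes data.frame (as from [generate_tracks()]).
#' @param path output file.
#' @export
write_tracks <- function(fixes, path) {
  out <- data.frame(
    bird_id = fixes$bird_id,
    timestamp = format(fixes$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    x = fixes$x, y = fixes$y,
    altitude = fixes$altitude_raw,
    altitude_datum = fixes$altitude_datum,
    ground_speed_ms = fixes$ground_speed,
    hdop = fixes$hdop, position_error_m = fixes$position_error)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  data.frame(
    bird_id = d$bird_id,
    timestamp = as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%OSZ",
                           tz = "UTC"),
    x = d$x, y = d$y, altitude_raw = d$altitude,
    altitude_datum = d$altitude_datum, ground_speed = d$ground_speed_ms,
    hdop = d$hdop, position_error = d$position_error_m,
    stringsAsFactors = FALSE)
}

#' Write / read per-bird metadata (bird_id, fledge_date)
#' @param meta data.frame with `bird_id`, `fledge_date`.
#' @param path file path.
#' @export
write_bird_meta <- function(meta, path) {
  utils::write.table(
    data.frame(bird_id = meta$bird_id,
               fledge_date = format(meta$fledge_date, "%Y-%m-%d")),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bird_meta
#' @export
read_bird_meta <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  d$fledge_date <- as.Date(d$fledge_date)
  d
}
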