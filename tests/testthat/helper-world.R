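# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small contaminated world: exercises every cleaning stage
small_world <- function() {
  cached("small_world", function() {
    cfg <- world_config(grid_rows = 60, grid_cols = 60, n_birds = 6,
                        fixes_per_bird = 600, burst_fraction = 0.34,
                        night_fraction = 0.05, perched_fraction = 0.05,
                        bad_quality_fraction = 0.05,
                        post_release_fraction = 0.04,
                        out_of_region_fraction = 0.03, seed = 42)
    dem <- generate_dem(cfg)
    world <- generate_env_stack(cfg, dem)
    tracks <- generate_tracks(cfg, world)
    list(cfg = cfg, world = world, tracks = tracks)
  })
}

# clean world + trained model for parameter-recovery / mapping checks
recovery_fixture <- function() {
  cached("recovery_fixture", function() {
    cfg <- world_config(grid_rows = 70, grid_cols = 70, n_birds = 6,
                        fixes_per_bird = 1500, burst_fraction = 0,
                        night_fraction = 0, perched_fraction = 0,
                        bad_quality_fraction = 0, seed = 99)
    dem <- generate_dem(cfg)
    world <- generate_env_stack(cfg, dem)
    tracks <- generate_tracks(cfg, world)
    cl <- clean_tracks(tracks$fixes, tracks$meta, world$dem,
                       world$undulation, world$region_mask,
                       world_latlon(cfg))
    fm <- extract_features(cl$fixes, world$env)
    mcfg <- model_config(units1 = 32, units2 = 16, dropout_rate = 0.3,
                         max_epochs = 40, patience = 10, seed = 3)
    tr <- split_train_val(nrow(fm$features), seed = 5)
    ns <- fit_normalizer(fm$features[tr, , drop = FALSE])
    xz <- apply_normalizer(fm$features, ns)
    fit <- train_network(init_network(mcfg), xz[tr, ], fm$labels[tr],
                         xz[!tr, ], fm$labels[!tr], mcfg)
    model <- fit$model
    model$norm_stats <- ns
    list(cfg = cfg, world = world, tracks = tracks, clean = cl, fm = fm,
         split = tr, ns = ns, xz = xz, model = model, log = fit$log,
         val_auc = auc(fm$labels[!tr], predict(model, xz[!tr, ])))
  })
}

# cleaned small world (cleaning is deterministic; cached for reuse)
small_world_clean <- function() {
  cached("small_world_clean", function() {
    sw <- small_world()
    cl <- clean_tracks(sw$tracks$fixes, sw$tracks$meta, sw$world$dem,
                       sw$world$undulation, sw$world$region_mask,
                       world_latlon(sw$cfg))
    fm <- extract_features(cl$fixes, sw$world$env)
    list(clean = cl, fm = fm)
  })
}

# leave-one-bird-out CV on the small world (fixed-epoch protocol)
loo_cv_fixture <- function() {
  cached("loo_cv", function() {
    fm <- small_world_clean()$fm
    cfg <- model_config(units1 = 16, units2 = 8, dropout_rate = 0.2,
                        batch_size = 256, seed = 2)
    list(fm = fm, cv = loo_bird_cv(fm$features, fm$labels, fm$bird_id,
                                   cfg, epochs = 8))
  })
}

# spatial-block CV on the clean recovery world
block_cv_fixture <- function() {
  cached("block_cv", function() {
    rf <- recovery_fixture()
    blocks <- make_blocks(rf$world$region_mask, side_m = 350, n_folds = 5,
                          seed = 8)
    cfg <- model_config(units1 = 16, units2 = 8, dropout_rate = 0.2,
                        batch_size = 512, seed = 21)
    cv <- block_cv(rf$fm$features, rf$fm$labels, rf$fm$x, rf$fm$y, blocks,
                   cfg, epochs = 10)
    list(blocks = blocks, cv = cv)
  })
}

# exact linear-logistic network: p = plogis(intercept + beta . x), built
# from relu pairs (relu(s) - relu(-s) = s); used as an analytic oracle
# model whose predictions are known in closed form
linear_logistic_model <- function(beta, intercept = 0,
                                  norm_stats = NULL) {
  cfg <- model_config(units1 = 2, units2 = 2, dropout_rate = 0, seed = 1)
  model <- init_network(cfg, n_inputs = length(beta))
  model$params <- list(
    W1 = cbind(beta, -beta), b1 = c(intercept, -intercept),
    W2 = matrix(c(1, -1, -1, 1), 2, 2), b2 = c(0, 0),
    W3 = matrix(c(1, -1), 2, 1), b3 = 0)
  model$norm_stats <- norm_stats
  model
}

# analytic tilted plane z = fx * x + fy * y (y increasing northwards)
plane_raster <- function(nr, nc, h, fx, fy) {
  cc_x <- outer(rep(1, nr), (seq_len(nc) - 0.5) * h)
  cc_y <- outer((nr:1 - 0.5) * h, rep(1, nc))
  grid_raster(fx * cc_x + fy * cc_y, cellsize = h)
}

# flat 20x20 DEM world pieces for the hand-built toy track
toy_rasters <- function() {
  m <- matrix(1000, 20, 20)
  dem <- grid_raster(m, cellsize = 25)
  undulation <- grid_raster(matrix(50, 20, 20), cellsize = 25)
  mask_vals <- matrix(1, 20, 20)
  mask_vals[20, 1] <- 0                     # cell [0,25) x [0,25) is out
  mask <- grid_raster(mask_vals, cellsize = 25)
  list(dem = dem, undulation = undulation, mask = mask)
}

# equatorial mapping: daylight is decided purely by UTC clock time
equator_latlon <- function(x, y) list(lat = 0 * x, lon = 0 * x)

utc <- function(s) as.POSIXct(s, tz = "UTC")

# raw-fix row constructor with clean defaults (noon, good quality, flying)
toy_fix <- function(timestamp = utc("2020-06-10 12:00:00"), x = 200, y = 200,
                    altitude_raw = 1500, altitude_datum = "msl",
                    ground_speed = 5, hdop = NA_real_,
                    position_error = NA_real_, bird_id = "T1") {
  data.frame(bird_id = bird_id, timestamp = timestamp, x = x, y = y,
             altitude_raw = altitude_raw, altitude_datum = altitude_datum,
             ground_speed = ground_speed, hdop = hdop,
             position_error = position_error, stringsAsFactors = FALSE)
}
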