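#' @title Terrain predictors and feature encoding
#' @description Derivation of the topographic predictor bands used by the
#'   low-flight model — slope, aspect (encoded as eastness/northness),
#'   topographic position index (TPI) and slope unevenness — together with
#'   wind resampling, the observation-to-feature-matrix encoding, the
#'   train-split normalizer and the Spearman collinearity screen.
#' @name terrain
NULL

# shift a matrix by (dr, dc), padding with NA
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

#' Slope and aspect from a DEM (Horn's method)
#'
#' Computes slope (degrees) and aspect (clockwise from north) from the
#' standard 3x3 Horn finite differences, then encodes aspect as
#' `eastness = sin(aspect)` and `northness = cos(aspect)` — the
#' circular-safe exposure encoding. Flat cells get eastness = northness =
#' 0; border cells (and cells with any missing neighbour) are nodata.
#'
#' @param dem a `grid_raster` elevation band (m), at least 3x3.
#' @return list of `grid_raster`s: `slope`, `eastness`, `northness`.
#' @export
slope_aspect <- function(dem) {
  z <- dem$values
  if (nrow(z) < 3 || ncol(z) < 3)
    stop("slope_aspect: DEM must be at least 3x3")
  h <- dem$cellsize
  # 3x3 neighbours; rows top-down so row-1 is north
  nw <- shift_mat(z, -1, -1); n  <- shift_mat(z, -1, 0); ne <- shift_mat(z, -1, 1)
  w  <- shift_mat(z,  0, -1);                             e  <- shift_mat(z,  0, 1)
  sw <- shift_mat(z,  1, -1); s  <- shift_mat(z,  1, 0); se <- shift_mat(z,  1, 1)
  dzdx <- ((ne + 2 * e + se) - (nw + 2 * w + sw)) / (8 * h)   # eastward
  dzdy <- ((nw + 2 * n + ne) - (sw + 2 * s + se)) / (8 * h)   # northward
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  # steepest-descent direction, clockwise from north
  east_c <- -dzdx; north_c <- -dzdy
  len <- sqrt(east_c^2 + north_c^2)
  eastness <- ifelse(len > 0, east_c / len, 0)
  northness <- ifelse(len > 0, north_c / len, 0)
  eastness[is.na(slope)] <- NA_real_
  northness[is.na(slope)] <- NA_real_
  g <- function(m) grid_raster(m, dem$xmin, dem$ymin, dem$cellsize)
  list(slope = g(slope), eastness = g(eastness), northness = g(northness))
}

# centre-excluded mean of the 8 neighbours (9-pixel moving window)
neighbour_mean <- function(m) {
  acc <- shift_mat(m, -1, -1) + shift_mat(m, -1, 0) + shift_mat(m, -1, 1) +
    shift_mat(m, 0, -1) + shift_mat(m, 0, 1) +
    shift_mat(m, 1, -1) + shift_mat(m, 1, 0) + shift_mat(m, 1, 1)
  acc / 8
}

#' Topographic position index
#'
#' Per cell: elevation minus the mean elevation of its eight neighbours
#' (centre excluded, 9-pixel window). Positive on ridges, negative in
#' valleys, zero on any plane. Border cells and cells adjacent to nodata
#' are nodata.
#'
#' @param dem a `grid_raster` elevation band.
#' @return a `grid_raster` of TPI values (m).
#' @export
tpi <- function(dem) {
  grid_raster(dem$values - neighbour_mean(dem$values),
              dem$xmin, dem$ymin, dem$cellsize)
}

#' Slope unevenness
#'
#' The TPI operator applied to the slope band: a cell's slope relative to
#' the mean slope of its surrounding terrain (same 9-pixel window).
#'
#' @param slope_raster slope band from [slope_aspect()] (degrees).
#' @return a `grid_raster` of slope-unevenness values (degrees).
#' @export
slope_unevenness <- function(slope_raster) tpi(slope_raster)

#' Resample a coarse wind band onto the model grid
#'
#' Bilinear interpolation of the 100 m wind-speed band onto the 25 m model
#' grid. Query points beyond the outermost coarse-cell centres are clamped
#' (constant extrapolation at the edge), which preserves the input range.
#'
#' @param wind_100m coarse `grid_raster` (wind speed at 100 m a.g.l., m/s).
#' @param target_grid a `grid_raster` defining the output geometry.
#' @param tol allowed extent mismatch, in units of coarse cells.
#' @return a `grid_raster` on the target grid.
#' @export
resample_wind <- function(wind_100m, target_grid, tol = 1) {
  if (wind_100m$cellsize < target_grid$cellsize)
    stop("resample_wind: wind grid must be coarser than the target grid")
  ec <- raster_extent(wind_100m); et <- raster_extent(target_grid)
  if (any(abs(ec - et) > tol * wind_100m$cellsize))
    stop("resample_wind: grids misaligned beyond tolerance")
  nrc <- nrow(wind_100m$values); ncc <- ncol(wind_100m$values)
  xs <- wind_100m$xmin + (seq_len(ncc) - 0.5) * wind_100m$cellsize
  ymax <- wind_100m$ymin + nrc * wind_100m$cellsize
  ys_desc <- ymax - (seq_len(nrc) - 0.5) * wind_100m$cellsize
  ys <- rev(ys_desc)                      # ascending for interp2
  zz <- wind_100m$values[nrc:1, , drop = FALSE]
  cc <- cell_centres(target_grid)
  xp <- pmin(pmax(as.vector(cc$x), min(xs)), max(xs))
  yp <- pmin(pmax(as.vector(cc$y), min(ys)), max(ys))
  vals <- pracma::interp2(xs, ys, zz, xp, yp, method = "linear")
  grid_raster(matrix(vals, nrow(target_grid$values), ncol(target_grid$values)),
              target_grid$xmin, target_grid$ymin, target_grid$cellsize)
}

#' Assemble the co-registered environmental stack
#'
#' Derives the topographic bands from the DEM, resamples wind onto the
#' model grid, and bundles everything into an `env_stack`: a named list of
#' co-registered bands (elevation, landcover, geology, eastness, northness,
#' slope, slope_unev, tpi, ibex, chamois, windspeed).
#'
#' @param dem elevation `grid_raster` (m).
#' @param landcover categorical band, class codes 1-10.
#' @param geology categorical band, class codes 1-4.
#' @param ibex,chamois occurrence-probability bands in \\[0,1\\].
#' @param wind_100m coarse wind band (resampled internally).
#' @return an `env_stack`.
#' @export
build_env_stack <- function(dem, landcover, geology, ibex, chamois, wind_100m) {
  sa <- slope_aspect(dem)
  bands <- list(
    elevation = dem, landcover = landcover, geology = geology,
    eastness = sa$eastness, northness = sa$northness, slope = sa$slope,
    slope_unev = slope_unevenness(sa$slope), tpi = tpi(dem),
    ibex = ibex, chamois = chamois,
    windspeed = resample_wind(wind_100m, dem)
  )
  for (nm in names(bands))
    stopifnot_same_grid(dem, bands[[nm]], paste("band", nm, "and DEM"))
  structure(bands, class = "env_stack")
}

N_LANDCOVER <- 10L
N_GEOLOGY <- 4L

#' Names of the encoded feature columns, in contract order
#'
#' Fixed column order of the 22-column feature matrix: 10 land-cover
#' indicators, 4 geology indicators, then the 8 continuous predictors.
#' Coefficient vectors and permutation-importance groups rely on this
#' order.
#' @return character vector of length 22.
#' @export
feature_names <- function() {
  c(paste0("landcover_", seq_len(N_LANDCOVER)),
    paste0("geology_", seq_len(N_GEOLOGY)),
    continuous_features())
}

#' Names of the continuous (z-scored) features
#' @return character vector of length 8.
#' @export
continuous_features <- function() {
  c("eastness", "northness", "slope", "slope_unev", "tpi",
    "ibex", "chamois", "windspeed")
}

# one-hot expansion of an integer code vector into n_class columns
one_hot <- function(codes, n_class, prefix) {
  m <- matrix(0, length(codes), n_class,
              dimnames = list(NULL, paste0(prefix, "_", seq_len(n_class))))
  ok <- !is.na(codes) & codes >= 1 & codes <= n_class
  m[cbind(which(ok), as.integer(codes[ok]))] <- 1
  m[!ok, ] <- NA_real_
  m
}

#' Encode raster cells into the 22-column feature space
#'
#' @param env an `env_stack`.
#' @param row,col integer cell indices (vectors of equal length).
#' @return numeric matrix, one row per cell; rows with any nodata band are
#'   all-`NA`.
#' @export
encode_cells <- function(env, row, col) {
  idx <- cbind(row, col)
  lc <- one_hot(env$landcover$values[idx], N_LANDCOVER, "landcover")
  ge <- one_hot(env$geology$values[idx], N_GEOLOGY, "geology")
  cont <- vapply(continuous_features(),
                 function(nm) env[[nm]]$values[idx], numeric(nrow(idx)))
  if (nrow(idx) == 1) cont <- matrix(cont, 1, dimnames = list(NULL, continuous_features()))
  m <- cbind(lc, ge, cont)
  m[apply(is.na(m), 1, any), ] <- NA_real_
  m
}

#' Join cleaned fixes to the environmental stack
#'
#' Samples every band at each fix's containing cell, one-hot encodes the
#' categorical bands, and labels each fix 1 if its altitude above ground is
#' strictly below the 200 m critical altitude (the rotor-swept band), else
#' 0. Fixes falling on nodata cells (or outside the grid) are dropped and
#' counted.
#'
#' @param fixes data.frame with columns `x`, `y`, `agl` (and optionally
#'   `bird_id`).
#' @param env an `env_stack`.
#' @param critical_altitude class boundary in metres above ground
#'   (default 200; AGL exactly at the boundary is class 0).
#' @return a `feature_matrix`: list with `features` (n x 22 matrix, natural
#'   scale), `labels` (0/1), `bird_id`, `x`, `y`, `agl`, and
#'   `dropped_nodata` (count of discarded fixes).
#' @export
extract_features <- function(fixes, env, critical_altitude = 200) {
  idx <- cell_index(env$elevation, fixes$x, fixes$y)
  inside <- !is.na(idx$row)
  feats <- matrix(NA_real_, nrow(fixes), length(feature_names()),
                  dimnames = list(NULL, feature_names()))
  if (any(inside))
    feats[inside, ] <- encode_cells(env, idx$row[inside], idx$col[inside])
  ok <- !apply(is.na(feats), 1, any)
  dropped <- sum(!ok)
  structure(list(
    features = feats[ok, , drop = FALSE],
    labels = as.integer(fixes$agl[ok] < critical_altitude),
    bird_id = if ("bird_id" %in% names(fixes)) fixes$bird_id[ok] else NULL,
    x = fixes$x[ok], y = fixes$y[ok], agl = fixes$agl[ok],
    dropped_nodata = dropped
  ), class = "feature_matrix")
}

#' Fit the train-split normalizer
#'
#' Mean and standard deviation of each continuous feature column, computed
#' on the training split only. Validation, test and map rows are always
#' transformed with these training statistics.
#'
#' @param train_rows numeric matrix with the 22 contract columns (or any
#'   matrix containing the continuous columns by name).
#' @return `norm_stats`: list with named `mean` and `sd` vectors.
#' @export
fit_normalizer <- function(train_rows) {
  if (nrow(train_rows) == 0) stop("fit_normalizer: empty training split")
  cols <- continuous_features()
  mu <- colMeans(train_rows[, cols, drop = FALSE])
  sd_ <- apply(train_rows[, cols, drop = FALSE], 2, stats::sd)
  zero <- names(sd_)[!is.finite(sd_) | sd_ == 0]
  if (length(zero))
    stop("fit_normalizer: zero-variance column(s): ",
         paste(zero, collapse = ", "))
  structure(list(mean = mu, sd = sd_), class = "norm_stats")
}

#' Apply the normalizer (z-score the continuous columns)
#'
#' @param rows numeric matrix with the contract columns.
#' @param norm_stats result of [fit_normalizer()].
#' @return matrix with the 8 continuous columns z-scored; one-hot columns
#'   untouched.
#' @export
apply_normalizer <- function(rows, norm_stats) {
  cols <- continuous_features()
  rows[, cols] <- sweep(sweep(rows[, cols, drop = FALSE], 2,
                              norm_stats$mean, "-"),
                        2, norm_stats$sd, "/")
  rows
}

#' Pairwise Spearman collinearity screen
#'
#' Spearman rank correlations between all pairs of the 8 continuous bands,
#' computed over randomly sampled non-nodata cells. Pairs at or above the
#' threshold are flagged with a warning.
#'
#' @param env an `env_stack`.
#' @param n_samples number of random cells (default 10000).
#' @param threshold flag level on `|r_s|` (default 0.6).
#' @param seed integer seed for the cell sample.
#' @return list with `correlations` (8x8 matrix), `flagged` (data.frame of
#'   pairs at/above threshold) and `n_sampled`.
#' @export
collinearity_screen <- function(env, n_samples = 10000, threshold = 0.6,
                                seed = 1) {
  cols <- continuous_features()
  valid <- Reduce(`&`, lapply(cols, function(nm) !is.na(env[[nm]]$values)))
  idx_all <- which(valid)
  n <- min(n_samples, length(idx_all))
  sel <- withr::with_seed(seed, sample(idx_all, n))
  vals <- vapply(cols, function(nm) env[[nm]]$values[sel], numeric(n))
  cm <- stats::cor(vals, method = "spearman")
  ut <- which(upper.tri(cm) & abs(cm) >= threshold, arr.ind = TRUE)
  flagged <- data.frame(var1 = cols[ut[, 1]], var2 = cols[ut[, 2]],
                        r_s = cm[ut])
  if (nrow(flagged))
    warning("collinearity screen: |r_s| >= ", threshold, " for ",
            paste(flagged$var1, flagged$var2, sep = "~", collapse = ", "))
  list(correlations = cm, flagged = flagged, n_sampled = n)
}
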