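#' @title Model evaluation suite
#' @description AUC, the hyperparameter grid search, leave-one-bird-out and
#'   spatial-block cross-validation, variogram-based block-size estimation,
#'   grouped permutation importance, and ICE/partial-dependence effect
#'   curves.
#' @name evalsuite
NULL

#' Rank-based AUC (Mann-Whitney)
#'
#' Probability that a random positive scores above a random negative, with
#' ties counted one half — computed from midranks, so it equals exhaustive
#' pairwise concordance.
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores numeric scores.
#' @return AUC in \\[0, 1\\].
#' @export
auc <- function(labels, scores) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("auc: both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' 70/30 train/validation split
#'
#' Seeded random split over fixes (the default), or stratified by bird so
#' that all of a bird's fixes land in one side.
#'
#' @param n number of rows (or a vector of bird ids when `by_bird`).
#' @param train_frac training share (default 0.7).
#' @param seed integer seed.
#' @param by_bird split whole birds instead of fixes.
#' @return logical vector, `TRUE` = training row.
#' @export
split_train_val <- function(n, train_frac = 0.7, seed = 1, by_bird = FALSE) {
  if (by_bird) {
    birds <- n
    ub <- unique(birds)
    tr <- withr::with_seed(seed,
      sample(ub, max(1, round(train_frac * length(ub)))))
    birds %in% tr
  } else {
    idx <- withr::with_seed(seed, sample.int(n))
    seq_len(n) %in% idx[seq_len(round(train_frac * n))]
  }
}

#' Hyperparameter grid specification
#'
#' The default grid doubles the hidden-layer widths independently from 16
#' to 512 and steps the dropout rate from 0.2 to 0.7 by 0.1 — 6 x 6 x 6 =
#' 216 configurations.
#'
#' @param units1_values,units2_values candidate hidden-layer widths.
#' @param dropout_values candidate dropout rates.
#' @return a `grid_spec` list.
#' @export
grid_spec <- function(units1_values = c(16, 32, 64, 128, 256, 512),
                      units2_values = c(16, 32, 64, 128, 256, 512),
                      dropout_values = seq(0.2, 0.7, by = 0.1)) {
  structure(list(units1_values = units1_values,
                 units2_values = units2_values,
                 dropout_values = dropout_values),
            class = "grid_spec")
}

#' Enumerate grid configurations
#' @param grid a [grid_spec()].
#' @return data.frame with one row per configuration (units1, units2,
#'   dropout_rate).
#' @export
grid_configs <- function(grid = grid_spec()) {
  expand.grid(units1 = grid$units1_values, units2 = grid$units2_values,
              dropout_rate = grid$dropout_values,
              KEEP.OUT.ATTRS = FALSE)
}

#' Architecture grid search
#'
#' Trains every configuration of the grid on a fixed 70/30 split with
#' early stopping on validation AUC, and ranks configurations by that AUC.
#'
#' @param features natural-scale feature matrix (contract columns).
#' @param labels 0/1 vector.
#' @param grid a [grid_spec()].
#' @param base_cfg [model_config()] supplying everything but the gridded
#'   fields.
#' @param split_seed seed of the shared 70/30 split.
#' @return data.frame of configurations with `train_auc`, `val_auc` and
#'   `best_epoch`, sorted by decreasing validation AUC.
#' @export
grid_search <- function(features, labels, grid = grid_spec(),
                        base_cfg = model_config(), split_seed = 1) {
  cfgs <- grid_configs(grid)
  tr <- split_train_val(nrow(features), seed = split_seed)
  ns <- fit_normalizer(features[tr, , drop = FALSE])
  xz <- apply_normalizer(features, ns)
  res <- lapply(seq_len(nrow(cfgs)), function(i) {
    cfg <- base_cfg
    cfg$units1 <- as.integer(cfgs$units1[i])
    cfg$units2 <- as.integer(cfgs$units2[i])
    cfg$dropout_rate <- cfgs$dropout_rate[i]
    fit <- train_network(init_network(cfg, ncol(features)),
                         xz[tr, , drop = FALSE], labels[tr],
                         xz[!tr, , drop = FALSE], labels[!tr], cfg)
    c(train_auc = auc(labels[tr], predict(fit$model, xz[tr, , drop = FALSE])),
      val_auc = auc(labels[!tr], predict(fit$model, xz[!tr, , drop = FALSE])),
      best_epoch = attr(fit$log, "best_epoch"))
  })
  out <- cbind(cfgs, do.call(rbind, res))
  out[order(-out$val_auc), ]
}

# shared engine for the fixed-epoch CV protocols: per fold, refit the
# normalizer on the training side, train `epochs` epochs without early
# stopping, report train/test AUC
cv_engine <- function(features, labels, fold_id, cfg, epochs) {
  folds <- sort(unique(fold_id))
  rows <- lapply(folds, function(f) {
    te <- fold_id == f
    if (!any(te) || length(unique(labels[te])) < 2) {
      warning("fold ", f, " empty or single-class; test AUC undefined")
      return(data.frame(fold = f, n_test = sum(te),
                        train_auc = NA_real_, test_auc = NA_real_))
    }
    ns <- fit_normalizer(features[!te, , drop = FALSE])
    xz <- apply_normalizer(features, ns)
    cfg2 <- cfg; cfg2$max_epochs <- as.integer(epochs)
    fit <- train_network(init_network(cfg2, ncol(features)),
                         xz[!te, , drop = FALSE], labels[!te],
                         cfg = cfg2, early_stopping = FALSE)
    data.frame(fold = f, n_test = sum(te),
               train_auc = auc(labels[!te],
                               predict(fit$model, xz[!te, , drop = FALSE])),
               test_auc = auc(labels[te],
                              predict(fit$model, xz[te, , drop = FALSE])))
  })
  per_fold <- do.call(rbind, rows)
  structure(list(
    per_fold = per_fold,
    mean_train_auc = mean(per_fold$train_auc, na.rm = TRUE),
    sd_train_auc = stats::sd(per_fold$train_auc, na.rm = TRUE),
    mean_test_auc = mean(per_fold$test_auc, na.rm = TRUE),
    sd_test_auc = stats::sd(per_fold$test_auc, na.rm = TRUE)),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("CV over %d folds: train AUC %.3f (sd %.3f), test AUC %.3f (sd %.3f)\n",
              nrow(x$per_fold), x$mean_train_auc, x$sd_train_auc,
              x$mean_test_auc, x$sd_test_auc))
  invisible(x)
}

#' Leave-one-bird-out cross-validation
#'
#' One model per bird: trained on all other birds' fixes for a fixed
#' number of epochs (20, no early stopping), evaluated on the held-out
#' bird. A held-out bird whose fixes are single-class gets an undefined
#' test AUC (excluded from the mean, with a warning).
#'
#' @param features natural-scale feature matrix.
#' @param labels 0/1 vector.
#' @param bird_id per-row bird identifiers (>= 2 birds).
#' @param cfg the selected [model_config()].
#' @param epochs fixed epoch count (default 20).
#' @return a `cv_result` with one row per bird.
#' @export
loo_bird_cv <- function(features, labels, bird_id, cfg = model_config(),
                        epochs = 20) {
  if (length(unique(bird_id)) < 2)
    stop("loo_bird_cv: need at least 2 birds")
  cv_engine(features, labels, as.character(bird_id), cfg, epochs)
}

#' Estimate the spatial-block size from variogram ranges
#'
#' Per continuous band: an empirical semivariogram from sampled cell
#' pairs, binned into log-spaced lags and fit with an exponential model
#' `gamma(h) = c0 + c1 (1 - exp(-h/a))` by weighted least squares (bin
#' counts as weights; the length scale is profiled over a log grid with
#' the partial sill solved per candidate). The practical range is 3a; the
#' recommended block side is the median of the per-band ranges. Constant
#' bands are skipped with a warning.
#'
#' @param env an `env_stack`.
#' @param n_points cells sampled per band (all pairs are used).
#' @param n_bins number of log-spaced lag bins (default 15).
#' @param seed integer seed for the cell sample.
#' @return list with `per_band` (data.frame band/range_m) and
#'   `recommended_m` (median range).
#' @export
estimate_block_size <- function(env, n_points = 800, n_bins = 15, seed = 1) {
  bands <- continuous_features()
  ref <- env$elevation
  valid <- Reduce(`&`, lapply(bands, function(nm) !is.na(env[[nm]]$values)))
  cells <- which(valid)
  n <- min(n_points, length(cells))
  sel <- withr::with_seed(seed, sample(cells, n))
  ctr <- cell_centres(ref)
  px <- ctr$x[sel]; py <- ctr$y[sel]
  d <- as.vector(stats::dist(cbind(px, py)))
  ranges <- vapply(bands, function(nm) {
    v <- env[[nm]]$values[sel]
    if (stats::sd(v) == 0) {
      warning("estimate_block_size: constant band ", nm, " skipped")
      return(NA_real_)
    }
    sv <- as.vector(stats::dist(v))^2 / 2
    fit_variogram_range(d, sv, ref$cellsize, n_bins)
  }, numeric(1))
  per_band <- data.frame(band = bands, range_m = ranges)
  list(per_band = per_band,
       recommended_m = stats::median(ranges, na.rm = TRUE))
}

# WLS exponential-variogram fit; returns the practical range 3a. The
# length scale is profiled over a log grid (smallest candidate within 1%
# of the minimum SSE, so ties collapse to the short end); if the fitted
# partial sill explains < 10% of the total sill the band is treated as
# pure nugget and the range collapses to the cell scale.
fit_variogram_range <- function(d, sv, cellsize, n_bins) {
  breaks <- exp(seq(log(max(cellsize / 2, min(d[d > 0]))),
                    log(max(d)), length.out = n_bins + 1))
  bin <- cut(d, breaks, include.lowest = TRUE, labels = FALSE)
  ok <- !is.na(bin)
  h <- as.numeric(tapply(d[ok], bin[ok], mean))
  g <- as.numeric(tapply(sv[ok], bin[ok], mean))
  w <- as.numeric(tapply(sv[ok], bin[ok], length))
  keep <- is.finite(h) & is.finite(g)
  h <- h[keep]; g <- g[keep]; w <- w[keep]
  cand <- exp(seq(log(cellsize / 4), log(max(h)), length.out = 60))
  wls_fit <- function(a) {
    basis <- 1 - exp(-h / a)
    # WLS under c0 >= 0, c1 >= 0: take the unconstrained solution when
    # feasible, else the better of the two single-term boundary fits
    cf <- stats::lm.wfit(cbind(1, basis), g, w)$coefficients
    if (!all(is.finite(cf)) || any(cf < 0)) {
      c0_only <- c(sum(w * g) / sum(w), 0)
      c1_only <- c(0, max(0, sum(w * g * basis) / sum(w * basis^2)))
      s0 <- sum(w * (g - c0_only[1])^2)
      s1 <- sum(w * (g - c1_only[2] * basis)^2)
      cf <- if (s0 <= s1) c0_only else c1_only
    }
    list(cf = cf, sse = sum(w * (g - (cf[1] + cf[2] * basis))^2))
  }
  fits <- lapply(cand, wls_fit)
  sse <- vapply(fits, function(f) f$sse, numeric(1))
  sse[!is.finite(sse)] <- Inf
  best <- which(sse <= 1.01 * min(sse))[1]
  cf <- fits[[best]]$cf
  # structure expressed inside the observed lag window; if it accounts
  # for < 10% of the sill there, the band is pure nugget
  expressed <- cf[2] * (1 - exp(-max(h) / cand[best]))
  if (expressed < 0.1 * (cf[1] + expressed)) return(3 * cand[1])
  3 * cand[best]
}

#' Build the spatial block grid
#'
#' Axis-aligned square blocks tile the region bounding box from its
#' origin; partial edge blocks are kept and treated as full blocks. Blocks
#' are dealt to folds by a seeded shuffle, balanced to within one block
#' per fold.
#'
#' @param region_mask `grid_raster` (its extent defines the tiling; only
#'   geometry is used).
#' @param side_m block side length in metres (default 10000).
#' @param n_folds number of folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @return a `block_grid`: list with `side_m`, `origin`, `n_block_rows`,
#'   `n_block_cols`, `fold_of_block` (integer vector over block index) and
#'   `block_raster` (block index per cell).
#' @export
make_blocks <- function(region_mask, side_m = 10000, n_folds = 5, seed = 1) {
  if (side_m < region_mask$cellsize)
    stop("make_blocks: block side must be at least the cell size")
  ext <- raster_extent(region_mask)
  nbx <- unname(ceiling((ext["xmax"] - ext["xmin"]) / side_m))
  nby <- unname(ceiling((ext["ymax"] - ext["ymin"]) / side_m))
  n_blocks <- nbx * nby
  if (n_blocks < n_folds)
    stop("make_blocks: fewer blocks (", n_blocks, ") than folds (",
         n_folds, ")")
  fold_of_block <- withr::with_seed(seed, {
    ord <- sample.int(n_blocks)
    f <- integer(n_blocks)
    f[ord] <- rep_len(seq_len(n_folds), n_blocks)
    f
  })
  cc <- cell_centres(region_mask)
  bx <- floor((cc$x - ext["xmin"]) / side_m)
  by <- floor((cc$y - ext["ymin"]) / side_m)
  block_vals <- by * nbx + bx + 1
  structure(list(side_m = side_m,
                 origin = c(x = unname(ext["xmin"]), y = unname(ext["ymin"])),
                 n_block_rows = nby, n_block_cols = nbx,
                 fold_of_block = fold_of_block,
                 block_raster = grid_raster(block_vals, region_mask$xmin,
                                            region_mask$ymin,
                                            region_mask$cellsize)),
            class = "block_grid")
}

#' Block and fold of point locations
#' @param blocks a `block_grid`.
#' @param x,y planar coordinates (m).
#' @return data.frame with `block` and `fold`.
#' @export
block_fold_of <- function(blocks, x, y) {
  bx <- floor((x - blocks$origin["x"]) / blocks$side_m)
  by <- floor((y - blocks$origin["y"]) / blocks$side_m)
  b <- as.integer(by * blocks$n_block_cols + bx + 1)
  bad <- bx < 0 | bx >= blocks$n_block_cols | by < 0 | by >= blocks$n_block_rows
  b[bad] <- NA_integer_
  data.frame(block = b, fold = blocks$fold_of_block[b])
}

#' Spatial-block cross-validation
#'
#' Five models (one per fold), each trained on the other folds for a
#' fixed number of epochs (20, matching the leave-one-bird-out protocol)
#' and tested on the held-out fold.
#'
#' @param features natural-scale feature matrix.
#' @param labels 0/1 vector.
#' @param x,y per-row planar coordinates.
#' @param blocks a [make_blocks()] grid.
#' @param cfg the selected [model_config()].
#' @param epochs fixed epoch count (default 20).
#' @return a `cv_result` with one row per fold.
#' @export
block_cv <- function(features, labels, x, y, blocks, cfg = model_config(),
                     epochs = 20) {
  fold <- block_fold_of(blocks, x, y)$fold
  if (anyNA(fold)) stop("block_cv: fixes outside the block grid")
  cv_engine(features, labels, fold, cfg, epochs)
}

#' Permutation-importance feature groups
#'
#' `"table1"` keeps every predictor separate (one-hot groups permuted
#' jointly); `"headline"` merges eastness+northness into `aspect` and
#' ibex+chamois into `food`, the grouping used when reporting the four
#' leading drivers.
#'
#' @param preset `"table1"` or `"headline"`.
#' @return named list of column-name vectors partitioning the 22 columns.
#' @export
importance_groups <- function(preset = c("table1", "headline")) {
  preset <- match.arg(preset)
  g <- list(
    landcover = paste0("landcover_", 1:10),
    geology = paste0("geology_", 1:4),
    eastness = "eastness", northness = "northness",
    slope = "slope", slope_unev = "slope_unev", tpi = "tpi",
    ibex = "ibex", chamois = "chamois", windspeed = "windspeed")
  if (preset == "headline") {
    g$aspect <- c("eastness", "northness")
    g$food <- c("ibex", "chamois")
    g$eastness <- g$northness <- g$ibex <- g$chamois <- NULL
  }
  g
}

#' Grouped permutation importance as AUC drop
#'
#' For each feature group, the rows of its columns are permuted jointly
#' (so one-hot groups stay intact) with a seeded shuffle, the AUC is
#' recomputed, and the drop is averaged over replicates. Reported as the
#' relative percentage drop `100 (AUC0 - AUCp) / AUC0` by default, or the
#' absolute percentage-point drop.
#'
#' @param model a trained `nn_model`.
#' @param rows normalized feature matrix (contract columns).
#' @param labels 0/1 vector.
#' @param groups named list of column groups ([importance_groups()]).
#' @param n_reps permutation replicates (default 10).
#' @param seed integer seed.
#' @param relative report `100 (AUC0 - AUCp)/AUC0` (default) instead of
#'   `100 (AUC0 - AUCp)`.
#' @return data.frame (group, auc_drop_pct) sorted by decreasing drop;
#'   attribute `auc_original`.
#' @export
permutation_importance <- function(model, rows, labels,
                                   groups = importance_groups(),
                                   n_reps = 10, seed = 1, relative = TRUE) {
  rows <- as.matrix(rows)
  unknown <- setdiff(unlist(groups), colnames(rows))
  if (length(unknown))
    stop("permutation_importance: unknown column(s): ",
         paste(unknown, collapse = ", "))
  auc0 <- auc(labels, predict(model, rows))
  drops <- vapply(names(groups), function(gn) {
    cols <- groups[[gn]]
    mean(vapply(seq_len(n_reps), function(r) {
      perm <- withr::with_seed(seed + 31L * r + sum(utf8ToInt(gn)),
                               sample.int(nrow(rows)))
      rp <- rows
      rp[, cols] <- rows[perm, cols, drop = FALSE]
      aucp <- auc(labels, predict(model, rp))
      if (relative) 100 * (auc0 - aucp) / auc0 else 100 * (auc0 - aucp)
    }, numeric(1)))
  }, numeric(1))
  out <- data.frame(group = names(groups), auc_drop_pct = unname(drops))
  out <- out[order(-out$auc_drop_pct), ]
  attr(out, "auc_original") <- auc0
  out
}

#' ICE and partial-dependence curves
#'
#' For each observation, predictions are made with the focal variable set
#' to each value of an equally spaced grid over its observed range (or to
#' each class, for a categorical group), all other variables held fixed —
#' one ICE curve per observation. The PD curve is the pointwise mean of
#' the ICE curves. Grid values are expressed on the natural scale and
#' transformed with the stored normalization statistics before prediction.
#'
#' @param model a trained `nn_model`.
#' @param rows natural-scale feature matrix (contract columns).
#' @param variable a continuous feature name, or `"landcover"`/`"geology"`.
#' @param norm_stats the model's training normalizer.
#' @param n_grid grid resolution for continuous variables (>= 2).
#' @return an `effect_curves` list: `variable`, `grid`, `ice` (n_obs x
#'   n_grid), `pd`.
#' @export
ice_pd <- function(model, rows, variable, norm_stats, n_grid = 20) {
  rows <- as.matrix(rows)
  categorical <- variable %in% c("landcover", "geology")
  if (categorical) {
    n_class <- if (variable == "landcover") N_LANDCOVER else N_GEOLOGY
    grid <- seq_len(n_class)
    cols <- paste0(variable, "_", grid)
    ice <- vapply(grid, function(k) {
      rp <- rows
      rp[, cols] <- 0
      rp[, cols[k]] <- 1
      predict(model, apply_normalizer(rp, norm_stats))
    }, numeric(nrow(rows)))
  } else {
    if (!variable %in% continuous_features())
      stop("ice_pd: unknown variable ", variable)
    if (n_grid < 2) stop("ice_pd: n_grid must be >= 2")
    rng <- range(rows[, variable])
    grid <- seq(rng[1], rng[2], length.out = n_grid)
    ice <- vapply(grid, function(v) {
      rp <- rows
      rp[, variable] <- v
      predict(model, apply_normalizer(rp, norm_stats))
    }, numeric(nrow(rows)))
  }
  if (nrow(rows) == 1) ice <- matrix(ice, 1)
  structure(list(variable = variable, grid = grid, ice = ice,
                 pd = colMeans(ice)),
            class = "effect_curves")
}
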