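#' @title Bagged probability maps and conflict products
#' @description The mapping stage: bootstrap-bagged probability surfaces
#'   with a 95% credible interval, the sensitivity-constrained threshold
#'   and binary critical-flight map, the joint occurrence-times-low-flight
#'   probability map, and the high-risk conflict map with its area-share
#'   table.
#' @name riskmap
NULL

#' Train a bagged ensemble
#'
#' The training split is resampled with replacement (same size as the
#' split) `B` times; each member is trained with early stopping (patience
#' as configured) against the shared validation split.
#'
#' @param features natural-scale feature matrix (contract columns).
#' @param labels 0/1 vector.
#' @param cfg the selected [model_config()].
#' @param B ensemble size (default 30, >= 2).
#' @param split_seed seed of the shared 70/30 split.
#' @param seed seed stream for the bootstrap resamples.
#' @return an `nn_ensemble`: list of trained `nn_model`s with the shared
#'   `norm_stats` attached.
#' @export
bagging_train <- function(features, labels, cfg = model_config(), B = 30,
                          split_seed = 1, seed = 1) {
  if (B < 2) stop("bagging_train: B must be >= 2")
  tr <- split_train_val(nrow(features), seed = split_seed)
  ns <- fit_normalizer(features[tr, , drop = FALSE])
  xz <- apply_normalizer(features, ns)
  tr_idx <- which(tr); va_idx <- which(!tr)
  members <- lapply(seq_len(B), function(b) {
    boot <- withr::with_seed(seed + 613L * b,
                             sample(tr_idx, length(tr_idx), replace = TRUE))
    cfg_b <- cfg; cfg_b$seed <- as.integer(cfg$seed + b)
    fit <- train_network(init_network(cfg_b, ncol(features)),
                         xz[boot, , drop = FALSE], labels[boot],
                         xz[va_idx, , drop = FALSE], labels[va_idx], cfg_b)
    m <- fit$model
    m$norm_stats <- ns
    m$boot_idx <- boot          # resample audit trail
    m
  })
  structure(list(members = members, norm_stats = ns, B = B),
            class = "nn_ensemble")
}

#' Project a model (or ensemble) over the study area
#'
#' Builds, for every cell with all bands available, the same 22-column
#' feature row as [extract_features()], normalizes it with the model's
#' training statistics, and applies the model. Nodata cells propagate.
#'
#' @param model an `nn_model` or `nn_ensemble`.
#' @param env an `env_stack`.
#' @param norm_stats normalizer to use (defaults to the one stored on the
#'   model/ensemble).
#' @return a probability `grid_raster` for a single model; a list of `B`
#'   member rasters for an ensemble.
#' @export
predict_raster <- function(model, env, norm_stats = NULL) {
  if (inherits(model, "nn_ensemble")) {
    ns <- if (is.null(norm_stats)) model$norm_stats else norm_stats
    return(lapply(model$members, predict_raster, env = env, norm_stats = ns))
  }
  ns <- if (is.null(norm_stats)) model$norm_stats else norm_stats
  if (is.null(ns)) stop("predict_raster: no normalization statistics")
  ref <- env$elevation
  nr <- nrow(ref$values); nc <- ncol(ref$values)
  feats <- encode_cells(env, as.vector(row(ref$values)),
                        as.vector(col(ref$values)))
  ok <- !apply(is.na(feats), 1, any)
  out <- rep(NA_real_, nr * nc)
  if (any(ok))
    out[ok] <- predict(model, apply_normalizer(feats[ok, , drop = FALSE], ns))
  grid_raster(matrix(out, nr, nc), ref$xmin, ref$ymin, ref$cellsize)
}

#' Aggregate bagged member maps
#'
#' Cellwise mean plus the empirical 2.5 and 97.5 percentiles (linear
#' interpolation between order statistics) as a 95% credible interval.
#'
#' @param member_maps list of >= 2 co-registered probability rasters.
#' @return a `bagged_prediction`: list with `mean`, `lower`, `upper`
#'   rasters and `B`.
#' @export
aggregate_bagged <- function(member_maps) {
  if (length(member_maps) < 2)
    stop("aggregate_bagged: need at least 2 member maps")
  ref <- member_maps[[1]]
  for (m in member_maps[-1]) stopifnot_same_grid(ref, m, "member maps")
  arr <- vapply(member_maps, function(m) m$values,
                matrix(0, nrow(ref$values), ncol(ref$values)))
  g <- function(v) grid_raster(v, ref$xmin, ref$ymin, ref$cellsize)
  qcell <- function(p) function(v)
    if (anyNA(v)) NA_real_ else stats::quantile(v, p, names = FALSE)
  structure(list(
    mean = g(apply(arr, c(1, 2), mean)),             # NA where any member NA
    lower = g(apply(arr, c(1, 2), qcell(0.025))),
    upper = g(apply(arr, c(1, 2), qcell(0.975))),
    B = length(member_maps)),
    class = "bagged_prediction")
}

#' Sensitivity-constrained binarization threshold
#'
#' The largest threshold `t` such that the true-positive rate of
#' `score >= t` is at least `target` (default 0.95), found by scanning
#' the unique scores of the positive class in decreasing order.
#'
#' @param labels 0/1 vector (positives must be present).
#' @param scores predicted probabilities.
#' @param target required sensitivity (default 0.95).
#' @return list with `threshold` and `achieved_tpr`.
#' @export
threshold_at_sensitivity <- function(labels, scores, target = 0.95) {
  pos <- scores[labels == 1]
  if (!length(pos)) stop("threshold_at_sensitivity: no positives")
  cand <- sort(unique(scores), decreasing = TRUE)
  n1 <- length(pos)
  for (t in cand) {
    tpr <- sum(pos >= t) / n1
    if (tpr >= target)
      return(list(threshold = t, achieved_tpr = tpr))
  }
  list(threshold = min(cand), achieved_tpr = 1)
}

#' Binarize a probability map
#'
#' 1 where `p >= threshold`, else 0 (the same `>=` convention as the
#' threshold-selection TPR, so the achieved sensitivity carries over
#' exactly); nodata preserved.
#'
#' @param prob_raster probability `grid_raster`.
#' @param threshold finite scalar.
#' @return 0/1 `grid_raster`.
#' @export
binarize <- function(prob_raster, threshold) {
  if (!is.finite(threshold)) stop("binarize: threshold must be finite")
  raster_map(prob_raster, function(v) ifelse(is.na(v), NA_real_,
                                             as.numeric(v >= threshold)))
}

#' Joint probability of occurrence and low flight
#'
#' Cellwise product of the species-occurrence probability raster and the
#' low-flight probability raster.
#'
#' @param low_flight_map,occurrence_map co-registered rasters in \\[0,1\\].
#' @return a probability `grid_raster`.
#' @export
joint_probability <- function(low_flight_map, occurrence_map) {
  stopifnot_same_grid(low_flight_map, occurrence_map, "probability maps")
  grid_raster(low_flight_map$values * occurrence_map$values,
              low_flight_map$xmin, low_flight_map$ymin,
              low_flight_map$cellsize)
}

#' High-risk conflict map and area shares
#'
#' Restricts the 4-level potential-conflict map to cells where low flight
#' is predicted (binary map = 1); elsewhere the level is 0. The area-share
#' table reports, for each sensitivity level 1-4 plus a total row, the
#' percentage of region cells carrying that level in the potential map, in
#' the high-risk map, and the remainder (potential minus high-risk) —
#' computed as cell counts times cell area.
#'
#' @param binary_low_flight 0/1 `grid_raster`.
#' @param conflict_levels co-registered raster with levels 0-4.
#' @return list with `high_risk` raster and `area_shares` data.frame
#'   (level, potential_pct, high_risk_pct, remaining_pct).
#' @export
high_risk_intersect <- function(binary_low_flight, conflict_levels) {
  stopifnot_same_grid(binary_low_flight, conflict_levels, "conflict inputs")
  lv <- conflict_levels$values
  known <- is.na(lv) | lv %in% 0:4
  if (!all(known))
    stop("high_risk_intersect: unknown conflict level code(s): ",
         paste(unique(lv[!known]), collapse = ", "))
  b <- binary_low_flight$values
  hr <- ifelse(is.na(b) | is.na(lv), NA_real_, lv * (b == 1))
  region_n <- sum(!is.na(lv) & !is.na(b))
  shares <- do.call(rbind, lapply(1:4, function(k) {
    pot <- sum(lv == k, na.rm = TRUE)
    hi <- sum(hr == k, na.rm = TRUE)
    data.frame(level = k,
               potential_pct = 100 * pot / region_n,
               high_risk_pct = 100 * hi / region_n,
               remaining_pct = 100 * (pot - hi) / region_n)
  }))
  shares$level <- as.character(shares$level)
  shares <- rbind(shares,
                  data.frame(level = "total",
                             potential_pct = sum(shares$potential_pct),
                             high_risk_pct = sum(shares$high_risk_pct),
                             remaining_pct = sum(shares$remaining_pct)))
  list(high_risk = grid_raster(hr, conflict_levels$xmin, conflict_levels$ymin,
                               conflict_levels$cellsize),
       area_shares = shares)
}
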