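# Exhaustive pairwise-concordance oracle for the AUC
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

test_that("AUC equals exhaustive pairwise concordance", {
  expect_equal(auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2)), 0.75)
  expect_equal(auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auc(c(0, 1, 0, 1), rep(0.3, 4)), 0.5)
  expect_error(auc(c(1, 1), c(0.2, 0.3)), "both classes")
  # random instances up to 12 observations, heavy ties included
  for (seed in 1:25) {
    withr::with_seed(seed, {
      n <- sample(4:12, 1)
      lab <- c(0, 1, rbinom(n - 2, 1, 0.5))
      sc <- sample(seq(0, 1, 0.25), n, replace = TRUE)
    })
    expect_equal(auc(lab, sc), oracle_auc(lab, sc))
  }
  # cross-check against an established ROC library on a larger instance
  withr::with_seed(99, {
    lab <- rbinom(300, 1, 0.4)
    sc <- runif(300) + 0.3 * lab
  })
  expect_equal(auc(lab, sc),
               as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                              direction = "<"))))
})

test_that("the default grid enumerates 216 distinct configurations", {
  cfgs <- grid_configs(grid_spec())
  expect_equal(nrow(cfgs), 216)
  expect_equal(nrow(unique(cfgs)), 216)
  expect_setequal(unique(cfgs$units1), c(16, 32, 64, 128, 256, 512))
  expect_equal(sort(unique(cfgs$dropout_rate)), seq(0.2, 0.7, 0.1))
  expect_equal(nrow(grid_configs(grid_spec(16, 16, 0.2))), 1)
})

test_that("grid search ranks by validation AUC and matches a direct fit", {
  d <- recovery_fixture()
  idx <- 1:1200
  feats <- d$fm$features[idx, ]; labs <- d$fm$labels[idx]
  base <- model_config(batch_size = 256, max_epochs = 6, patience = 2,
                       seed = 11)
  gs <- grid_search(feats, labs, grid_spec(c(8, 16), 8, c(0.2, 0.4)),
                    base_cfg = base, split_seed = 3)
  expect_equal(nrow(gs), 4)
  expect_true(all(diff(gs$val_auc) <= 0))
  expect_true(all(gs$val_auc >= 0 & gs$val_auc <= 1))
  # a single-configuration grid reproduces a direct training call
  gs1 <- grid_search(feats, labs, grid_spec(8, 8, 0.2),
                     base_cfg = base, split_seed = 3)
  tr <- split_train_val(length(labs), seed = 3)
  ns <- fit_normalizer(feats[tr, ])
  xz <- apply_normalizer(feats, ns)
  cfg <- base; cfg$units1 <- 8L; cfg$units2 <- 8L; cfg$dropout_rate <- 0.2
  fit <- train_network(init_network(cfg), xz[tr, ], labs[tr],
                       xz[!tr, ], labs[!tr], cfg)
  expect_equal(gs1$val_auc, auc(labs[!tr], predict(fit$model, xz[!tr, ])))
})

test_that("leave-one-bird-out holds each bird fully out", {
  lf <- loo_cv_fixture()
  fm <- lf$fm; cv <- lf$cv
  cfg <- model_config(units1 = 16, units2 = 8, dropout_rate = 0.2,
                      batch_size = 256, seed = 2)
  birds <- sort(unique(as.character(fm$bird_id)))
  expect_equal(cv$per_fold$fold, birds)          # one model per bird
  expect_equal(cv$per_fold$n_test,
               as.integer(table(fm$bird_id)[birds]), ignore_attr = TRUE)
  expect_true(all(cv$per_fold$test_auc >= 0 & cv$per_fold$test_auc <= 1,
                  na.rm = TRUE))
  # birds share one generating process: per-bird AUCs are homogeneous
  ta <- cv$per_fold$test_auc
  expect_true(all(abs(ta - mean(ta)) <= 3 * sd(ta) + 1e-9))
  expect_equal(cv$mean_test_auc, mean(ta))
  expect_error(loo_bird_cv(fm$features, fm$labels,
                           rep("one", nrow(fm$features)), cfg), "2 birds")
})

test_that("block construction tiles the bounding box and balances folds", {
  mask <- grid_raster(matrix(1, 100, 100), cellsize = 25)  # 2500 m square
  blocks <- make_blocks(mask, side_m = 1000, n_folds = 5, seed = 3)
  expect_equal(blocks$n_block_rows * blocks$n_block_cols, 9)
  tab <- table(blocks$fold_of_block)
  expect_lte(diff(range(tab)), 1)
  expect_identical(blocks$fold_of_block,
                   make_blocks(mask, 1000, 5, seed = 3)$fold_of_block)
  expect_false(identical(blocks$fold_of_block,
                         make_blocks(mask, 1000, 5, seed = 4)$fold_of_block))
  expect_error(make_blocks(mask, side_m = 2500, n_folds = 5), "fewer blocks")
  expect_error(make_blocks(mask, side_m = 10), "cell size")
  # every point inherits the fold of its containing block
  pts <- withr::with_seed(1, data.frame(x = runif(50, 0, 2500),
                                        y = runif(50, 0, 2500)))
  bf <- block_fold_of(blocks, pts$x, pts$y)
  expect_true(all(bf$fold %in% 1:5))
  expect_equal(bf$fold, blocks$fold_of_block[bf$block])
  manual_block <- floor(pts$y / 1000) * 3 + floor(pts$x / 1000) + 1
  expect_equal(bf$block, as.integer(manual_block))
})

test_that("variogram ranges behave as the band's autocorrelation implies", {
  n <- 60
  mkband <- function(vals) grid_raster(vals, cellsize = 25)
  noise <- function(seed) withr::with_seed(seed,
                                           matrix(rnorm(n^2), n, n))
  env <- stats::setNames(
    lapply(1:8, function(i) mkband(noise(200 + i))),
    continuous_features())
  env$elevation <- env$slope
  # white noise: flat variogram beyond lag 0, range collapses to ~cell scale
  est <- estimate_block_size(env, n_points = 500, seed = 6)
  expect_true(all(est$per_band$range_m <= 2 * 25))
  # two identical bands get identical ranges
  env$tpi <- env$slope
  est2 <- estimate_block_size(env, n_points = 500, seed = 6)
  pb <- est2$per_band
  expect_equal(pb$range_m[pb$band == "tpi"], pb$range_m[pb$band == "slope"])
  # constant band skipped with a warning
  env$chamois <- mkband(matrix(1, n, n))
  expect_warning(estimate_block_size(env, n_points = 300, seed = 6),
                 "constant band")
})

test_that("smoothed fields yield ranges near the kernel's correlation length", {
  n <- 80; s_cells <- 4
  sm <- function(seed) rotorrisk:::smooth_field(n, n, s_cells, seed)
  env <- stats::setNames(lapply(1:8, function(i)
    grid_raster(sm(300 + i), cellsize = 25)), continuous_features())
  env$elevation <- env$slope
  est <- estimate_block_size(env, n_points = 500, seed = 2)
  # oracle: Gaussian-kernel autocorrelation exp(-d^2 / (4 s^2)) falls to
  # 0.05 at d = 2 s sqrt(log 20) cells
  oracle_m <- 2 * s_cells * sqrt(log(20)) * 25
  expect_gt(est$recommended_m, oracle_m / 2)
  expect_lt(est$recommended_m, oracle_m * 2)
})

test_that("spatial folds partition fixes and generalize on homogeneous data", {
  rf <- recovery_fixture()
  bf0 <- block_cv_fixture()
  blocks <- bf0$blocks; cv <- bf0$cv
  fold <- block_fold_of(blocks, rf$fm$x, rf$fm$y)$fold
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(sum(table(fold)), nrow(rf$fm$features))   # exact partition
  expect_equal(nrow(cv$per_fold), 5)
  # no spatial confounding in the generator: block CV tracks a random split
  expect_lt(abs(cv$mean_test_auc - rf$val_auc), 0.05)
})

test_that("permutation importance isolates what the model uses", {
  # analytic model that uses only the slope column
  beta <- stats::setNames(numeric(22), feature_names())
  beta["slope"] <- 2
  m <- linear_logistic_model(beta)
  rf <- recovery_fixture()
  rows <- rf$xz[1:800, ]
  labs <- as.integer(rows[, "slope"] + withr::with_seed(2, rnorm(800, 0, 0.5)) > 0)
  imp <- permutation_importance(m, rows, labs, n_reps = 5, seed = 3)
  expect_equal(imp$group[1], "slope")
  unused <- imp$auc_drop_pct[imp$group != "slope"]
  expect_true(all(abs(unused) < 1e-9))    # permuting unused inputs: no drop
  # permuting everything jointly destroys all discrimination
  all_cols <- list(everything = feature_names())
  full <- permutation_importance(m, rows, labs, groups = all_cols,
                                 n_reps = 10, seed = 4, relative = FALSE)
  auc0 <- attr(full, "auc_original")
  expect_lt(abs((auc0 - full$auc_drop_pct / 100) - 0.5), 0.05)
  expect_error(permutation_importance(m, rows, labs,
                                      groups = list(bad = "nope")),
               "unknown column")
})

test_that("joint one-hot permutation keeps rows intact and seeds average out", {
  rf <- recovery_fixture()
  rows <- rf$xz[1:500, ]
  labs <- rf$fm$labels[1:500]
  # one-hot invariant survives any joint permutation (rows move intact)
  perm <- withr::with_seed(5, sample.int(nrow(rows)))
  rp <- rows
  rp[, paste0("landcover_", 1:10)] <- rows[perm, paste0("landcover_", 1:10)]
  expect_equal(rowSums(rp[, paste0("landcover_", 1:10)]), rep(1, 500),
               ignore_attr = TRUE)
  # two seeds agree within Monte-Carlo error at n_reps = 20
  i1 <- permutation_importance(rf$model, rows, labs, n_reps = 20, seed = 1)
  i2 <- permutation_importance(rf$model, rows, labs, n_reps = 20, seed = 2)
  top <- i1$group[1]
  d1 <- i1$auc_drop_pct[i1$group == top]; d2 <- i2$auc_drop_pct[i2$group == top]
  expect_lt(abs(d1 - d2), max(1, 0.25 * d1))
  # headline preset merges aspect and food
  g <- importance_groups("headline")
  expect_setequal(g$aspect, c("eastness", "northness"))
  expect_setequal(g$food, c("ibex", "chamois"))
  expect_setequal(unlist(importance_groups("table1")), feature_names())
})

test_that("ICE/PD recovers a known generating link exactly", {
  rf <- recovery_fixture()
  rows <- rf$fm$features[1:300, ]
  ns <- rf$ns
  beta <- stats::setNames(numeric(22), feature_names())
  beta["slope"] <- 1.4
  m <- linear_logistic_model(beta, intercept = -0.3, norm_stats = ns)
  ec <- ice_pd(m, rows, "slope", ns, n_grid = 15)
  # oracle: the model depends on slope alone through a fixed transform,
  # so every ICE curve equals the link evaluated on the grid
  link <- plogis(-0.3 + 1.4 * (ec$grid - ns$mean["slope"]) / ns$sd["slope"])
  for (i in c(1, 150, 300))
    expect_equal(unname(ec$ice[i, ]), unname(link), tolerance = 1e-6)
  expect_equal(ec$pd, colMeans(ec$ice))            # definitional identity
  expect_equal(unname(ec$pd), unname(link), tolerance = 1e-6)
  # constant model: flat curves
  m0 <- linear_logistic_model(stats::setNames(numeric(22), feature_names()),
                              intercept = 0.7, norm_stats = ns)
  ec0 <- ice_pd(m0, rows, "windspeed", ns, n_grid = 5)
  expect_equal(diff(range(ec0$ice)), 0)
  expect_error(ice_pd(m, rows, "slope", ns, n_grid = 1), "n_grid")
  expect_error(ice_pd(m, rows, "not_a_var", ns), "unknown")
})

test_that("categorical ICE sweeps the class set", {
  rf <- recovery_fixture()
  rows <- rf$fm$features[1:100, ]
  ec <- ice_pd(rf$model, rows, "landcover", rf$ns)
  expect_equal(ec$grid, 1:10)
  expect_equal(dim(ec$ice), c(100, 10))
  expect_equal(ec$pd, colMeans(ec$ice))
})
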