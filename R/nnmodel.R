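#' @title Feedforward low-flight classifier
#' @description A two-hidden-layer feedforward network with an inverted
#'   dropout layer between the hidden layers and a single sigmoid output
#'   unit, trained to minimize binary cross-entropy with the Adam optimizer
#'   and early stopping on validation AUC. Implemented directly on BLAS
#'   matrix operations: forward pass, analytic backpropagation, Adam with
#'   bias-corrected moments, seeded mini-batch shuffling and best-weights
#'   restoration are all in this file.
#' @name nnmodel
NULL

#' Network/training configuration
#'
#' Defaults are the architecture selected by the grid search (256 and 32
#' hidden units, dropout 0.4) and the optimizer's standard settings
#' (learning rate 0.001, beta1 0.9, beta2 0.999, epsilon 1e-7, batch 512,
#' early-stopping patience 10).
#'
#' @param units1,units2 hidden-layer widths (>= 1).
#' @param dropout_rate dropout probability in \\[0, 1).
#' @param learning_rate,beta1,beta2,epsilon Adam scalars.
#' @param batch_size mini-batch size.
#' @param max_epochs epoch cap.
#' @param patience epochs without validation-AUC improvement before
#'   stopping (strict improvement; 0 stops at the first non-improving
#'   epoch).
#' @param activation hidden activation (`"relu"`).
#' @param seed integer seed driving initialization, shuffling and dropout.
#' @return a `model_config` list.
#' @export
model_config <- function(units1 = 256, units2 = 32, dropout_rate = 0.4,
                         learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-7, batch_size = 512,
                         max_epochs = 100, patience = 10,
                         activation = "relu", seed = 1L) {
  if (units1 < 1 || units2 < 1) stop("model_config: units must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("model_config: dropout_rate must be in [0, 1)")
  structure(list(units1 = as.integer(units1), units2 = as.integer(units2),
                 dropout_rate = dropout_rate, learning_rate = learning_rate,
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 activation = activation, seed = as.integer(seed)),
            class = "model_config")
}

relu <- function(x) pmax(x, 0)

#' Initialize a network
#'
#' He-style initialization: weights drawn N(0, sqrt(2/fan_in)), biases
#' zero; fully determined by the config seed.
#'
#' @param cfg a [model_config()].
#' @param n_inputs input width (default 22, the contract feature count).
#' @return an `nn_model`: parameter list `W1,b1,W2,b2,W3,b3` + config.
#' @export
init_network <- function(cfg, n_inputs = length(feature_names())) {
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)),
                                   nin, nout)
  params <- withr::with_seed(cfg$seed, list(
    W1 = he(n_inputs, cfg$units1), b1 = numeric(cfg$units1),
    W2 = he(cfg$units1, cfg$units2), b2 = numeric(cfg$units2),
    W3 = he(cfg$units2, 1), b3 = numeric(1)))
  structure(list(params = params, config = cfg, n_inputs = n_inputs,
                 norm_stats = NULL),
            class = "nn_model")
}

#' Number of trainable parameters
#' @param model an `nn_model`.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# forward pass keeping intermediates for backprop; mask is the (already
# scaled) inverted-dropout multiplier on h1, or NULL for inference
forward_cache <- function(params, X, mask = NULL) {
  Z1 <- sweep(X %*% params$W1, 2, params$b1, "+")
  A1 <- relu(Z1)
  A1d <- if (is.null(mask)) A1 else A1 * mask
  Z2 <- sweep(A1d %*% params$W2, 2, params$b2, "+")
  A2 <- relu(Z2)
  Z3 <- sweep(A2 %*% params$W3, 2, params$b3, "+")
  p <- stats::plogis(drop(Z3))
  list(Z1 = Z1, A1 = A1, A1d = A1d, Z2 = Z2, A2 = A2, p = p)
}

#' Forward pass
#'
#' In training mode an inverted-dropout mask (drawn from `dropout_seed`)
#' deactivates hidden units after the first layer and rescales survivors
#' by 1/(1 - rate), so the expected pre-activation into the second layer
#' equals its inference-mode value; inference mode applies no mask and no
#' scaling.
#'
#' @param model an `nn_model`.
#' @param rows numeric matrix with `model$n_inputs` (normalized) columns.
#' @param training logical; draw and apply the dropout mask?
#' @param dropout_seed seed for the mask (training mode only).
#' @return vector of probabilities in (0, 1).
#' @export
forward <- function(model, rows, training = FALSE, dropout_seed = 1L) {
  rows <- as.matrix(rows)
  if (ncol(rows) != model$n_inputs)
    stop("forward: expected ", model$n_inputs, " columns, got ", ncol(rows))
  mask <- NULL
  r <- model$config$dropout_rate
  if (training && r > 0) {
    mask <- withr::with_seed(dropout_seed,
      matrix(stats::rbinom(nrow(rows) * model$config$units1, 1, 1 - r),
             nrow(rows), model$config$units1) / (1 - r))
  }
  forward_cache(model$params, rows, mask)$p
}

#' Binary cross-entropy loss
#'
#' Mean of `-[y log p + (1 - y) log(1 - p)]` with probabilities clipped to
#' `(eps, 1 - eps)` for numerical safety.
#'
#' @param labels 0/1 vector.
#' @param probabilities predicted probabilities.
#' @param eps clipping bound (default 1e-7).
#' @return scalar >= 0.
#' @export
bce_loss <- function(labels, probabilities, eps = 1e-7) {
  p <- pmin(pmax(probabilities, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

# analytic gradients of the mean BCE loss wrt all parameters
nn_gradients <- function(params, X, y, mask = NULL, eps = 1e-7) {
  fc <- forward_cache(params, X, mask)
  n <- nrow(X)
  p <- pmin(pmax(fc$p, eps), 1 - eps)
  d3 <- matrix((p - y) / n, n, 1)          # dL/dZ3 for sigmoid + BCE
  gW3 <- crossprod(fc$A2, d3)
  gb3 <- colSums(d3)
  dA2 <- d3 %*% t(params$W3)
  d2 <- dA2 * (fc$Z2 > 0)
  gW2 <- crossprod(fc$A1d, d2)
  gb2 <- colSums(d2)
  dA1d <- d2 %*% t(params$W2)
  dA1 <- if (is.null(mask)) dA1d else dA1d * mask
  d1 <- dA1 * (fc$Z1 > 0)
  gW1 <- crossprod(X, d1)
  gb1 <- colSums(d1)
  list(grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                    W3 = gW3, b3 = gb3),
       loss = bce_loss(y, fc$p, eps))
}

#' Initialize Adam optimizer state
#' @param params network parameter list.
#' @return list with zeroed first/second moments and step counter.
#' @export
adam_init <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  list(m = zero, v = zero, t = 0L)
}

#' One Adam update
#'
#' Standard Adam with bias-corrected first and second moments:
#' `theta <- theta - lr * m_hat / (sqrt(v_hat) + epsilon)`.
#'
#' @param params network parameter list.
#' @param grads matching gradient list.
#' @param state optimizer state from [adam_init()].
#' @param cfg a [model_config()] (uses learning_rate, beta1, beta2,
#'   epsilon).
#' @return list with updated `params` and `state`.
#' @export
adam_step <- function(params, grads, state, cfg) {
  if (any(!vapply(grads, function(g) all(is.finite(g)), logical(1))))
    stop("adam_step: non-finite gradient")
  t <- state$t + 1L
  new_m <- mapply(function(m, g) cfg$beta1 * m + (1 - cfg$beta1) * g,
                  state$m, grads, SIMPLIFY = FALSE)
  new_v <- mapply(function(v, g) cfg$beta2 * v + (1 - cfg$beta2) * g^2,
                  state$v, grads, SIMPLIFY = FALSE)
  bc1 <- 1 - cfg$beta1^t; bc2 <- 1 - cfg$beta2^t
  new_p <- mapply(function(p, m, v)
    p - cfg$learning_rate * (m / bc1) / (sqrt(v / bc2) + cfg$epsilon),
    params, new_m, new_v, SIMPLIFY = FALSE)
  list(params = new_p, state = list(m = new_m, v = new_v, t = t))
}

#' Train the network
#'
#' Mini-batch training: each epoch is one pass over seeded-shuffled
#' batches with fresh dropout masks; after each epoch the validation AUC
#' is computed. With `early_stopping = TRUE` training stops once the
#' validation AUC has not strictly improved for `patience` consecutive
#' epochs (or at `max_epochs`) and the parameters are restored to the best
#' epoch. With `early_stopping = FALSE` (the fixed-epoch protocol used by
#' the cross-validation stages) exactly `max_epochs` epochs are run and
#' the final parameters kept; validation data are then optional.
#'
#' @param model an `nn_model` from [init_network()].
#' @param train_x,train_y training split (matrix of normalized features,
#'   0/1 labels).
#' @param val_x,val_y validation split (required for early stopping; must
#'   contain both classes).
#' @param cfg optional [model_config()] override (defaults to the model's).
#' @param early_stopping logical (see above).
#' @return list with `model` (trained) and `log` (a `train_log`:
#'   data.frame epoch/train_loss/val_auc + `best_epoch`, `stopped_epoch`
#'   attributes).
#' @export
train_network <- function(model, train_x, train_y, val_x = NULL,
                          val_y = NULL, cfg = model$config,
                          early_stopping = TRUE) {
  train_x <- as.matrix(train_x)
  if (nrow(train_x) == 0) stop("train_network: empty training split")
  has_val <- !is.null(val_x)
  if (early_stopping) {
    if (!has_val) stop("train_network: early stopping requires validation data")
    if (length(unique(val_y)) < 2)
      stop("train_network: validation split has a single class; AUC undefined")
  }
  params <- model$params
  state <- adam_init(params)
  n <- nrow(train_x)
  best_auc <- -Inf; best_params <- params; best_epoch <- 0L
  wait <- 0L
  ep_loss <- numeric(); ep_auc <- numeric()
  stopped <- cfg$max_epochs
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- withr::with_seed(cfg$seed + 7919L * epoch, sample.int(n))
    starts <- seq(1, n, by = cfg$batch_size)
    losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + cfg$batch_size - 1, n)]
      mask <- NULL
      if (cfg$dropout_rate > 0) {
        mask <- withr::with_seed(cfg$seed + 104729L * epoch + bi,
          matrix(stats::rbinom(length(idx) * cfg$units1, 1,
                               1 - cfg$dropout_rate),
                 length(idx), cfg$units1) / (1 - cfg$dropout_rate))
      }
      g <- nn_gradients(params, train_x[idx, , drop = FALSE], train_y[idx],
                        mask)
      losses[bi] <- g$loss
      upd <- adam_step(params, g$grads, state, cfg)
      params <- upd$params; state <- upd$state
    }
    ep_loss[epoch] <- mean(losses)
    va <- NA_real_
    if (has_val) {
      mtmp <- model; mtmp$params <- params
      va <- auc(val_y, forward(mtmp, val_x))
    }
    ep_auc[epoch] <- va
    if (early_stopping) {
      if (va > best_auc) {
        best_auc <- va; best_params <- params; best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait > cfg$patience) { stopped <- epoch; break }
      }
    }
  }
  if (early_stopping) {
    model$params <- best_params
  } else {
    model$params <- params
    best_epoch <- length(ep_loss)
    stopped <- length(ep_loss)
  }
  model$config <- cfg
  log <- structure(
    data.frame(epoch = seq_along(ep_loss), train_loss = ep_loss,
               val_auc = ep_auc),
    class = c("train_log", "data.frame"),
    best_epoch = best_epoch, stopped_epoch = stopped)
  list(model = model, log = log)
}

#' Predict low-flight probabilities
#'
#' Inference-mode forward pass (no dropout). Rows must be normalized with
#' the model's stored normalization statistics.
#'
#' @param object an `nn_model`.
#' @param newdata numeric matrix of normalized feature rows.
#' @param ... unused.
#' @return vector of probabilities in (0, 1).
#' @export
predict.nn_model <- function(object, newdata, ...) {
  forward(object, newdata, training = FALSE)
}

#' Serialize / restore a model as plain text
#'
#' Writes config, normalization statistics and flat parameter arrays with
#' named shapes to a portable delimited-text container.
#'
#' @param model an `nn_model`.
#' @param path output file.
#' @export
write_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- model$config
  writeLines(sprintf("config %s %s", names(cfg),
                     vapply(cfg, as.character, character(1))), con)
  writeLines(sprintf("n_inputs %d", model$n_inputs), con)
  if (!is.null(model$norm_stats)) {
    writeLines(sprintf("norm_mean %s %.17g", names(model$norm_stats$mean),
                       model$norm_stats$mean), con)
    writeLines(sprintf("norm_sd %s %.17g", names(model$norm_stats$sd),
                       model$norm_stats$sd), con)
  }
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    d <- if (is.matrix(p)) dim(p) else c(length(p), 1L)
    writeLines(sprintf("param %s %d %d", nm, d[1], d[2]), con)
    writeLines(paste(sprintf("%.17g", as.vector(p)), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  cfg_lines <- grep("^config ", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^config ", "", cfg_lines), " "))
  cfgl <- as.list(kv[, 2]); names(cfgl) <- kv[, 1]
  num <- setdiff(names(cfgl), "activation")
  cfgl[num] <- lapply(cfgl[num], as.numeric)
  cfg <- do.call(model_config, cfgl)
  n_inputs <- as.integer(sub("^n_inputs ", "",
                             grep("^n_inputs ", lines, value = TRUE)))
  params <- list()
  i <- 1
  while (i <= length(lines)) {
    if (grepl("^param ", lines[i])) {
      hdr <- strsplit(lines[i], " ")[[1]]
      vals <- scan(text = lines[i + 1], quiet = TRUE)
      nr <- as.integer(hdr[3]); nc <- as.integer(hdr[4])
      params[[hdr[2]]] <- if (nc == 1 && grepl("^b", hdr[2]))
        vals else matrix(vals, nr, nc)
      i <- i + 2
    } else i <- i + 1
  }
  ns <- NULL
  nm_lines <- grep("^norm_mean ", lines, value = TRUE)
  if (length(nm_lines)) {
    pm <- do.call(rbind, strsplit(sub("^norm_mean ", "", nm_lines), " "))
    ps <- do.call(rbind, strsplit(sub("^norm_sd ", "",
                                      grep("^norm_sd ", lines, value = TRUE)), " "))
    ns <- structure(list(mean = stats::setNames(as.numeric(pm[, 2]), pm[, 1]),
                         sd = stats::setNames(as.numeric(ps[, 2]), ps[, 1])),
                    class = "norm_stats")
  }
  structure(list(params = params, config = cfg, n_inputs = n_inputs,
                 norm_stats = ns),
            class = "nn_model")
}
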