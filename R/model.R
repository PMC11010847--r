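# Multi-head-attention convolutional weight regressor (MACNN).
#
# Architecture: five pointwise convolution layers (a shared linear map per
# point, channel counts strictly increasing), each followed by the
# activation and batch normalization; a k-head scaled-dot-product attention
# block over the points; global max pooling over the point dimension;
# dropout (training only); one linear output node. Trained with plain SGD on
# an MSE loss plus L2 weight decay, Xavier-uniform initialization.
#
# All forward and backward passes are implemented directly on matrices: a
# minibatch of B samples with n points each travels as a (B*n) x c matrix
# through the pointwise layers and is sliced per sample for attention.

#' MACNN configuration
#'
#' @param feature_mode `"xyz"` (3 input channels) or `"xyzrgb"` (6).
#' @param n_points fixed point-set size fed to the network; clouds are
#'   resampled to this size by [assemble_features()].
#' @param conv_channels five strictly increasing channel counts.
#' @param n_heads number of attention heads k.
#' @param head_dim per-head dimension d; `n_heads * head_dim` must equal the
#'   last conv channel count (default: that count divided by `n_heads`).
#' @param dropout_rate dropout probability on the pooled feature vector.
#' @param learning_rate SGD step size.
#' @param batch_size minibatch size (capped at the training-set size).
#' @param l2_lambda L2 penalty on weights (never biases or the batch-norm
#'   scale/shift).
#' @param epochs training epochs.
#' @param val_fraction held-out validation fraction of the dataset.
#' @param activation `"relu"` (the unnamed activation is configurable).
#' @param bn_momentum running-statistics momentum of batch normalization.
#' @param bn_eps batch-normalization variance floor.
#' @param seed RNG seed for initialization, splitting, shuffling, dropout.
#' @return list of class `macnn_config`.
#' @export
macnn_config <- function(feature_mode = c("xyz", "xyzrgb"), n_points = 1024L,
                         conv_channels = c(32L, 64L, 128L, 256L, 512L),
                         n_heads = 4L, head_dim = NULL, dropout_rate = 0.5,
                         learning_rate = 0.001, batch_size = 128L,
                         l2_lambda = 0.001, epochs = 200L,
                         val_fraction = 0.2, activation = "relu",
                         bn_momentum = 0.1, bn_eps = 1e-5, seed = 1L) {
  feature_mode <- match.arg(feature_mode)
  conv_channels <- as.integer(conv_channels)
  if (length(conv_channels) != 5L || any(diff(conv_channels) <= 0L))
    stop("macnn_config: conv_channels must be 5 strictly increasing integers")
  c5 <- conv_channels[5]
  if (is.null(head_dim)) {
    if (c5 %% n_heads != 0L)
      stop("macnn_config: last conv channel count not divisible by n_heads")
    head_dim <- c5 %/% n_heads
  }
  if (n_heads * head_dim != c5)
    stop("macnn_config: n_heads * head_dim must equal the last conv channels")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("macnn_config: dropout_rate must lie in [0, 1)")
  structure(list(feature_mode = feature_mode, n_points = as.integer(n_points),
                 conv_channels = conv_channels, n_heads = as.integer(n_heads),
                 head_dim = as.integer(head_dim),
                 dropout_rate = dropout_rate, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), l2_lambda = l2_lambda,
                 epochs = as.integer(epochs), val_fraction = val_fraction,
                 activation = activation, bn_momentum = bn_momentum,
                 bn_eps = bn_eps, seed = as.integer(seed)),
            class = "macnn_config")
}

input_width <- function(cfg) if (cfg$feature_mode == "xyzrgb") 6L else 3L

xavier_uniform <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

# Initialize all learnable parameters and batch-norm running statistics.
init_macnn_params <- function(cfg) {
  with_seed(cfg$seed, {
    c_in <- input_width(cfg)
    chans <- c(c_in, cfg$conv_channels)
    conv <- lapply(1:5, function(l)
      list(W = xavier_uniform(chans[l], chans[l + 1]),
           b = numeric(chans[l + 1])))
    bn <- lapply(1:5, function(l)
      list(gamma = rep(1, chans[l + 1]), beta = numeric(chans[l + 1]),
           run_mean = numeric(chans[l + 1]), run_var = rep(1, chans[l + 1])))
    c5 <- cfg$conv_channels[5]
    attn <- lapply(seq_len(cfg$n_heads), function(h)
      list(Wq = xavier_uniform(c5, cfg$head_dim),
           Wk = xavier_uniform(c5, cfg$head_dim),
           Wv = xavier_uniform(c5, cfg$head_dim)))
    out <- list(W = xavier_uniform(c5, 1L), b = 0)
    list(conv = conv, bn = bn, attn = attn, out = out)
  })
}

#' Assemble network input features from a point cloud
#'
#' Resamples the cloud to exactly `n_points` points (uniformly without
#' replacement when enough points exist, with replacement otherwise),
#' centers the coordinates on the centroid of the sampled set, and — in
#' `xyzrgb` mode — appends the colours scaled to `[0, 1]`.
#'
#' @param cloud a non-empty [point_cloud()].
#' @param mode `"xyz"` or `"xyzrgb"`.
#' @param n_points output row count.
#' @param seed RNG seed for the resampling.
#' @return `n_points` x 3 (or x 6) numeric matrix.
#' @export
assemble_features <- function(cloud, mode = c("xyz", "xyzrgb"),
                              n_points = 1024L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(cloud, "point_cloud"))
  n <- n_points(cloud)
  if (n < 1L) stop("assemble_features: empty cloud")
  if (mode == "xyzrgb" && !has_colors(cloud))
    stop("assemble_features: xyzrgb mode requires a coloured cloud")
  idx <- with_seed(seed,
    sample.int(n, n_points, replace = n < n_points))
  xyz <- cloud$points[idx, , drop = FALSE]
  xyz <- sweep(xyz, 2, colMeans(xyz))
  feats <- if (mode == "xyzrgb")
    cbind(xyz, cloud$colors[idx, , drop = FALSE] / 255) else xyz
  dimnames(feats) <- NULL
  feats
}

#' Multi-head scaled-dot-product attention over a point set
#'
#' For each head h, `Q = X Wq_h`, `K = X Wk_h`, `V = X Wv_h` and the head
#' output is `softmax(Q K' / sqrt(d)) V`; head outputs are concatenated.
#' Every row of each attention-weight matrix sums to 1.
#'
#' @param features n x c matrix (c = `n_heads * head_dim`).
#' @param heads list of heads, each a list with `Wq`, `Wk`, `Wv`
#'   (c x d matrices).
#' @return n x c matrix of attended features.
#' @export
multi_head_attention <- function(features, heads) {
  features <- as.matrix(features)
  d <- ncol(heads[[1]]$Wq)
  if (ncol(features) != nrow(heads[[1]]$Wq))
    stop("multi_head_attention: feature width does not match projections")
  if (length(heads) * d != ncol(features))
    stop("multi_head_attention: n_heads * head_dim must equal feature width")
  do.call(cbind, lapply(heads, function(hp)
    attention_forward(features, hp)$O))
}

row_softmax <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

attention_forward <- function(X, hp) {
  d <- ncol(hp$Wq)
  Q <- X %*% hp$Wq
  K <- X %*% hp$Wk
  V <- X %*% hp$Wv
  A <- row_softmax(Q %*% t(K) / sqrt(d))
  list(Q = Q, K = K, V = V, A = A, O = A %*% V)
}

attention_backward <- function(X, hp, cache, dO) {
  d <- ncol(hp$Wq)
  A <- cache$A
  dV <- t(A) %*% dO
  dA <- dO %*% t(cache$V)
  dS <- A * (dA - rowSums(dA * A))
  dQ <- dS %*% cache$K / sqrt(d)
  dK <- t(dS) %*% cache$Q / sqrt(d)
  list(dWq = t(X) %*% dQ, dWk = t(X) %*% dK, dWv = t(X) %*% dV,
       dX = dQ %*% t(hp$Wq) + dK %*% t(hp$Wk) + dV %*% t(hp$Wv))
}

activate <- function(Z, kind) {
  switch(kind,
         relu = pmax(Z, 0),
         tanh = tanh(Z),
         stop("unknown activation: ", kind))
}

activate_grad <- function(Z, A, kind) {
  switch(kind,
         relu = (Z > 0) + 0,
         tanh = 1 - A^2,
         stop("unknown activation: ", kind))
}

# Forward pass on a stacked minibatch.
# X: (B*n) x c_in matrix; returns prediction (standardized scale), cache for
# backward, and (train mode) freshly updated running statistics.
macnn_forward <- function(params, cfg, X, B, train = FALSE,
                          dropout_mask = NULL) {
  n <- nrow(X) / B
  H <- X
  cache <- list(H0 = X, layers = vector("list", 5L))
  bn_new <- params$bn
  for (l in 1:5) {
    cv <- params$conv[[l]]; bnp <- params$bn[[l]]
    Z <- H %*% cv$W + rep(cv$b, each = nrow(H))
    A <- activate(Z, cfg$activation)
    if (train) {
      mu <- colMeans(A)
      va <- pmax(colMeans(A^2) - mu^2, 0)
      bn_new[[l]]$run_mean <- (1 - cfg$bn_momentum) * bnp$run_mean +
        cfg$bn_momentum * mu
      bn_new[[l]]$run_var <- (1 - cfg$bn_momentum) * bnp$run_var +
        cfg$bn_momentum * va
    } else {
      mu <- bnp$run_mean
      va <- bnp$run_var
    }
    ivar <- 1 / sqrt(va + cfg$bn_eps)
    xhat <- sweep(sweep(A, 2, mu), 2, ivar, "*")
    Hn <- sweep(sweep(xhat, 2, bnp$gamma, "*"), 2, bnp$beta, "+")
    cache$layers[[l]] <- list(Z = Z, A = A, xhat = xhat, ivar = ivar)
    H <- Hn
  }
  c5 <- cfg$conv_channels[5]
  att <- matrix(0, nrow(H), c5)
  acache <- vector("list", B)
  for (i in seq_len(B)) {
    rows <- ((i - 1) * n + 1):(i * n)
    Xi <- H[rows, , drop = FALSE]
    hc <- vector("list", cfg$n_heads)
    for (h in seq_len(cfg$n_heads)) {
      hc[[h]] <- attention_forward(Xi, params$attn[[h]])
      att[rows, ((h - 1) * cfg$head_dim + 1):(h * cfg$head_dim)] <- hc[[h]]$O
    }
    acache[[i]] <- hc
  }
  # global max pool over the point dimension, per sample
  P <- matrix(0, B, c5)
  amax <- matrix(0L, B, c5)
  for (i in seq_len(B)) {
    rows <- ((i - 1) * n + 1):(i * n)
    Ai <- att[rows, , drop = FALSE]
    amax[i, ] <- max.col(t(Ai), ties.method = "first")
    P[i, ] <- Ai[cbind(amax[i, ], seq_len(c5))]
  }
  Pd <- P
  if (train && cfg$dropout_rate > 0) {
    if (is.null(dropout_mask))
      dropout_mask <- matrix(stats::rbinom(length(P), 1, 1 - cfg$dropout_rate),
                             nrow(P)) / (1 - cfg$dropout_rate)
    Pd <- P * dropout_mask
  }
  yhat <- as.vector(Pd %*% params$out$W + params$out$b)
  cache$H5 <- H; cache$att = att; cache$acache <- acache
  cache$P <- P; cache$Pd <- Pd; cache$amax <- amax
  cache$dropout_mask <- dropout_mask; cache$B <- B; cache$n <- n
  list(yhat = yhat, cache = cache, bn_new = bn_new)
}

# Training objective on the standardized scale: MSE + l2 * sum of squared
# weights (conv W, attention projections, output W).
macnn_loss <- function(params, cfg, yhat, y) {
  l2 <- sum(vapply(params$conv, function(cv) sum(cv$W^2), numeric(1))) +
    sum(vapply(params$attn, function(hp)
      sum(hp$Wq^2) + sum(hp$Wk^2) + sum(hp$Wv^2), numeric(1))) +
    sum(params$out$W^2)
  mean((yhat - y)^2) + cfg$l2_lambda * l2
}

# Backward pass: gradients of macnn_loss w.r.t. every learnable parameter.
macnn_backward <- function(params, cfg, cache, yhat, y) {
  B <- cache$B; n <- cache$n
  c5 <- cfg$conv_channels[5]
  g <- list(conv = vector("list", 5L), bn = vector("list", 5L),
            attn = vector("list", cfg$n_heads), out = NULL)
  dyhat <- 2 * (yhat - y) / B
  g$out <- list(W = t(cache$Pd) %*% dyhat + 2 * cfg$l2_lambda * params$out$W,
                b = sum(dyhat))
  dPd <- outer(dyhat, as.vector(params$out$W))
  dP <- if (!is.null(cache$dropout_mask)) dPd * cache$dropout_mask else dPd
  # un-pool: gradient flows to the argmax row of each channel
  datt <- matrix(0, B * n, c5)
  for (i in seq_len(B)) {
    rows0 <- (i - 1) * n
    datt[cbind(rows0 + cache$amax[i, ], seq_len(c5))] <- dP[i, ]
  }
  # attention backward per sample/head
  dH <- matrix(0, B * n, c5)
  for (h in seq_len(cfg$n_heads))
    g$attn[[h]] <- list(dWq = 2 * cfg$l2_lambda * params$attn[[h]]$Wq,
                        dWk = 2 * cfg$l2_lambda * params$attn[[h]]$Wk,
                        dWv = 2 * cfg$l2_lambda * params$attn[[h]]$Wv)
  for (i in seq_len(B)) {
    rows <- ((i - 1) * n + 1):(i * n)
    Xi <- cache$H5[rows, , drop = FALSE]
    for (h in seq_len(cfg$n_heads)) {
      cols <- ((h - 1) * cfg$head_dim + 1):(h * cfg$head_dim)
      ab <- attention_backward(Xi, params$attn[[h]], cache$acache[[i]][[h]],
                               datt[rows, cols, drop = FALSE])
      g$attn[[h]]$dWq <- g$attn[[h]]$dWq + ab$dWq
      g$attn[[h]]$dWk <- g$attn[[h]]$dWk + ab$dWk
      g$attn[[h]]$dWv <- g$attn[[h]]$dWv + ab$dWv
      dH[rows, ] <- dH[rows, ] + ab$dX
    }
  }
  # conv + BN stack, reversed
  for (l in 5:1) {
    lc <- cache$layers[[l]]
    bnp <- params$bn[[l]]
    m <- nrow(dH)
    dgamma <- colSums(dH * lc$xhat)
    dbeta <- colSums(dH)
    dxhat <- sweep(dH, 2, bnp$gamma, "*")
    mean_dxhat <- colMeans(dxhat)
    mean_dxx <- colMeans(dxhat * lc$xhat)
    dA <- sweep(sweep(dxhat, 2, mean_dxhat) -
                  sweep(lc$xhat, 2, mean_dxx, "*"), 2, lc$ivar, "*")
    dZ <- dA * activate_grad(lc$Z, lc$A, cfg$activation)
    Hprev <- if (l == 1) cache$H0 else {
      lp <- cache$layers[[l - 1]]
      sweep(sweep(lp$xhat, 2, params$bn[[l - 1]]$gamma, "*"), 2,
            params$bn[[l - 1]]$beta, "+")
    }
    g$conv[[l]] <- list(W = t(Hprev) %*% dZ +
                          2 * cfg$l2_lambda * params$conv[[l]]$W,
                        b = colSums(dZ))
    g$bn[[l]] <- list(gamma = dgamma, beta = dbeta)
    dH <- dZ %*% t(params$conv[[l]]$W)
  }
  g
}

sgd_step <- function(params, g, lr) {
  for (l in 1:5) {
    params$conv[[l]]$W <- params$conv[[l]]$W - lr * g$conv[[l]]$W
    params$conv[[l]]$b <- params$conv[[l]]$b - lr * g$conv[[l]]$b
    params$bn[[l]]$gamma <- params$bn[[l]]$gamma - lr * g$bn[[l]]$gamma
    params$bn[[l]]$beta <- params$bn[[l]]$beta - lr * g$bn[[l]]$beta
  }
  for (h in seq_along(params$attn)) {
    params$attn[[h]]$Wq <- params$attn[[h]]$Wq - lr * g$attn[[h]]$dWq
    params$attn[[h]]$Wk <- params$attn[[h]]$Wk - lr * g$attn[[h]]$dWk
    params$attn[[h]]$Wv <- params$attn[[h]]$Wv - lr * g$attn[[h]]$dWv
  }
  params$out$W <- params$out$W - lr * g$out$W
  params$out$b <- params$out$b - lr * g$out$b
  params
}

#' Train the MACNN weight regressor
#'
#' Xavier-uniform initialization, seeded 80/20 train/validation split,
#' minibatch SGD on mean squared error with L2 weight decay. Targets are
#' z-standardized internally (the network learns on unit scale; predictions
#' are mapped back to kg), which keeps plain SGD well conditioned for
#' kg-scale weights.
#'
#' @param dataset list of samples, each a list with `features` (an
#'   `n_points` x width matrix from [assemble_features()]) and `weight` (kg,
#'   > 0).
#' @param config a [macnn_config()].
#' @param verbose print a line every `verbose` epochs (0 = silent).
#' @return object of class `macnn_model`: list with `config`, `params`,
#'   `w_mean`, `w_sd`, and `history` (per-epoch data frame with `train_loss`
#'   and `val_loss`, both MSE in kg^2; `val_loss` is `NA` when the split
#'   leaves no validation samples).
#' @export
train_macnn <- function(dataset, config, verbose = 0L) {
  stopifnot(inherits(config, "macnn_config"))
  N <- length(dataset)
  if (N < 2L) stop("train_macnn: need at least 2 samples")
  y_raw <- vapply(dataset, function(s) s$weight, numeric(1))
  if (any(!is.finite(y_raw)) || any(y_raw <= 0))
    stop("train_macnn: weights must be positive and finite")
  width <- input_width(config)
  feats <- lapply(dataset, function(s) {
    f <- as.matrix(s$features)
    if (nrow(f) != config$n_points || ncol(f) != width)
      stop("train_macnn: features must be n_points x ", width)
    f
  })
  w_mean <- mean(y_raw)
  w_sd <- stats::sd(y_raw)
  if (!is.finite(w_sd) || w_sd < 1e-8) w_sd <- 1
  y <- (y_raw - w_mean) / w_sd

  params <- init_macnn_params(config)
  n_val <- floor(config$val_fraction * N)
  history <- data.frame(epoch = seq_len(config$epochs),
                        train_loss = NA_real_, val_loss = NA_real_)
  with_seed(config$seed + 1L, {
    val_idx <- if (n_val > 0) sample.int(N, n_val) else integer(0)
    tr_idx <- setdiff(seq_len(N), val_idx)
    bsz <- min(config$batch_size, length(tr_idx))
    Xval <- if (n_val > 0) do.call(rbind, feats[val_idx])
    for (ep in seq_len(config$epochs)) {
      ord <- sample(tr_idx)
      ep_sse <- 0
      for (start in seq(1, length(ord), by = bsz)) {
        bi <- ord[start:min(start + bsz - 1, length(ord))]
        X <- do.call(rbind, feats[bi])
        fw <- macnn_forward(params, config, X, B = length(bi), train = TRUE)
        if (any(!is.finite(fw$yhat)))
          stop("train_macnn: non-finite loss at epoch ", ep)
        params$bn <- fw$bn_new
        g <- macnn_backward(params, config, fw$cache, fw$yhat, y[bi])
        params <- sgd_step(params, g, config$learning_rate)
        ep_sse <- ep_sse + sum((fw$yhat - y[bi])^2)
      }
      history$train_loss[ep] <- ep_sse / length(tr_idx) * w_sd^2
      if (n_val > 0) {
        fv <- macnn_forward(params, config, Xval, B = n_val, train = FALSE)
        history$val_loss[ep] <- mean((fv$yhat - y[val_idx])^2) * w_sd^2
      }
      if (verbose > 0 && ep %% verbose == 0)
        message(sprintf("epoch %d: train MSE %.3f kg^2, val MSE %s", ep,
                        history$train_loss[ep],
                        if (n_val > 0) sprintf("%.3f", history$val_loss[ep])
                        else "-"))
    }
  })
  structure(list(config = config, params = params, w_mean = w_mean,
                 w_sd = w_sd, history = history,
                 val_idx = if (n_val > 0) sort(val_idx) else integer(0)),
            class = "macnn_model")
}

#' Predict weights with a trained MACNN
#'
#' Evaluation mode: batch normalization uses running statistics and dropout
#' is disabled, so predictions are deterministic and invariant to point
#' order.
#'
#' @param object a `macnn_model`.
#' @param features one feature matrix or a list of them (each
#'   `n_points` x input width).
#' @param ... unused.
#' @return numeric vector of predicted weights, kg.
#' @export
predict.macnn_model <- function(object, features, ...) {
  if (is.matrix(features)) features <- list(features)
  X <- do.call(rbind, lapply(features, as.matrix))
  fw <- macnn_forward(object$params, object$config, X, B = length(features),
                      train = FALSE)
  fw$yhat * object$w_sd + object$w_mean
}

#' @export
print.macnn_model <- function(x, ...) {
  cat(sprintf(
    "macnn_model: %s features, channels %s, %d heads x %d, %d epochs\n",
    x$config$feature_mode, paste(x$config$conv_channels, collapse = "-"),
    x$config$n_heads, x$config$head_dim, x$config$epochs))
  tl <- x$history$train_loss[x$config$epochs]
  cat(sprintf("  final train MSE %.3f kg^2\n", tl))
  invisible(x)
}

#' Save / load a trained model checkpoint
#'
#' Single-file bundle holding the configuration and parameter arrays.
#'
#' @param model a `macnn_model`.
#' @param path checkpoint file path.
#' @return `path` (save) or the restored `macnn_model` (load).
#' @export
save_weight_model <- function(model, path) {
  stopifnot(inherits(model, "macnn_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_weight_model
#' @export
load_weight_model <- function(path) {
  if (!file.exists(path))
    stop("load_weight_model: model checkpoint not found: ", path)
  model <- readRDS(path)
  if (!inherits(model, "macnn_model"))
    stop("load_weight_model: not a macnn_model checkpoint")
  model
}

#' Build a training dataset from a synthetic cohort
#'
#' @param cohort list of `scene_sample` (e.g. from [make_cohort()]).
#' @param mode feature mode, `"xyz"` or `"xyzrgb"`.
#' @param n_points rows per feature matrix.
#' @param seed base seed; sample i is resampled with `seed + i`.
#' @return list of `list(features, weight)` suitable for [train_macnn()].
#' @export
cohort_features <- function(cohort, mode = "xyz", n_points = 256L,
                            seed = 1L) {
  lapply(seq_along(cohort), function(i)
    list(features = assemble_features(cohort[[i]]$cloud, mode = mode,
                                      n_points = n_points, seed = seed + i),
         weight = cohort[[i]]$truth$weight))
}
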