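tiny_cfg <- function(...) {
  macnn_config(n_points = 12L, conv_channels = c(4L, 6L, 8L, 10L, 12L),
               n_heads = 2L, dropout_rate = 0, activation = "tanh",
               l2_lambda = 0.001, seed = 2L, ...)
}

test_that("macnn_config validates its architecture", {
  expect_s3_class(macnn_config(), "macnn_config")
  expect_error(macnn_config(conv_channels = c(32, 16, 64, 128, 256)),
               "increasing")
  expect_error(macnn_config(conv_channels = c(8, 16, 32, 64, 100),
                            n_heads = 3), "divisible")
  expect_error(macnn_config(n_heads = 4, head_dim = 100), "head")
  expect_error(macnn_config(dropout_rate = 1), "dropout")
  # default head_dim splits the last conv layer evenly
  cfg <- macnn_config(n_heads = 4)
  expect_equal(cfg$n_heads * cfg$head_dim, cfg$conv_channels[5])
})

test_that("assemble_features centers, resamples and encodes colour", {
  pc <- random_cloud(500, seed = 80, with_colors = TRUE)
  f <- assemble_features(pc, "xyz", n_points = 64, seed = 3)
  expect_equal(dim(f), c(64, 3))
  expect_equal(colMeans(f), rep(0, 3), tolerance = 1e-12)
  expect_identical(f, assemble_features(pc, "xyz", n_points = 64, seed = 3))
  g <- assemble_features(pc, "xyzrgb", n_points = 64, seed = 3)
  expect_equal(dim(g), c(64, 6))
  expect_true(all(g[, 4:6] >= 0 & g[, 4:6] <= 1))
  expect_equal(g[, 1:3], f)
  # upsampling small clouds works; colourless clouds refuse xyzrgb
  expect_equal(nrow(assemble_features(subset_cloud(pc, 1:5), "xyz",
                                      n_points = 32, seed = 1)), 32)
  expect_error(assemble_features(random_cloud(10, seed = 1), "xyzrgb"),
               "colou|color")
})

test_that("multi_head_attention matches an independent recomputation", {
  cfg <- tiny_cfg()
  params <- with_seed(4, pigback:::init_macnn_params(cfg))
  X <- with_seed(5, matrix(rnorm(12 * 12), 12, 12))
  out <- multi_head_attention(X, params$attn)
  expect_equal(dim(out), c(12, 12))
  manual <- NULL
  for (hp in params$attn) {
    d <- ncol(hp$Wq)
    S <- (X %*% hp$Wq) %*% t(X %*% hp$Wk) / sqrt(d)
    A <- exp(S - apply(S, 1, max))
    A <- A / rowSums(A)
    expect_equal(unname(rowSums(A)), rep(1, 12), tolerance = 1e-12)
    manual <- cbind(manual, A %*% (X %*% hp$Wv))
  }
  expect_equal(out, manual, tolerance = 1e-12)
  expect_error(multi_head_attention(X[, 1:5], params$attn), "width|match")
})

test_that("analytic gradients pass a finite-difference check", {
  cfg <- tiny_cfg()
  params <- pigback:::init_macnn_params(cfg)
  B <- 3L; n <- cfg$n_points
  X <- with_seed(6, matrix(rnorm(B * n * 3, 0, 0.5), B * n, 3))
  y <- c(-0.5, 0.2, 1.1)
  loss_at <- function(p) {
    fw <- pigback:::macnn_forward(p, cfg, X, B, train = TRUE)
    pigback:::macnn_loss(p, cfg, fw$yhat, y)
  }
  fw <- pigback:::macnn_forward(params, cfg, X, B, train = TRUE)
  g <- pigback:::macnn_backward(params, cfg, fw$cache, fw$yhat, y)
  eps <- 1e-6
  check <- function(get, set, analytic) {
    for (k in with_seed(7, sample(length(get(params)),
                                  min(4, length(get(params)))))) {
      pp <- params; v <- get(pp); v[k] <- v[k] + eps; pp <- set(pp, v)
      pm <- params; v <- get(pm); v[k] <- v[k] - eps; pm <- set(pm, v)
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      expect_equal(analytic[k], num, tolerance = 1e-4)
    }
  }
  check(function(p) p$conv[[1]]$W,
        function(p, v) { p$conv[[1]]$W[] <- v; p }, g$conv[[1]]$W)
  check(function(p) p$conv[[4]]$b,
        function(p, v) { p$conv[[4]]$b[] <- v; p }, g$conv[[4]]$b)
  check(function(p) p$bn[[3]]$gamma,
        function(p, v) { p$bn[[3]]$gamma[] <- v; p }, g$bn[[3]]$gamma)
  check(function(p) p$attn[[2]]$Wq,
        function(p, v) { p$attn[[2]]$Wq[] <- v; p }, g$attn[[2]]$dWq)
  check(function(p) p$out$W,
        function(p, v) { p$out$W[] <- v; p }, g$out$W)
})

test_that("predictions are invariant to point order", {
  cfg <- tiny_cfg()
  model <- structure(list(config = cfg,
                          params = pigback:::init_macnn_params(cfg),
                          w_mean = 220, w_sd = 35, history = NULL),
                     class = "macnn_model")
  f <- with_seed(8, matrix(rnorm(12 * 3), 12, 3))
  perm <- with_seed(9, sample(12))
  expect_equal(predict(model, f), predict(model, f[perm, ]),
               tolerance = 1e-10)
  expect_true(is.finite(predict(model, f)))
})

test_that("training reduces the loss and checkpoints round-trip", {
  cohort <- make_cohort(8, seed = 31, points_per_m2 = 300)
  cfg <- macnn_config(n_points = 32L, conv_channels = c(4L, 6L, 8L, 10L, 12L),
                      n_heads = 2L, dropout_rate = 0, learning_rate = 0.01,
                      batch_size = 8L, epochs = 40L, val_fraction = 0,
                      l2_lambda = 0, seed = 3L)
  ds <- cohort_features(cohort, n_points = 32L, seed = 1L)
  model <- train_macnn(ds, cfg)
  h <- model$history$train_loss
  expect_lt(mean(tail(h, 5)), mean(head(h, 5)))          # loss went down
  preds <- predict(model, lapply(ds, `[[`, "features"))
  expect_length(preds, 8)
  expect_true(all(is.finite(preds)))
  f <- withr::local_tempfile(fileext = ".rds")
  save_weight_model(model, f)
  back <- load_weight_model(f)
  expect_equal(predict(back, ds[[1]]$features),
               predict(model, ds[[1]]$features), tolerance = 1e-12)
  expect_error(train_macnn(ds[1], cfg), "2")
})
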