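test_that("binary relabeling folds RSN and SOZ into the non-noise class", {
  expect_equal(relabel_for_noise(c("NOISE", "RSN", "SOZ")),
               c("NOISE", "NOISE-bar", "NOISE-bar"))
  x <- rep("NOISE", 5)
  expect_equal(relabel_for_noise(x), x)
  labs <- sample(c("NOISE", "RSN", "SOZ"), 50, replace = TRUE)
  expect_length(relabel_for_noise(labs), 50L)
  expect_error(relabel_for_noise(c("NOISE", "WAT")), "unknown")
})

test_that("the default architecture matches the tuned configuration", {
  m <- build_model(cnn_config())
  convs <- Filter(function(l) l$type == "conv", m$layers)
  expect_length(convs, 3L)
  expect_equal(vapply(convs, function(l) l$filters, 0L), c(64L, 64L, 256L))
  expect_true(all(vapply(convs, function(l) all(l$kernel == c(3, 3)), TRUE)))
  pools <- Filter(function(l) l$type == "maxpool", m$layers)
  expect_length(pools, 3L)                  # one 2x2 pool after every conv
  dense <- Filter(function(l) l$type == "dense", m$layers)
  expect_equal(dense[[1]]$units, 704L)
  expect_equal(dense[[1]]$dropout, 0.33)
  expect_equal(dense[[2]]$activation, "sigmoid")
  expect_equal(m$config$learning_rate, 1e-4)
  expect_equal(m$config$input_size, c(270L, 470L, 3L))
  expect_equal(m$config$loss, "binary_crossentropy")
  expect_equal(m$config$optimizer, "adam")
  # config generality: a single conv layer
  m1 <- build_model(cnn_config(conv_filters = 8L, input_size = c(20L, 20L, 3L)))
  expect_length(Filter(function(l) l$type == "conv", m1$layers), 1L)
  expect_error(cnn_config(dropout = 0), "dropout")
  expect_error(cnn_config(learning_rate = -1), "learning_rate")
})

test_that("backpropagation matches numerical gradients", {
  cfg <- cnn_config(conv_filters = c(3L, 4L), dense_units = 5L, dropout = 0.5,
                    input_size = c(12L, 14L, 3L), seed = 3)
  model <- build_model(cfg)
  sozloc:::.cnn_init_weights(model, sozloc:::.seeded_rng(3))
  set.seed(21)
  X <- matrix(runif(12 * 14 * 3 * 3), ncol = 3)
  y <- c(1, 0, 1)
  fw <- sozloc:::.cnn_forward(model, X)
  lg <- sozloc:::.loss_grad(model, fw$out, y)
  g <- sozloc:::.cnn_backward(model, fw, lg$dZ2)
  f_loss <- function() {
    fw <- sozloc:::.cnn_forward(model, X)
    sum(sozloc:::.loss_grad(model, fw$out, y)$loss)
  }
  for (l in seq_along(model$env$weights$W)) {
    W <- model$env$weights$W[[l]]
    for (t in 1:6) {
      i <- sample(length(W), 1); eps <- 1e-5
      model$env$weights$W[[l]][i] <- W[i] + eps; lp <- f_loss()
      model$env$weights$W[[l]][i] <- W[i] - eps; lm <- f_loss()
      model$env$weights$W[[l]][i] <- W[i]
      num <- (lp - lm) / (2 * eps); an <- g$W[[l]][i]
      if (abs(num) + abs(an) > 1e-10)
        expect_lt(abs(num - an) / (abs(num) + abs(an)), 1e-4)
    }
  }
})

test_that("training is seeded, improves the loss, and predicts in [0, 1]", {
  set.seed(4)
  mk <- function(hot) {
    a <- array(runif(16 * 18 * 3, 0, 0.2) * 255, c(16, 18, 3))
    if (hot) a[5:12, 5:12, 1] <- 240
    a
  }
  imgs <- c(lapply(1:20, function(i) mk(TRUE)), lapply(1:20, function(i) mk(FALSE)))
  y <- rep(c("NOISE-bar", "NOISE"), each = 20)
  cfg <- cnn_config(conv_filters = c(4L, 4L), dense_units = 8L, dropout = 0.2,
                    input_size = c(16L, 18L, 3L), learning_rate = 3e-3,
                    max_epochs = 8L, patience = 8L, batch_size = 8L, seed = 11)
  m1 <- build_model(cfg); cnn_train(m1, imgs, y)
  h1 <- cnn_history(m1)
  expect_true(all(is.finite(h1$train_loss)))
  expect_lt(h1$train_loss[nrow(h1)], h1$train_loss[1])
  # same seed and data reproduce the epoch-1 loss exactly
  m2 <- build_model(cfg); cnn_train(m2, imgs, y)
  expect_identical(cnn_history(m2)$train_loss[1], h1$train_loss[1])
  expect_identical(m1$env$weights, m2$env$weights)
  p <- predict_noise(m1, imgs[[1]])
  expect_true(p$probability >= 0 && p$probability <= 1)
  # the hot square is the non-noise signature here
  expect_equal(p$label, "NOISE-bar")
  # tie at the threshold resolves to NOISE-bar
  expect_equal(predict_noise(m1, imgs[[1]], threshold = p$probability)$label,
               "NOISE-bar")
  expect_error(cnn_train(build_model(cfg), imgs[1:20], y[1:20]), "both classes")
  expect_error(predict_noise(m1, array(0, c(5, 5, 3))), "smaller")
})

test_that("the 3-class cost-sensitive head trains and predicts", {
  set.seed(6)
  mk <- function(cls) {
    a <- array(runif(16 * 18 * 3, 0, 0.2) * 255, c(16, 18, 3))
    if (cls == 2) a[3:8, 3:8, 1] <- 250
    if (cls == 3) a[10:15, 12:17, 1] <- 250
    a
  }
  y <- c("NOISE", "RSN", "SOZ")[c(rep(1, 14), rep(2, 14), rep(3, 4))]
  imgs <- lapply(match(y, c("NOISE", "RSN", "SOZ")), mk)
  cfg <- cnn_config(conv_filters = c(4L, 4L), dense_units = 8L, dropout = 0.2,
                    input_size = c(16L, 18L, 3L), learning_rate = 3e-3,
                    n_classes = 3L, max_epochs = 6L, patience = 6L,
                    batch_size = 8L, seed = 2)
  m <- build_model(cfg)
  cnn_train(m, imgs, y)
  out <- predict_3class(m, imgs[[1]])
  expect_equal(sum(out$probabilities), 1, tolerance = 1e-9)
  expect_true(out$label %in% c("NOISE", "RSN", "SOZ"))
  expect_error(predict_noise(m, imgs[[1]]), "binary")
})
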