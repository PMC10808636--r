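#' CNN configuration for the noise-screening arm
#'
#' Defaults are the tuned architecture for 270 x 470 x 3 montages: three
#' 3 x 3 convolution layers with 64, 64 and 256 filters, each followed by
#' 2 x 2 max pooling; a 704-unit ReLU dense layer with dropout 0.33; a
#' sigmoid output; binary cross-entropy loss with the Adam optimizer at
#' learning rate 1e-4; early stopping on validation loss.
#'
#' @param conv_filters Integer vector of filters per convolution layer.
#' @param kernel Convolution kernel size (square; default 3).
#' @param dense_units Width of the fully connected layer.
#' @param learning_rate Adam learning rate.
#' @param dropout Dropout rate on the dense layer, in (0, 1).
#' @param input_size c(height, width, channels) expected by the network.
#' @param n_classes 1 for the binary NOISE screen (sigmoid); 3 for the
#'   cost-sensitive 3-class baseline (softmax).
#' @param class_weights Optional per-class loss weights (3-class mode).
#' @param max_epochs,patience Early-stopping budget (patience on
#'   validation loss).
#' @param val_fraction Fraction of training data held out for validation.
#' @param batch_size Minibatch size.
#' @param seed Integer seed controlling init, shuffling and dropout.
#' @return Object of class `cnn_config`.
#' @export
cnn_config <- function(conv_filters = c(64L, 64L, 256L), kernel = 3L,
                       dense_units = 704L, learning_rate = 1e-4,
                       dropout = 0.33, input_size = c(270L, 470L, 3L),
                       n_classes = 1L, class_weights = NULL,
                       max_epochs = 50L, patience = 5L, val_fraction = 0.2,
                       batch_size = 16L, seed = 1L) {
  if (dropout <= 0 || dropout >= 1) stop("dropout must be in (0, 1)")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (length(conv_filters) < 1L) stop("need at least one convolution layer")
  structure(list(conv_filters = as.integer(conv_filters), kernel = as.integer(kernel),
                 dense_units = as.integer(dense_units), learning_rate = learning_rate,
                 dropout = dropout, input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes), class_weights = class_weights,
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 val_fraction = val_fraction, batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 loss = if (n_classes == 1L) "binary_crossentropy" else "weighted_categorical_crossentropy",
                 optimizer = "adam"),
            class = "cnn_config")
}

#' Reduced-scale CNN configuration
#'
#' The `small` variant used for cohort-scale experiments on a single CPU:
#' montages are downscaled to 44 x 76 and the layer widths shrunk, keeping
#' the three-conv + pool + dense + dropout topology.
#'
#' @param ... Overrides passed to [cnn_config()].
#' @return A `cnn_config`.
#' @export
cnn_small_config <- function(...) {
  args <- list(conv_filters = c(4L, 4L, 8L), dense_units = 16L,
               learning_rate = 3e-3, input_size = c(44L, 76L, 3L),
               max_epochs = 10L, patience = 3L, batch_size = 32L)
  override <- list(...)
  args[names(override)] <- override
  do.call(cnn_config, args)
}

#' Relabel a 3-class IC set for the binary noise screen
#'
#' RSN and SOZ ICs are relabeled "NOISE-bar"; NOISE is kept. Bijective over
#' ICs.
#'
#' @param labels Character vector in c("NOISE", "RSN", "SOZ").
#' @return Character vector in c("NOISE", "NOISE-bar"), same length.
#' @export
relabel_for_noise <- function(labels) {
  if (!all(labels %in% c("NOISE", "RSN", "SOZ")))
    stop("unknown label(s): ", paste(setdiff(labels, c("NOISE", "RSN", "SOZ")), collapse = ", "))
  ifelse(labels == "NOISE", "NOISE", "NOISE-bar")
}

# ---------------------------------------------------------------------------
# Layer shape chain and introspection

.cnn_shapes <- function(config) {
  h <- config$input_size[1]; w <- config$input_size[2]; cin <- config$input_size[3]
  k <- config$kernel
  layers <- list()
  for (f in config$conv_filters) {
    if (h < k || w < k) stop("input too small for the convolution chain")
    h <- h - (k - 1L); w <- w - (k - 1L)
    layers[[length(layers) + 1L]] <- list(type = "conv", filters = f,
                                          kernel = c(k, k), out = c(h, w, f),
                                          in_channels = cin)
    cin <- f
    h <- h %/% 2L; w <- w %/% 2L
    if (h < 1L || w < 1L) stop("pooling collapsed the feature map; input too small")
    layers[[length(layers) + 1L]] <- list(type = "maxpool", size = c(2L, 2L),
                                          out = c(h, w, f))
  }
  flat <- h * w * cin
  layers[[length(layers) + 1L]] <- list(type = "flatten", out = flat)
  layers[[length(layers) + 1L]] <- list(type = "dense", units = config$dense_units,
                                        activation = "relu", dropout = config$dropout)
  layers[[length(layers) + 1L]] <- list(
    type = "dense", units = config$n_classes,
    activation = if (config$n_classes == 1L) "sigmoid" else "softmax")
  layers
}

#' Build the noise-screening CNN
#'
#' Constructs the network with introspectable architecture. Weights are
#' allocated lazily (Glorot-uniform, seeded) on first training or
#' prediction, so architecture inspection is cheap even for the full-size
#' configuration.
#'
#' @param config A [cnn_config()].
#' @return Object of class `cnn_model` with `config`, `layers` (shape
#'   chain) and an environment holding weights once initialized.
#' @export
build_model <- function(config = cnn_config()) {
  layers <- .cnn_shapes(config)
  structure(list(config = config, layers = layers,
                 env = new.env(parent = emptyenv())),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> input %s | %s | trained: %s\n",
              paste(x$config$input_size, collapse = "x"),
              paste(vapply(x$layers, function(l) switch(l$type,
                conv = sprintf("conv%dx%d(%d)", l$kernel[1], l$kernel[2], l$filters),
                maxpool = "pool2x2",
                flatten = sprintf("flat(%d)", l$out),
                dense = sprintf("dense(%d,%s)", l$units, l$activation)), ""),
                collapse = " -> "),
              !is.null(x$env$weights)))
  invisible(x)
}

.glorot <- function(rng, n_in, n_out, dims) {
  lim <- sqrt(6 / (n_in + n_out))
  array(rng$unif(prod(dims)) * 2 * lim - lim, dims)
}

.cnn_init_weights <- function(model, rng) {
  cfg <- model$config
  k2 <- cfg$kernel^2
  W <- list(); b <- list()
  cin <- cfg$input_size[3]
  for (f in cfg$conv_filters) {
    W[[length(W) + 1L]] <- .glorot(rng, k2 * cin, f, c(k2 * cin, f))
    b[[length(b) + 1L]] <- numeric(f)
    cin <- f
  }
  flat <- Filter(function(l) l$type == "flatten", model$layers)[[1]]$out
  W[[length(W) + 1L]] <- .glorot(rng, flat, cfg$dense_units, c(flat, cfg$dense_units))
  b[[length(b) + 1L]] <- numeric(cfg$dense_units)
  W[[length(W) + 1L]] <- .glorot(rng, cfg$dense_units, cfg$n_classes,
                                 c(cfg$dense_units, cfg$n_classes))
  b[[length(b) + 1L]] <- numeric(cfg$n_classes)
  model$env$weights <- list(W = W, b = b)
  invisible(model)
}

# Precompute layer dimensions and pooling index maps.
.cnn_plan <- function(model) {
  if (!is.null(model$env$plan)) return(model$env$plan)
  cfg <- model$config
  k <- cfg$kernel
  h <- cfg$input_size[1]; w <- cfg$input_size[2]; cin <- cfg$input_size[3]
  plan <- list()
  for (f in cfg$conv_filters) {
    ho <- h - (k - 1L); wo <- w - (k - 1L)
    hp <- ho %/% 2L; wp <- wo %/% 2L
    plan[[length(plan) + 1L]] <- list(conv_dim = c(ho, wo),
                                      in_dim = c(h, w, cin),
                                      pool_dim = c(hp, wp),
                                      in_len = h * w * cin, channels = f)
    h <- hp; w <- wp; cin <- f
  }
  model$env$plan <- plan
  plan
}

# Forward pass for a batch. `X` is (input length) x B; `drop_mask` an
# optional dense_units x B inverted-dropout mask. Returns activations.
.cnn_forward <- function(model, X, drop_mask = NULL) {
  if (is.null(dim(X))) X <- matrix(X, length(X), 1L)
  B <- ncol(X)
  wts <- model$env$weights
  plan <- .cnn_plan(model)
  nconv <- length(model$config$conv_filters)
  acts <- list(X = vector("list", nconv), Z = vector("list", nconv),
               arg = vector("list", nconv))
  a <- X
  for (l in seq_len(nconv)) {
    pl <- plan[[l]]
    Z <- cpp_conv_fwd(a, wts$W[[l]], wts$b[[l]],
                      pl$in_dim[1], pl$in_dim[2], pl$in_dim[3],
                      model$config$kernel)
    rp <- cpp_relu_pool(Z, pl$conv_dim[1], pl$conv_dim[2])
    f <- pl$channels
    npool <- prod(pl$pool_dim)
    acts$X[[l]] <- a; acts$Z[[l]] <- Z; acts$arg[[l]] <- rp$arg
    # rows of M are (pool position, image); regroup to (position, channel) x image
    M <- rp$M
    dim(M) <- c(npool, B, f)
    a <- aperm(M, c(1, 3, 2))
    dim(a) <- c(npool * f, B)
  }
  ld <- nconv + 1L
  Z1 <- crossprod(wts$W[[ld]], a) + wts$b[[ld]]
  A1 <- Z1 * (Z1 > 0)
  if (!is.null(drop_mask)) A1 <- A1 * drop_mask
  Z2 <- crossprod(wts$W[[ld + 1L]], A1) + wts$b[[ld + 1L]]
  out <- if (model$config$n_classes == 1L) {
    1 / (1 + exp(-Z2))
  } else {
    e <- exp(sweep(Z2, 2, apply(Z2, 2, max)))
    sweep(e, 2, colSums(e), `/`)
  }
  list(acts = acts, flat = a, Z1 = Z1, A1 = A1, out = out, B = B)
}

# Backward pass for a batch; `dZ2` is n_classes x B (summed over the batch
# by the caller's averaging). Returns summed per-weight gradients.
.cnn_backward <- function(model, fw, dZ2, drop_mask = NULL) {
  wts <- model$env$weights
  plan <- .cnn_plan(model)
  nconv <- length(model$config$conv_filters)
  B <- fw$B
  ld <- nconv + 1L
  gW <- vector("list", ld + 1L); gb <- vector("list", ld + 1L)
  gW[[ld + 1L]] <- fw$A1 %*% t(dZ2)
  gb[[ld + 1L]] <- rowSums(dZ2)
  dA1 <- wts$W[[ld + 1L]] %*% dZ2
  if (!is.null(drop_mask)) dA1 <- dA1 * drop_mask
  dZ1 <- dA1 * (fw$Z1 > 0)
  gW[[ld]] <- fw$flat %*% t(dZ1)
  gb[[ld]] <- rowSums(dZ1)
  dX <- wts$W[[ld]] %*% dZ1                       # (npool*f) x B
  for (l in rev(seq_len(nconv))) {
    pl <- plan[[l]]
    f <- pl$channels
    npool <- prod(pl$pool_dim)
    dim(dX) <- c(npool, f, B)
    dM <- aperm(dX, c(1, 3, 2))
    dim(dM) <- c(npool * B, f)
    dA <- cpp_pool_bwd(dM, fw$acts$arg[[l]], nrow(fw$acts$Z[[l]]))
    dZ <- dA * (fw$acts$Z[[l]] > 0)
    res <- cpp_conv_bwd(fw$acts$X[[l]], wts$W[[l]], dZ,
                        pl$in_dim[1], pl$in_dim[2], pl$in_dim[3],
                        model$config$kernel, l > 1L)
    gW[[l]] <- res$gW
    gb[[l]] <- res$gb
    if (l > 1L) dX <- res$dX
  }
  list(W = gW, b = gb)
}

# Batched loss and output-preactivation gradient. `out` is n_classes x B,
# `y` a length-B numeric (binary) or integer (3-class) vector.
.loss_grad <- function(model, out, y, class_weights = NULL) {
  if (model$config$n_classes == 1L) {
    p <- pmin(pmax(out[1, ], 1e-12), 1 - 1e-12)
    list(loss = -(y * log(p) + (1 - y) * log(1 - p)),
         dZ2 = matrix(out[1, ] - y, 1L))
  } else {
    w <- class_weights
    if (is.null(w)) w <- rep(1, model$config$n_classes)
    B <- ncol(out)
    py <- pmax(out[cbind(y, seq_len(B))], 1e-12)
    onehot <- matrix(0, nrow(out), B)
    onehot[cbind(y, seq_len(B))] <- 1
    dZ2 <- sweep(out - onehot, 2, w[y], `*`)
    list(loss = -w[y] * log(py), dZ2 = dZ2)
  }
}

# Montage -> network input vector, scaled to [0, 1]; a 270x470 montage is
# downscaled to the configured input size when the config is smaller.
.cnn_input <- function(model, m) {
  px <- if (inherits(m, "ic_montage")) m$pixels else m
  d <- dim(px)
  tgt <- model$config$input_size
  if (!all(d[1:2] == tgt[1:2])) {
    if (inherits(m, "ic_montage") && isTRUE(m$native))
      stop("montage must be resized (see resize_montage()) before the CNN")
    if (d[1] < tgt[1] || d[2] < tgt[2])
      stop(sprintf("input %dx%d smaller than configured %dx%d", d[1], d[2], tgt[1], tgt[2]))
    out <- array(0, tgt)
    for (ch in 1:3) out[, , ch] <- .resize_mat(px[, , ch], tgt[1], tgt[2])
    px <- out
  }
  as.vector(px) / 255
}

#' Train the CNN
#'
#' Seeded training with Adam, the configured loss, dropout on the dense
#' layer, a validation split and early stopping (patience on validation
#' loss, best weights restored).
#'
#' @param model A [build_model()] result.
#' @param images List of resized [ic_montage()]s (or raw H x W x 3 arrays).
#' @param labels For the binary screen: character in c("NOISE",
#'   "NOISE-bar") or 0/1 numeric (NOISE-bar encoded as 1). For 3-class:
#'   integer 1..3 or c("NOISE", "RSN", "SOZ").
#' @return The model (weights updated in place) with `history` (data frame
#'   of per-epoch train/validation loss) stored in `model$env`.
#' @export
cnn_train <- function(model, images, labels) {
  cfg <- model$config
  if (cfg$n_classes == 1L) {
    if (is.character(labels)) {
      if (!all(labels %in% c("NOISE", "NOISE-bar"))) stop("binary labels must be NOISE / NOISE-bar")
      y <- as.numeric(labels == "NOISE-bar")
    } else y <- as.numeric(labels)
    if (length(unique(y)) < 2L) stop("training data must contain both classes")
  } else {
    if (is.character(labels)) {
      if (!all(labels %in% c("NOISE", "RSN", "SOZ"))) stop("labels must be NOISE/RSN/SOZ")
      y <- match(labels, c("NOISE", "RSN", "SOZ"))
    } else y <- as.integer(labels)
    if (is.null(cfg$class_weights)) {
      tab <- tabulate(y, cfg$n_classes)
      model$config$class_weights <- length(y) / (cfg$n_classes * pmax(tab, 1))
      cfg <- model$config
    }
  }
  rng <- .seeded_rng(cfg$seed)
  if (is.null(model$env$weights)) .cnn_init_weights(model, rng)
  XS <- vapply(images, function(m) .cnn_input(model, m),
               numeric(prod(cfg$input_size)))

  n <- ncol(XS)
  ord <- order(rng$unif(n))
  n_val <- max(1L, round(cfg$val_fraction * n))
  val_i <- ord[seq_len(n_val)]
  tr_i <- ord[-seq_len(n_val)]

  wts_names <- seq_along(model$env$weights$W)
  mom <- list(mW = lapply(model$env$weights$W, function(w) w * 0),
              vW = lapply(model$env$weights$W, function(w) w * 0),
              mb = lapply(model$env$weights$b, function(b) b * 0),
              vb = lapply(model$env$weights$b, function(b) b * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; tstep <- 0
  best_val <- Inf; best_wts <- NULL; wait <- 0L
  hist <- NULL
  cw <- cfg$class_weights

  val_loss <- function() {
    fw <- .cnn_forward(model, XS[, val_i, drop = FALSE])
    mean(.loss_grad(model, fw$out, y[val_i], cw)$loss)
  }

  for (epoch in seq_len(cfg$max_epochs)) {
    ep_ord <- tr_i[order(rng$unif(length(tr_i)))]
    ep_loss <- 0
    batches <- split(ep_ord, ceiling(seq_along(ep_ord) / cfg$batch_size))
    for (bt in batches) {
      B <- length(bt)
      dm <- if (cfg$dropout > 0) {
        matrix((rng$unif(cfg$dense_units * B) >= cfg$dropout) / (1 - cfg$dropout),
               cfg$dense_units, B)
      } else NULL
      fw <- .cnn_forward(model, XS[, bt, drop = FALSE], drop_mask = dm)
      lg <- .loss_grad(model, fw$out, y[bt], cw)
      ep_loss <- ep_loss + sum(lg$loss)
      acc <- .cnn_backward(model, fw, lg$dZ2, drop_mask = dm)
      tstep <- tstep + 1
      corr1 <- 1 - beta1^tstep; corr2 <- 1 - beta2^tstep
      for (l in wts_names) {
        gw <- acc$W[[l]] / length(bt); gb2 <- acc$b[[l]] / length(bt)
        mom$mW[[l]] <- beta1 * mom$mW[[l]] + (1 - beta1) * gw
        mom$vW[[l]] <- beta2 * mom$vW[[l]] + (1 - beta2) * gw^2
        mom$mb[[l]] <- beta1 * mom$mb[[l]] + (1 - beta1) * gb2
        mom$vb[[l]] <- beta2 * mom$vb[[l]] + (1 - beta2) * gb2^2
        model$env$weights$W[[l]] <- model$env$weights$W[[l]] -
          cfg$learning_rate * (mom$mW[[l]] / corr1) / (sqrt(mom$vW[[l]] / corr2) + eps)
        model$env$weights$b[[l]] <- model$env$weights$b[[l]] -
          cfg$learning_rate * (mom$mb[[l]] / corr1) / (sqrt(mom$vb[[l]] / corr2) + eps)
      }
    }
    vl <- val_loss()
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = ep_loss / length(tr_i),
                                   val_loss = vl))
    if (vl < best_val - 1e-6) {
      best_val <- vl
      best_wts <- list(W = lapply(model$env$weights$W, identity),
                       b = lapply(model$env$weights$b, identity))
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  if (!is.null(best_wts)) model$env$weights <- best_wts
  model$env$history <- hist
  invisible(model)
}

#' Predict the binary noise label of one resized montage
#'
#' Dropout is disabled at inference; prediction is deterministic given
#' fixed weights. Probability is of the NOISE-bar (non-noise) class; the
#' tie at exactly the threshold goes to NOISE-bar.
#'
#' @param model Trained binary [build_model()].
#' @param m Resized [ic_montage()] (or array).
#' @param threshold Decision threshold (default 0.5).
#' @return List `(probability, label)`, label in c("NOISE", "NOISE-bar").
#' @export
predict_noise <- function(model, m, threshold = 0.5) {
  if (model$config$n_classes != 1L) stop("predict_noise needs a binary model")
  if (is.null(model$env$weights)) stop("model is not trained")
  fw <- .cnn_forward(model, .cnn_input(model, m))
  p <- as.numeric(fw$out)
  list(probability = p, label = if (p >= threshold) "NOISE-bar" else "NOISE")
}

#' Predict 3-class probabilities (cost-sensitive CNN baseline)
#'
#' @param model Trained 3-class [build_model()].
#' @param m Resized [ic_montage()] (or array).
#' @return List `(probabilities, label)`, label in c("NOISE","RSN","SOZ").
#' @export
predict_3class <- function(model, m) {
  if (model$config$n_classes != 3L) stop("predict_3class needs a 3-class model")
  if (is.null(model$env$weights)) stop("model is not trained")
  fw <- .cnn_forward(model, .cnn_input(model, m))
  p <- as.numeric(fw$out)
  names(p) <- c("NOISE", "RSN", "SOZ")
  list(probabilities = p, label = names(p)[which.max(p)])
}

#' Training history of a trained CNN
#' @param model A trained `cnn_model`.
#' @return Data frame with epoch, train_loss, val_loss.
#' @export
cnn_history <- function(model) model$env$history
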