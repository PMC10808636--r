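#' Expert feature vector of one IC
#'
#' The four expert features describing SOZ-likeness of an IC: activation
#' cluster count/asymmetry score, white-matter-to-ventricle extension
#' fraction, wavelet-domain (activelet) Gini sparsity and sine-dictionary
#' Gini sparsity of the BOLD time course. A logical `mask` selects the
#' features enabled for a given (possibly ablated) model.
#'
#' @param values Numeric feature vector.
#' @param ic_id Optional identifier.
#' @param mask Logical vector of enabled features (default all).
#' @return Object of class `expert_features`.
#' @export
expert_features <- function(values, ic_id = NA_character_,
                            mask = rep(TRUE, length(values))) {
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("feature values must be finite")
  if (length(mask) != length(values)) stop("mask length must match values")
  if (sum(mask) < 1L) stop("at least one feature must be enabled")
  structure(list(values = values, ic_id = ic_id, mask = as.logical(mask)),
            class = "expert_features")
}

.feature_names <- c("f_clusters", "f_wm_ventricle", "activelet_gini", "sine_gini")

.enabled_values <- function(f) {
  if (inherits(f, "expert_features")) f$values[f$mask] else as.numeric(f)
}

#' Build EKI training pairs from labeled feature vectors
#'
#' Each RSN or SOZ IC contributes a pair (F-hat, y) where F-hat is the
#' L2-normalized enabled feature vector and y is -1 for RSN, +1 for SOZ.
#' Zero feature vectors are kept as zero (they cannot be normalized) and a
#' warning is raised.
#'
#' @param features List of [expert_features()] (or numeric vectors).
#' @param labels Character vector in `c("RSN", "SOZ")`.
#' @return List of pairs, each `list(fhat, y, synthetic = FALSE)`.
#' @export
training_pairs <- function(features, labels) {
  if (length(features) != length(labels)) stop("features/labels length mismatch")
  if (!all(labels %in% c("RSN", "SOZ")))
    stop("labels must be RSN or SOZ (noise ICs are handled by the CNN arm)")
  lapply(seq_along(features), function(i) {
    v <- .enabled_values(features[[i]])
    nv <- sqrt(sum(v^2))
    if (nv > 0) v <- v / nv else warning("zero feature vector in training pairs")
    list(fhat = v, y = if (labels[i] == "SOZ") 1 else -1, synthetic = FALSE)
  })
}

#' Balance RSN/SOZ training pairs with SMOTE
#'
#' Synthetic minority over-sampling: new minority samples are drawn by
#' linear interpolation between a minority sample and one of its k nearest
#' minority neighbors (Euclidean distance in feature space), until both
#' classes have equal counts. Synthetic pairs are flagged.
#'
#' @param pairs List of training pairs from [training_pairs()].
#' @param k_neighbors Number of minority neighbors considered (default 5,
#'   clipped to minority size - 1).
#' @param seed Integer seed for the interpolation draws.
#' @return Balanced list of pairs; synthetic entries have `synthetic = TRUE`.
#' @export
balance_with_smote <- function(pairs, k_neighbors = 5L, seed = 1L) {
  y <- vapply(pairs, function(p) p$y, 0)
  n_pos <- sum(y > 0); n_neg <- sum(y < 0)
  if (n_pos == n_neg) return(pairs)
  minority_y <- if (n_pos < n_neg) 1 else -1
  idx <- which(y == minority_y)
  if (length(idx) < 2L)
    stop("SMOTE needs at least 2 minority samples")
  X <- do.call(rbind, lapply(pairs[idx], function(p) p$fhat))
  k <- max(1L, min(as.integer(k_neighbors), nrow(X) - 1L))
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  nn <- do.call(rbind, lapply(seq_len(nrow(X)),
                              function(i) order(D[i, ])[seq_len(k)]))
  n_new <- abs(n_pos - n_neg)
  rng <- .seeded_rng(seed)
  base <- rng$int(n_new, nrow(X))
  pick <- rng$int(n_new, k)
  gap <- rng$unif(n_new)
  synth <- lapply(seq_len(n_new), function(i) {
    a <- X[base[i], ]; b <- X[nn[base[i], pick[i]], ]
    list(fhat = a + gap[i] * (b - a), y = minority_y, synthetic = TRUE)
  })
  c(pairs, synth)
}

# Small deterministic RNG helper: isolates the package's stochastic steps
# from the caller's RNG state.
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- f()
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(
    unif = function(n, max = 1) with_state(function() stats::runif(n, 0, max)),
    norm = function(n, sd = 1) with_state(function() stats::rnorm(n, 0, sd)),
    int = function(n, max) with_state(function() sample.int(max, n, replace = TRUE)),
    pick = function(x, n = 1, replace = FALSE) with_state(function() {
      if (length(x) == 1L && is.numeric(x)) x else x[sample.int(length(x), n, replace = replace)]
    })
  )
}

#' Fit the expert-knowledge weight vector
#'
#' Solves the equality-constrained least squares problem
#' minimize sum_i (1 - y_i * w . fhat_i)^2 subject to sum(w) = 1.
#' Among minimizers the minimum-norm one is returned (pseudo-inverse in the
#' constraint null space). Weights are not sign-constrained.
#'
#' @param pairs Balanced training pairs (real and/or SMOTE-synthetic).
#' @param rho_threshold Confidence threshold stored on the model
#'   (default 0.9, used by the fusion rule).
#' @param feature_mask Logical mask of enabled features recorded on the
#'   model (bookkeeping for ablation runs).
#' @return Object of class `eki_model` with `omega`, `rho_threshold`,
#'   `objective`, `n_pairs`, `feature_mask`.
#' @export
fit_weights <- function(pairs, rho_threshold = 0.9, feature_mask = NULL) {
  if (length(pairs) < 2L) stop("need at least one pair per class")
  y <- vapply(pairs, function(p) p$y, 0)
  if (!any(y > 0) || !any(y < 0)) stop("need both RSN and SOZ pairs")
  X <- do.call(rbind, lapply(pairs, function(p) {
    v <- p$fhat; nv <- sqrt(sum(v^2)); if (nv > 0) v / nv else v
  }))
  d <- ncol(X)
  A <- X * y                         # rows y_i * fhat_i
  b <- rep(1, length(y))
  if (d == 1L) {
    omega <- 1
  } else {
    # parametrize w = w0 + Z t with w0 = 1/d (min-norm feasible point) and
    # Z an orthonormal basis of the null space of the sum constraint;
    # w0 is orthogonal to range(Z), so min-norm t gives the min-norm w.
    w0 <- rep(1 / d, d)
    Z <- qr.Q(qr(cbind(rep(1, d))), complete = TRUE)[, -1, drop = FALSE]
    M <- A %*% Z
    r <- b - A %*% w0
    sv <- svd(M)
    # rank tolerance on the scale of the full design, so a feature
    # direction that is numerically absent (duplicated columns) is dropped
    tol <- max(dim(M)) * .Machine$double.eps * max(c(sv$d, sqrt(sum(A^2))))
    pos <- sv$d > tol
    t_hat <- if (any(pos)) {
      sv$v[, pos, drop = FALSE] %*% ((crossprod(sv$u[, pos, drop = FALSE], r)) / sv$d[pos])
    } else {
      matrix(0, ncol(M), 1)
    }
    if (!any(pos))
      warning("degenerate EKI fit: features carry no class signal; returning uniform weights")
    omega <- as.numeric(w0 + Z %*% t_hat)
  }
  obj <- sum((b - A %*% omega)^2)
  if (is.null(feature_mask)) feature_mask <- rep(TRUE, d)
  structure(list(omega = omega, rho_threshold = rho_threshold,
                 objective = obj, n_pairs = length(pairs),
                 feature_mask = as.logical(feature_mask)),
            class = "eki_model")
}

#' @export
print.eki_model <- function(x, ...) {
  nm <- .feature_names[x$feature_mask]
  if (length(nm) != length(x$omega)) nm <- paste0("f", seq_along(x$omega))
  cat("<eki_model>\n  omega:",
      paste(sprintf("%s=%.3f", nm, x$omega), collapse = ", "),
      sprintf("\n  sum(omega)=%.6f, objective=%.4g, pairs=%d, rho*=%.2f\n",
              sum(x$omega), x$objective, x$n_pairs, x$rho_threshold))
  invisible(x)
}

#' Confidence score of an IC being SOZ
#'
#' rho = omega . F / ||F|| with the L2 norm; scale-invariant in F. A zero
#' feature vector is assigned rho = 0 with a warning.
#'
#' @param model An [fit_weights()] model.
#' @param f An [expert_features()] or numeric vector (enabled features).
#' @return Numeric confidence score rho.
#' @export
confidence_score <- function(model, f) {
  v <- .enabled_values(f)
  if (length(v) != length(model$omega))
    stop("feature vector length does not match model weights")
  nv <- sqrt(sum(v^2))
  if (nv == 0) {
    warning("zero feature vector: rho defined as 0")
    return(0)
  }
  sum(model$omega * v) / nv
}

#' Classify an IC as RSN or SOZ with explanation
#'
#' The sign of rho implements the +/-1 target coding: rho > 0 is SOZ. The
#' explanation is the enabled feature with the largest contribution
#' omega_j * F_j to the score.
#'
#' @inheritParams confidence_score
#' @return List with `label` ("RSN"/"SOZ"), `rho`, `explanation` (feature
#'   name) and `contributions` (named numeric vector).
#' @export
classify_eki <- function(model, f) {
  v <- .enabled_values(f)
  rho <- confidence_score(model, f)
  contrib <- model$omega * v
  nm <- .feature_names[model$feature_mask]
  if (length(nm) != length(contrib)) nm <- paste0("f", seq_along(contrib))
  names(contrib) <- nm
  list(label = if (rho > 0) "SOZ" else "RSN",
       rho = rho,
       explanation = nm[which.max(contrib)],
       contributions = contrib)
}
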