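test_that("training pairs carry unit-norm features and +/-1 targets", {
  f <- list(expert_features(c(1, 2, 2, 0)), expert_features(c(0, 3, 0, 4)))
  p <- training_pairs(f, c("RSN", "SOZ"))
  expect_equal(vapply(p, function(x) sqrt(sum(x$fhat^2)), 0), c(1, 1), tolerance = 1e-9)
  expect_equal(vapply(p, function(x) x$y, 0), c(-1, 1))
  expect_error(training_pairs(f, c("RSN", "NOISE")), "RSN or SOZ")
})

test_that("SMOTE balances classes by interpolating minority neighbors", {
  set.seed(1)
  maj <- lapply(1:10, function(i) list(fhat = rnorm(4), y = -1, synthetic = FALSE))
  a <- c(1, 0, 0, 0); b <- c(0, 1, 0, 0)
  minr <- list(list(fhat = a, y = 1, synthetic = FALSE),
               list(fhat = b, y = 1, synthetic = FALSE))
  out <- balance_with_smote(c(maj, minr), k_neighbors = 1, seed = 5)
  y <- vapply(out, function(p) p$y, 0)
  expect_equal(sum(y > 0), sum(y < 0))
  synth <- Filter(function(p) isTRUE(p$synthetic), out)
  expect_length(synth, 8L)
  for (s in synth) {
    # with k = 1 every synthetic point lies on the segment between a and b
    expect_equal(s$fhat, a + s$fhat[2] * (b - a), tolerance = 1e-9)
    expect_true(all(s$fhat >= pmin(a, b) - 1e-12 & s$fhat <= pmax(a, b) + 1e-12))
  }
  # already balanced input is returned unchanged
  expect_identical(balance_with_smote(c(maj[1:2], minr)), c(maj[1:2], minr))
  expect_error(balance_with_smote(c(maj, minr[1])), "2 minority")
})

test_that("SMOTE is deterministic under a fixed seed", {
  maj <- lapply(1:9, function(i) list(fhat = c(i, 1, 0, 0) / i, y = -1, synthetic = FALSE))
  minr <- lapply(1:3, function(i) list(fhat = c(0, 0, i, 1) / i, y = 1, synthetic = FALSE))
  expect_identical(balance_with_smote(c(maj, minr), seed = 9),
                   balance_with_smote(c(maj, minr), seed = 9))
})

test_that("constrained weight fit reproduces closed-form cases", {
  # d = 1: the constraint forces omega = 1
  p1 <- list(list(fhat = 1, y = 1, synthetic = FALSE),
             list(fhat = 1, y = -1, synthetic = FALSE))
  expect_equal(fit_weights(p1)$omega, 1)
  # a perfectly separating first feature with an inert second one
  p2 <- c(lapply(1:5, function(i) list(fhat = c(1, 0), y = 1, synthetic = FALSE)),
          lapply(1:5, function(i) list(fhat = c(-1, 0), y = -1, synthetic = FALSE)))
  fit2 <- fit_weights(p2)
  expect_equal(fit2$omega, c(1, 0), tolerance = 1e-9)
  expect_lt(fit2$objective, 1e-18)
  # duplicated identical features: minimum-norm tie-break splits evenly
  # (with a warning, since the constraint alone fixes the solution)
  p3 <- c(lapply(1:4, function(i) list(fhat = c(1, 1) / sqrt(2), y = 1, synthetic = FALSE)),
          lapply(1:4, function(i) list(fhat = c(-1, -1) / sqrt(2), y = -1, synthetic = FALSE)))
  expect_warning(f3 <- fit_weights(p3), "degenerate")
  expect_equal(f3$omega, c(0.5, 0.5), tolerance = 1e-9)
})

test_that("weight fit matches a dense grid search on toy problems", {
  set.seed(77)
  for (rep in 1:6) {
    d <- sample(2:3, 1)
    n <- 14
    pairs <- lapply(seq_len(n), function(i) {
      y <- if (i <= n / 2) 1 else -1
      f <- rnorm(d) + y * c(1.2, seq_len(d - 1) * 0.3)
      list(fhat = f / sqrt(sum(f^2)), y = y, synthetic = FALSE)
    })
    fit <- fit_weights(pairs)
    ora <- oracle_fit_grid(pairs)
    expect_equal(sum(fit$omega), 1, tolerance = 1e-9)
    expect_lte(fit$objective, ora$objective + 1e-3)
  }
})

test_that("every fit satisfies the sum-to-one constraint to 1e-9", {
  set.seed(3)
  for (rep in 1:25) {
    d <- sample(1:4, 1)
    pairs <- lapply(1:10, function(i) {
      f <- rnorm(d)
      list(fhat = f / sqrt(sum(f^2)), y = sample(c(-1, 1), 1), synthetic = FALSE)
    })
    if (length(unique(vapply(pairs, function(p) p$y, 0))) < 2) next
    expect_lt(abs(sum(fit_weights(pairs)$omega) - 1), 1e-9)
  }
})

test_that("confidence score is the normalized weighted projection", {
  m4 <- structure(list(omega = c(1, 0, 0, 0), rho_threshold = 0.9,
                       feature_mask = rep(TRUE, 4)), class = "eki_model")
  expect_equal(confidence_score(m4, c(2, 0, 0, 0)), 1)
  m2 <- structure(list(omega = c(0.5, 0.5), rho_threshold = 0.9,
                       feature_mask = c(TRUE, TRUE, FALSE, FALSE)), class = "eki_model")
  expect_equal(confidence_score(m2, c(3, 4)), 0.7)
  f <- c(0.3, 1.1)
  expect_equal(confidence_score(m2, 10 * f), confidence_score(m2, f), tolerance = 1e-12)
  expect_warning(z <- confidence_score(m2, c(0, 0)), "zero")
  expect_equal(z, 0)
})

test_that("classification uses the sign rule and explains by top contribution", {
  m2 <- structure(list(omega = c(0.7, 0.3), rho_threshold = 0.9,
                       feature_mask = c(TRUE, TRUE, FALSE, FALSE)), class = "eki_model")
  expect_equal(classify_eki(m2, c(0.9, 0.8))$label, "SOZ")
  neg <- structure(list(omega = c(-1, 2), rho_threshold = 0.9,
                        feature_mask = c(TRUE, TRUE, FALSE, FALSE)), class = "eki_model")
  expect_equal(classify_eki(neg, c(1, 0))$label, "RSN")
  out <- classify_eki(m2, c(0.2, 0.9))
  expect_equal(unname(out$contributions), c(0.14, 0.27), tolerance = 1e-12)
  expect_equal(out$explanation, "f_wm_ventricle")
})

test_that("degenerate fits warn and fall back to uniform weights", {
  pairs <- c(lapply(1:3, function(i) list(fhat = c(1, 0), y = 1, synthetic = FALSE)),
             lapply(1:3, function(i) list(fhat = c(1, 0), y = -1, synthetic = FALSE)))
  # same features for both classes: no signal along the constraint line in
  # the second coordinate; solution stays finite with sum 1
  fit <- fit_weights(pairs)
  expect_lt(abs(sum(fit$omega) - 1), 1e-9)
  expect_true(all(is.finite(fit$omega)))
})
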