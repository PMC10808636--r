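# Independent reference implementations used to cross-check the package.

# Brute-force DBSCAN by O(n^2) neighborhood expansion over the pixel list.
# Returns core pixel ids (row-col strings), the partition of cores into
# clusters, border assignments (pixel -> set of admissible clusters, i.e.
# clusters holding a core at minimal distance), and disregarded pixels.
oracle_dbscan <- function(mask, epsilon, v_min) {
  pts <- which(mask, arr.ind = TRUE)
  n <- nrow(pts)
  key <- function(p) paste(p[, 1], p[, 2], sep = "_")
  if (n == 0) return(list(cores = character(0), partition = list(),
                          border = list(), noise = character(0)))
  D <- as.matrix(stats::dist(pts))
  nb <- rowSums(D <= epsilon + 1e-12) - 1
  core <- nb > v_min
  lab <- rep(NA_integer_, n)
  cl <- 0L
  for (i in which(core)) {
    if (!is.na(lab[i])) next
    cl <- cl + 1L
    queue <- i
    lab[i] <- cl
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      nbrs <- which(core & D[j, ] <= epsilon + 1e-12 & is.na(lab))
      lab[nbrs] <- cl
      queue <- c(queue, nbrs)
    }
  }
  border <- list()
  noise <- character(0)
  for (i in which(!core)) {
    dc <- D[i, core]
    if (length(dc) == 0 || min(dc) > epsilon + 1e-12) {
      noise <- c(noise, key(pts[i, , drop = FALSE]))
    } else {
      dmin <- min(dc)
      adm <- unique(lab[core][abs(dc - dmin) < 1e-9])
      border[[key(pts[i, , drop = FALSE])]] <- adm
    }
  }
  partition <- split(key(pts[core, , drop = FALSE]), lab[core])
  list(cores = key(pts[core, , drop = FALSE]), partition = partition,
       border = border, noise = noise)
}

# Gini index by the mean-absolute-difference identity.
oracle_gini <- function(x) {
  n <- length(x)
  if (sum(x) == 0) return(0)
  sum(abs(outer(x, x, `-`))) / (2 * n^2 * mean(x))
}

# EKI objective for a given weight vector.
eki_objective <- function(omega, pairs) {
  sum(vapply(pairs, function(p) {
    f <- p$fhat / sqrt(sum(p$fhat^2))
    (1 - p$y * sum(omega * f))^2
  }, 0))
}

# Dense search over the sum-to-one constraint set (d = 2 or 3).
oracle_fit_grid <- function(pairs, lo = -2, hi = 3, step = 0.005) {
  d <- length(pairs[[1]]$fhat)
  if (d == 2) {
    w1 <- seq(lo, hi, by = step)
    obj <- vapply(w1, function(a) eki_objective(c(a, 1 - a), pairs), 0)
    list(omega = c(w1[which.min(obj)], 1 - w1[which.min(obj)]), objective = min(obj))
  } else if (d == 3) {
    g <- expand.grid(w1 = seq(lo, hi, by = step * 8), w2 = seq(lo, hi, by = step * 8))
    obj <- mapply(function(a, b) eki_objective(c(a, b, 1 - a - b), pairs), g$w1, g$w2)
    i <- which.min(obj)
    list(omega = c(g$w1[i], g$w2[i], 1 - g$w1[i] - g$w2[i]), objective = min(obj))
  } else stop("oracle supports d = 2 or 3")
}

# Point-in-convex-hull test (ray-free: all cross products one-signed).
in_convex_hull <- function(pt, hull_pts) {
  h <- hull_pts[grDevices::chull(hull_pts), , drop = FALSE]
  n <- nrow(h)
  if (n < 3) return(FALSE)
  s <- 0
  for (i in seq_len(n)) {
    a <- h[i, ]; b <- h[if (i == n) 1 else i + 1, ]
    cr <- (b[1] - a[1]) * (pt[2] - a[2]) - (b[2] - a[2]) * (pt[1] - a[1])
    if (abs(cr) < 1e-9) next
    if (s == 0) s <- sign(cr)
    else if (sign(cr) != s) return(FALSE)
  }
  TRUE
}
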