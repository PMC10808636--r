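#' DBSCAN parameters for activation clustering
#'
#' Density-based clustering of activation pixels. A pixel with more than
#' `v_min` neighbors within distance `epsilon` is a core point; core points
#' within `epsilon` of each other merge into one cluster; non-core pixels
#' within `epsilon` of a core point are border points assigned to the
#' nearest core point's cluster; all other pixels are disregarded. Only
#' clusters strictly larger than `min_cluster_px` pixels are retained.
#'
#' @param epsilon Neighborhood radius in pixels (default 2).
#' @param v_min Minimum neighbor count for a core point (default 4; a pixel
#'   needs strictly more than `v_min` neighbors).
#' @param min_cluster_px Retention threshold in pixels (default 135; strict
#'   "greater than" comparison).
#' @return An object of class `dbscan_params`.
#' @export
dbscan_params <- function(epsilon = 2, v_min = 4L, min_cluster_px = 135L) {
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (v_min < 1) stop("v_min must be >= 1")
  if (min_cluster_px < 1) stop("min_cluster_px must be >= 1")
  structure(list(epsilon = as.numeric(epsilon), v_min = as.integer(v_min),
                 min_cluster_px = as.integer(min_cluster_px)),
            class = "dbscan_params")
}

# Integer pixel offsets (dr, dc) with 0 < dr^2 + dc^2 <= epsilon^2,
# ordered by increasing distance (used for nearest-core tie handling).
.epsilon_offsets <- function(epsilon) {
  r <- floor(epsilon)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  d2 <- g$dr^2 + g$dc^2
  keep <- d2 > 0 & d2 <= epsilon^2 + 1e-12
  g <- g[keep, , drop = FALSE]
  g[order(d2[keep]), , drop = FALSE]
}

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
.shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

#' DBSCAN clustering of a binary activation mask
#'
#' @param mask Logical (or 0/1) matrix marking activation pixels.
#' @param p A [dbscan_params()] object.
#' @param tile_index Optional slice index stored on each cluster.
#' @return List of `activation_cluster` objects, each with `pixels` (two-column
#'   row/col matrix in mask coordinates), `size_px`, `centroid`,
#'   `tile_index`, and placeholder anatomy flags `overlaps_white_matter`,
#'   `reaches_ventricle` (filled by the spatial feature pass). Clusters are
#'   ordered by decreasing size. Empty mask gives an empty list.
#' @export
dbscan_clusters <- function(mask, p = dbscan_params(), tile_index = NA_integer_) {
  if (!is.matrix(mask)) stop("mask must be a 2-D matrix")
  m <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  m[is.na(m)] <- FALSE
  if (!any(m)) return(list())

  # crop to the bounding box (plus margin) to keep propagation cheap
  rr <- range(which(rowSums(m) > 0)); cc <- range(which(colSums(m) > 0))
  pad <- ceiling(p$epsilon)
  r0 <- max(1L, rr[1] - pad); r1 <- min(nrow(m), rr[2] + pad)
  c0 <- max(1L, cc[1] - pad); c1 <- min(ncol(m), cc[2] + pad)
  sub <- m[r0:r1, c0:c1, drop = FALSE]

  offs <- .epsilon_offsets(p$epsilon)
  subn <- sub * 1
  counts <- matrix(0, nrow(sub), ncol(sub))
  for (i in seq_len(nrow(offs)))
    counts <- counts + .shift_mat(subn, offs$dr[i], offs$dc[i])
  core <- sub & counts > p$v_min

  # merge core points within epsilon of each other: vectorized edge
  # construction over the offset set, connected components via igraph
  lab <- matrix(Inf, nrow(sub), ncol(sub))
  if (any(core)) {
    core_id <- matrix(0L, nrow(sub), ncol(sub))
    core_lin <- which(core)
    core_id[core_lin] <- seq_along(core_lin)
    edges <- list()
    for (i in seq_len(nrow(offs))) {
      sh <- .shift_mat(core_id, offs$dr[i], offs$dc[i], fill = 0L)
      both <- core_id > 0L & sh > 0L
      if (any(both)) edges[[length(edges) + 1L]] <- cbind(core_id[both], sh[both])
    }
    g <- igraph::graph_from_edgelist(
      if (length(edges)) do.call(rbind, edges) else matrix(0L, 0, 2),
      directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(core_lin) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
    lab[core_lin] <- comp[seq_along(core_lin)]
  }

  # border points: nearest core neighbor's label (offsets are distance-sorted)
  border_lab <- matrix(Inf, nrow(sub), ncol(sub))
  border <- sub & !core
  if (any(border) && any(core)) {
    core_lab <- lab; core_lab[!core] <- Inf
    for (i in seq_len(nrow(offs))) {
      sh <- .shift_mat(core_lab, offs$dr[i], offs$dc[i], fill = Inf)
      fill_now <- border & !is.finite(border_lab) & is.finite(sh)
      border_lab[fill_now] <- sh[fill_now]
    }
  }
  full <- lab
  take <- is.finite(border_lab) & !is.finite(full)
  full[take] <- border_lab[take]

  ids <- unique(full[is.finite(full)])
  out <- list()
  for (id in ids) {
    w <- which(full == id, arr.ind = TRUE)
    if (nrow(w) <= p$min_cluster_px) next
    px <- cbind(row = w[, 1] + r0 - 1L, col = w[, 2] + c0 - 1L)
    out[[length(out) + 1L]] <- structure(
      list(pixels = px, size_px = nrow(px),
           centroid = c(row = mean(px[, 1]), col = mean(px[, 2])),
           tile_index = tile_index,
           overlaps_white_matter = NA, reaches_ventricle = NA),
      class = "activation_cluster")
  }
  out[order(vapply(out, function(cl) cl$size_px, 0), decreasing = TRUE)]
}

#' @export
print.activation_cluster <- function(x, ...) {
  cat(sprintf("<activation_cluster> %d px @ (%.1f, %.1f), tile %s, wm=%s vent=%s\n",
              x$size_px, x$centroid[1], x$centroid[2],
              ifelse(is.na(x$tile_index), "?", x$tile_index),
              x$overlaps_white_matter, x$reaches_ventricle))
  invisible(x)
}
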