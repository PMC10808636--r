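#' Cluster-count / asymmetry expert feature
#'
#' Scores SOZ-likeness of the activation cluster configuration in [0, 1]:
#' with `c` the median per-slice count of retained clusters (over slices
#' with at least one) and `asym` the fraction of retained-cluster pixels on
#' the dominant side of the slice midline (in [0.5, 1]), the score is
#' `(2 * asym - 1) / c`. A single cluster fully in one hemisphere scores 1;
#' mirrored symmetric clusters score near 0; no clusters score 0. The
#' midline is the column of the brain-mask centroid of each slice (falling
#' back to the tile center), which makes the score invariant to montage
#' translation.
#'
#' @param slices List of `list(slice = brain_slice, clusters = list(...))`
#'   entries, one per slice (clusters from [dbscan_clusters()]).
#' @return Score in [0, 1].
#' @export
f_clusters <- function(slices) {
  counts <- integer(0)
  left <- 0; total <- 0
  for (sc in slices) {
    cl <- sc$clusters
    if (length(cl) == 0L) next
    counts <- c(counts, length(cl))
    mid <- if (any(sc$slice$brain_mask)) {
      mean(which(sc$slice$brain_mask, arr.ind = TRUE)[, 2])
    } else {
      (ncol(sc$slice$brain_mask) + 1) / 2
    }
    for (x in cl) {
      left <- left + sum(x$pixels[, 2] < mid)
      total <- total + x$size_px
    }
  }
  if (length(counts) == 0L || total == 0) return(0)
  asym <- max(left / total, 1 - left / total)
  (2 * asym - 1) / stats::median(counts)
}

#' White-matter-to-ventricle extension expert feature
#'
#' For every retained cluster, tests (a) overlap with the white-matter
#' contour (dilated by `wm_dilate` px, default 2, to absorb rasterization
#' gaps and the 1-px artifact margin around inpainted activation) and (b) reach
#' into the ventricle region; returns the fraction of retained clusters
#' satisfying both, 0 when there are none. The anatomy must come from
#' activation-free slices (two-pass protocol: inpaint first, then detect
#' contours, then intersect with the clusters of the original slice).
#' Cluster flags `overlaps_white_matter` / `reaches_ventricle` are filled
#' in on the returned cluster list.
#'
#' @param slices List of `list(anatomy = slice_anatomy, clusters = list())`
#'   entries per slice.
#' @param wm_dilate Dilation radius (px) applied to the white-matter
#'   contour before the overlap test.
#' @return List with `score` (fraction in [0, 1]) and `slices` (input with
#'   cluster flags filled).
#' @export
f_wm_ventricle <- function(slices, wm_dilate = 2L) {
  n_q <- 0L; n_tot <- 0L
  for (j in seq_along(slices)) {
    an <- slices[[j]]$anatomy
    cl <- slices[[j]]$clusters
    if (length(cl) == 0L) next
    dims <- dim(an$ventricle_region)
    wm_mask <- matrix(FALSE, dims[1], dims[2])
    if (nrow(an$white_matter_contour) > 0) {
      wm_mask[an$white_matter_contour] <- TRUE
      wm_mask <- .dilate_mask(wm_mask, wm_dilate)
    }
    for (k in seq_along(cl)) {
      px <- cl[[k]]$pixels
      px <- px[px[, 1] >= 1 & px[, 1] <= dims[1] &
               px[, 2] >= 1 & px[, 2] <= dims[2], , drop = FALSE]
      ow <- any(wm_mask[px])
      rv <- any(an$ventricle_region[px])
      cl[[k]]$overlaps_white_matter <- ow
      cl[[k]]$reaches_ventricle <- rv
      n_tot <- n_tot + 1L
      if (ow && rv) n_q <- n_q + 1L
    }
    slices[[j]]$clusters <- cl
  }
  list(score = if (n_tot == 0L) 0 else n_q / n_tot, slices = slices)
}

#' Full spatial + temporal expert-feature extraction for one IC
#'
#' Runs the complete per-IC feature pipeline: slice extraction by template
#' matching on the native montage, activation masking, DBSCAN clustering
#' per slice, activation-free anatomy detection, the two spatial features,
#' and the two temporal sparsity features from the BOLD time course.
#'
#' @param m Native [ic_montage()].
#' @param ts The IC's [bold_timecourse()].
#' @param template Slice template (default [slice_template()] for `config`).
#' @param config [synthetic_config()] supplying geometry defaults.
#' @param dbscan [dbscan_params()].
#' @return List with `features` ([expert_features()] of
#'   `c(f_clusters, f_wm_ventricle, activelet_gini, sine_gini)`),
#'   `clusters` (flat list of retained `activation_cluster`s, anatomy flags
#'   filled, slice-local coordinates plus `tile_index`),
#'   `per_slice_counts`, and `sparsity` (the [sparsity_summary()]).
#' @export
ic_expert_features <- function(m, ts, template = NULL,
                               config = synthetic_config(),
                               dbscan = dbscan_params()) {
  if (is.null(template)) template <- slice_template(config)
  slices <- extract_brain_slices(m, template)
  act_full <- activation_mask(m)  # one pass over the montage
  sc <- lapply(slices, function(s) {
    mask <- act_full[s$origin[1] + seq_len(nrow(s$brain_mask)),
                     s$origin[2] + seq_len(ncol(s$brain_mask)), drop = FALSE]
    cl <- dbscan_clusters(mask, dbscan, tile_index = s$tile_index)
    list(slice = s, clusters = cl)
  })
  f1 <- f_clusters(sc)
  # anatomy is only consulted where clusters exist (two-pass protocol)
  an <- lapply(sc, function(x) {
    if (length(x$clusters) == 0L)
      return(list(anatomy = NULL, clusters = x$clusters))
    clean <- remove_activation(x$slice)
    list(anatomy = detect_anatomy(clean), clusters = x$clusters)
  })
  fw <- f_wm_ventricle(an)
  sp <- sparsity_summary(ts)
  clusters <- do.call(c, lapply(fw$slices, function(x) x$clusters))
  structure(list(
    features = expert_features(
      c(f1, fw$score, sp$activelet_gini, sp$sine_gini), ic_id = m$ic_id),
    clusters = clusters,
    per_slice_counts = vapply(sc, function(x) length(x$clusters), 0L),
    sparsity = sp), class = "ic_expert_features")
}

#' @export
print.ic_expert_features <- function(x, ...) {
  v <- x$features$values
  cat(sprintf("<ic_expert_features> %s: f_clusters=%.3f f_wm_ventricle=%.3f activelet_gini=%.3f sine_gini=%.3f | %d retained cluster(s)\n",
              x$features$ic_id, v[1], v[2], v[3], v[4], length(x$clusters)))
  invisible(x)
}
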