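#' IC montage container
#'
#' One independent component's spatial map rendered as an RGB montage of
#' axial slice tiles.
#'
#' @param pixels H x W x 3 numeric array with intensities in 0-255.
#' @param ic_id,patient_id Identifiers.
#' @param label Ground-truth class ("NOISE", "RSN", "SOZ" or "unknown").
#' @param native TRUE for native resolution, FALSE after [resize_montage()].
#' @return Object of class `ic_montage`.
#' @export
ic_montage <- function(pixels, ic_id = NA_character_, patient_id = NA_character_,
                       label = "unknown", native = TRUE) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an H x W x 3 array")
  if (any(dim(pixels)[1:2] < 1L)) stop("empty image")
  label <- match.arg(label, c("NOISE", "RSN", "SOZ", "unknown"))
  structure(list(pixels = pixels, ic_id = ic_id, patient_id = patient_id,
                 label = label, native = native),
            class = "ic_montage")
}

#' @export
print.ic_montage <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<ic_montage> %s (%s) %dx%dx3 %s, label %s\n",
              x$ic_id, x$patient_id, d[1], d[2],
              if (x$native) "native" else "resized", x$label))
  invisible(x)
}

# EBImage convention: the first image dimension is `w`. Helpers keep all
# package code in (row, col) = (height, width) order.
.resize_mat <- function(m, new_h, new_w) {
  as.matrix(EBImage::resize(EBImage::Image(m), w = new_h, h = new_w))
}

#' Resize a native montage for the CNN arm
#'
#' Native 709 x 1006 x 3 montages are reduced to 270 x 470 x 3 (bilinear)
#' for the noise-screening CNN; the expert-knowledge arm keeps working on
#' the native image. Re-resizing an already-resized montage is refused to
#' avoid silent double interpolation.
#'
#' @param m A native [ic_montage()].
#' @param size Target c(height, width) (default c(270, 470)).
#' @return The resized [ic_montage()] (metadata preserved, `native` cleared).
#' @export
resize_montage <- function(m, size = c(270L, 470L)) {
  if (!inherits(m, "ic_montage")) stop("m must be an ic_montage")
  if (!m$native) stop("montage is already resized; refusing to resize again")
  px <- array(0, c(size[1], size[2], 3))
  for (ch in 1:3) px[, , ch] <- .resize_mat(m$pixels[, , ch], size[1], size[2])
  ic_montage(px, ic_id = m$ic_id, patient_id = m$patient_id,
             label = m$label, native = FALSE)
}

#' Packaged synthetic slice template for template matching
#'
#' A single-slice grayscale template (elliptical brain with gray-matter
#' ring and interior white-matter contour) used to locate slice tiles in a
#' montage by normalized cross-correlation. A user-supplied template (e.g.,
#' one rendered from a standard brain atlas) can be passed to
#' [extract_brain_slices()] instead.
#'
#' @param config A [synthetic_config()] fixing the tile geometry.
#' @return Grayscale matrix (tile_h x tile_w, 0-255 scale).
#' @export
slice_template <- function(config = synthetic_config()) {
  lay <- tile_layout(config)
  i <- which.max(lay$s)  # the largest (mid-stack) slice generalizes best
  255 * .tile_fields(lay$tile_h[i], lay$tile_w[i], lay$s[i], FALSE)$img
}

#' Extract per-slice sub-images from a montage via template matching
#'
#' Computes the zero-mean cross-correlation of the montage's grayscale
#' minimum-channel image (activation overlays are suppressed by taking the
#' per-pixel channel minimum) with the slice template via FFT filtering.
#' Because slice tiles repeat on a regular grid with the template's period,
#' the grid phase is voted globally from the correlation surface, and each
#' grid cell is then accepted if its local correlation exceeds
#' `match_threshold` relative to the best cell (rejecting blank cells).
#' Tiles are returned in base-to-apex order (row-major by origin).
#'
#' @param m A native [ic_montage()].
#' @param template Grayscale template matrix (0-255), e.g. [slice_template()].
#' @param match_threshold Relative correlation threshold in (0, 1]
#'   (default 0.1).
#' @return List of `brain_slice` objects: `pixels` (tile RGB array),
#'   `tile_index` (0-based), `origin` (0-based row/col), `brain_mask`,
#'   `is_base_slice`. Empty list (with a warning) if nothing matches.
#' @export
extract_brain_slices <- function(m, template, match_threshold = 0.1) {
  if (!inherits(m, "ic_montage")) stop("m must be an ic_montage")
  th <- nrow(template); tw <- ncol(template)
  if (th > dim(m$pixels)[1] || tw > dim(m$pixels)[2])
    stop("template larger than montage")
  gray <- pmin(m$pixels[, , 1], m$pixels[, , 2], m$pixels[, , 3]) / 255
  H <- nrow(gray); W <- ncol(gray)
  # Zero-mean cross-correlation via FFT (zero-padded to composite sizes;
  # the template spectrum is cached across calls). score[r, c] is the
  # correlation of the template placed with its top-left corner at (r, c).
  # L >= image size suffices: windows of valid (in-image) origins never
  # reach the circular wrap, so their scores equal the fully padded ones
  L1 <- .fft_size(max(H, th)); L2 <- .fft_size(max(W, tw))
  key <- sprintf("%d_%d_%d_%d_%.6f", th, tw, L1, L2, sum(template))
  Tc <- .tm_cache[[key]]
  if (is.null(Tc)) {
    tp <- matrix(0, L1, L2)
    tp[seq_len(th), seq_len(tw)] <- template / 255 - mean(template / 255)
    Tc <- Conj(stats::fft(tp))
    .tm_cache[[key]] <- Tc
  }
  gp <- matrix(0, L1, L2)
  gp[seq_len(H), seq_len(W)] <- gray
  cc <- Re(stats::fft(stats::fft(gp) * Tc, inverse = TRUE)) / (L1 * L2)
  score <- cc[seq_len(H - th + 1L), seq_len(W - tw + 1L), drop = FALSE]
  best <- max(score)
  if (best <= 0) {
    warning("no slice tile matched the template")
    return(list())
  }
  thr <- match_threshold * best
  # Slice tiles repeat on a regular grid with the template's period, so the
  # grid phase is voted globally: fold the correlation surface modulo the
  # tile size and take the maximizing phase. Individual tiles are then
  # accepted by their local correlation (rejecting blank grid cells).
  nbr <- H %/% th; nbc <- W %/% tw
  fold <- matrix(0, th, tw)
  for (i in seq_len(nbr) - 1L) for (j in seq_len(nbc) - 1L) {
    rs <- i * th + seq_len(th); cs <- j * tw + seq_len(tw)
    blk <- matrix(0, th, tw)
    rs_ok <- rs <= nrow(score); cs_ok <- cs <= ncol(score)
    blk[rs_ok, cs_ok] <- score[rs[rs_ok], cs[cs_ok]]
    fold <- fold + blk
  }
  ph <- which(fold == max(fold), arr.ind = TRUE)[1, ]
  origins <- NULL
  for (i in seq_len(nbr) - 1L) for (j in seq_len(nbc) - 1L) {
    r <- i * th + ph[1]; c <- j * tw + ph[2]   # 1-based origin + 1
    if (r > nrow(score) || c > ncol(score)) next
    if (score[r, c] < thr) next
    origins <- rbind(origins, c(r - 1L, c - 1L))  # 0-based origins
  }
  if (is.null(origins)) {
    warning("no slice tile matched the template")
    return(list())
  }
  origins <- origins[order(origins[, 1], origins[, 2]), , drop = FALSE]
  n_base <- nrow(origins) %/% 3L
  lapply(seq_len(nrow(origins)), function(i) {
    r0 <- origins[i, 1]; c0 <- origins[i, 2]
    px <- m$pixels[r0 + seq_len(th), c0 + seq_len(tw), , drop = FALSE]
    structure(list(pixels = px, tile_index = i - 1L,
                   origin = c(row = r0, col = c0),
                   brain_mask = gray[r0 + seq_len(th), c0 + seq_len(tw)] > 0.15,
                   is_base_slice = (i - 1L) < n_base),
              class = "brain_slice")
  })
}

#' @export
print.brain_slice <- function(x, ...) {
  cat(sprintf("<brain_slice> tile %d @ (%d, %d), %dx%d, %s, %d brain px\n",
              x$tile_index, x$origin[1], x$origin[2],
              nrow(x$brain_mask), ncol(x$brain_mask),
              if (x$is_base_slice) "base" else "apex-ward", sum(x$brain_mask)))
  invisible(x)
}

# Color-dominance rule identifying warm activation-overlay pixels on the
# grayscale anatomy (0-255 scale): strong red, red clearly above green,
# green at or above blue.
.activation_rule <- function(r, g, b) {
  r >= 166 & (r - g) >= 30 & g >= b
}

#' Binary activation mask of a slice (or montage)
#'
#' Applies the documented color-dominance rule (R >= 166, R - G >= 30,
#' G >= B on the 0-255 scale) marking the warm-colormap activation overlay.
#' Idempotent: re-applying to a masked render changes nothing.
#'
#' @param s A `brain_slice` (or [ic_montage()]).
#' @return Logical matrix.
#' @export
activation_mask <- function(s) {
  px <- if (inherits(s, "ic_montage")) s$pixels else s$pixels
  .activation_rule(px[, , 1], px[, , 2], px[, , 3])
}

#' Remove the activation overlay from a slice
#'
#' Produces a version of the slice devoid of activation clusters, the basis
#' for anatomy contour identification: activation pixels are replaced by
#' iterative inpainting from the surrounding anatomy (onion-peel averaging
#' of known neighbors), and the result is collapsed to grayscale. A slice
#' with no activation pixels passes through unchanged (grayscaled); a fully
#' saturated slice is filled with the mid-parenchyma intensity.
#'
#' @param s A `brain_slice`.
#' @return The activation-free `brain_slice` (grayscale replicated to RGB).
#' @export
remove_activation <- function(s) {
  mask <- activation_mask(s)
  g <- pmin(s$pixels[, , 1], s$pixels[, , 2], s$pixels[, , 3])
  if (any(mask)) {
    known <- !mask
    if (!any(known)) {
      g[] <- 0.45 * 255
    } else {
      val <- g * known
      for (iter in seq_len(128L)) {
        if (all(known)) break
        ssum <- .box3_sum(val)
        scount <- .box3_sum(known * 1)
        newly <- !known & scount > 0.5
        if (!any(newly)) break
        val[newly] <- ssum[newly] / scount[newly]
        known <- known | newly
      }
      if (!all(known)) val[!known] <- 0.45 * 255
      g <- val
    }
  }
  out <- s
  px <- array(0, dim(s$pixels))
  px[, , 1] <- g; px[, , 2] <- g; px[, , 3] <- g
  out$pixels <- px
  out$brain_mask <- g / 255 > 0.15  # re-derive anatomy mask from the inpaint
  out$inpainted <- mask             # gradients here are fill artifacts
  out
}

#' Detect slice anatomy: contours, white matter, ventricles
#'
#' Applies Sobel edge detection to the activation-free slice, thresholds
#' the gradient magnitude and labels connected edge components as contours.
#' Components adjacent to non-brain area (outside background or interior
#' holes) are brain-boundary contours; the most prominent remaining
#' interior component (longest, ties by enclosed area) is the white-matter
#' contour. On base slices the ventricle region is recovered inside the
#' convex hull of the boundary contours as the interior area that
#' interrupts the brain image (holes), excluding pixels adjacent to any
#' boundary contour; on apex-ward slices it is empty.
#'
#' @param s An activation-free `brain_slice` (see [remove_activation()]).
#' @param sobel_threshold Gradient-magnitude threshold on the 0-1 intensity
#'   scale (default 0.5).
#' @return Object of class `slice_anatomy`: `boundary_contours` (list of
#'   pixel coordinate matrices), `white_matter_contour` (matrix, possibly
#'   empty), `ventricle_region` (logical matrix).
#' @export
detect_anatomy <- function(s, sobel_threshold = 0.5) {
  g <- s$pixels[, , 1] / 255
  # separable Sobel via shifts (zero-fill borders sit on dark background)
  smc <- .shift_mat(g, 0, -1) + 2 * g + .shift_mat(g, 0, 1)
  smr <- .shift_mat(g, -1, 0) + 2 * g + .shift_mat(g, 1, 0)
  gx <- .shift_mat(smc, -1, 0) - .shift_mat(smc, 1, 0)
  gy <- .shift_mat(smr, 0, -1) - .shift_mat(smr, 0, 1)
  mag <- sqrt(gx^2 + gy^2)
  # gradients inside an inpainted corridor are fill artifacts, not anatomy
  if (!is.null(s$inpainted) && any(s$inpainted))
    mag[.dilate_mask(s$inpainted, 1L)] <- 0
  edges <- mag > sobel_threshold
  if (!any(edges))
    return(structure(list(boundary_contours = list(),
                          white_matter_contour = matrix(0, 0, 2),
                          ventricle_region = matrix(FALSE, nrow(g), ncol(g))),
                     class = "slice_anatomy"))
  lab <- EBImage::bwlabel(EBImage::Image(edges * 1))
  lab <- matrix(as.integer(lab), nrow(g), ncol(g))

  brain <- s$brain_mask
  filled <- matrix(as.logical(EBImage::fillHull(EBImage::Image(brain * 1)) > 0.5),
                   nrow(g), ncol(g))
  holes <- filled & !brain
  outside <- !filled
  nonbrain <- outside | holes
  # adjacency = within 1 px (8-neighborhood dilation of the non-brain area)
  near_nonbrain <- .dilate_mask(nonbrain, 1L)

  ids <- sort(unique(lab[lab > 0]))
  comp_px <- lapply(ids, function(id) which(lab == id, arr.ind = TRUE))
  is_boundary <- vapply(seq_along(ids), function(k) {
    any(near_nonbrain[comp_px[[k]]])
  }, TRUE)

  boundary_contours <- comp_px[is_boundary]
  interior <- comp_px[!is_boundary]
  wm <- matrix(0L, 0, 2)
  if (length(interior) > 0) {
    len <- vapply(interior, nrow, 0L)
    area <- vapply(interior, function(px) {
      (max(px[, 1]) - min(px[, 1]) + 1) * (max(px[, 2]) - min(px[, 2]) + 1)
    }, 0)
    wm <- interior[[order(-len, -area)[1]]]
  }

  vent <- matrix(FALSE, nrow(g), ncol(g))
  if (isTRUE(s$is_base_slice) && length(boundary_contours) > 0 && any(holes)) {
    bpx <- do.call(rbind, boundary_contours)
    bmask <- matrix(FALSE, nrow(g), ncol(g))
    bmask[bpx] <- TRUE
    # the filled silhouette is a closed stand-in for the contour hull (an
    # activation corridor can leave the traced boundary contour open)
    vent <- holes & filled & !.dilate_mask(bmask, 1L)
  }
  structure(list(boundary_contours = boundary_contours,
                 white_matter_contour = wm,
                 ventricle_region = vent),
            class = "slice_anatomy")
}

#' @export
print.slice_anatomy <- function(x, ...) {
  cat(sprintf("<slice_anatomy> %d boundary contour(s), white-matter contour %d px, ventricle region %d px\n",
              length(x$boundary_contours), nrow(x$white_matter_contour),
              sum(x$ventricle_region)))
  invisible(x)
}

# Smallest 5-smooth integer >= n (keeps base-R FFTs fast).
.fft_size <- function(n) {
  k <- n
  repeat {
    m <- k
    for (p in c(2, 3, 5)) while (m %% p == 0) m <- m / p
    if (m == 1) return(k)
    k <- k + 1
  }
}

.tm_cache <- new.env(parent = emptyenv())

# Sum over the 3x3 neighborhood (separable, zero boundary).
.box3_sum <- function(m) {
  rp <- m + .shift_mat(m, 1, 0) + .shift_mat(m, -1, 0)
  rp + .shift_mat(rp, 0, 1) + .shift_mat(rp, 0, -1)
}

# Binary dilation by `r` pixels (square structuring element).
.dilate_mask <- function(mask, r = 1L) {
  if (!any(mask)) return(mask)
  out <- EBImage::dilate(EBImage::Image(mask * 1),
                         EBImage::makeBrush(2L * r + 1L, "box")) > 0.5
  matrix(as.logical(out), nrow(mask), ncol(mask))
}
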