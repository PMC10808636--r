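#' Fuse the CNN and expert-knowledge labels into a final 3-class call
#'
#' Decision table: if the CNN arm sees a non-noise montage ("NOISE-bar"),
#' the expert-knowledge label is retained (SOZ or RSN). If the CNN says
#' NOISE, the IC stays NOISE unless the expert arm calls SOZ with
#' confidence strictly above `threshold` (default 0.9), in which case the
#' expert call overrides the noise screen.
#'
#' @param dl_label "NOISE" or "NOISE-bar" from the CNN arm.
#' @param eki_label "RSN" or "SOZ" from the expert-knowledge arm.
#' @param rho Confidence score from the expert-knowledge arm.
#' @param threshold Override threshold (strict inequality; default 0.9).
#' @return Final label: "NOISE", "RSN" or "SOZ".
#' @export
fuse <- function(dl_label, eki_label, rho, threshold = 0.9) {
  dl_label <- match.arg(dl_label, c("NOISE", "NOISE-bar"))
  eki_label <- match.arg(eki_label, c("RSN", "SOZ"))
  if (!is.finite(rho)) stop("rho must be finite")
  if (dl_label == "NOISE-bar") return(eki_label)
  if (eki_label == "SOZ" && rho > threshold) return("SOZ")
  "NOISE"
}

#' Localize the SOZ of each SOZ-labeled IC as its largest cluster
#'
#' For every IC finally labeled SOZ, the localized SOZ is the activation
#' cluster of maximal pixel count across all of its slices (argmax over
#' retained DBSCAN clusters). Ties go to the lowest tile index, then the
#' lowest centroid row. ICs without any retained cluster are reported as
#' unlocalizable rather than dropped.
#'
#' @param soz_ics Named list: per SOZ IC, a list of `activation_cluster`
#'   objects (possibly empty) pooled across its slices.
#' @return List of `soz_localization` objects with `ic_id`, `clusters`,
#'   `largest` (or NULL), `tile_index`, `centroid`, `unlocalizable`,
#'   `reason`.
#' @export
localize_soz <- function(soz_ics) {
  out <- vector("list", length(soz_ics))
  ids <- names(soz_ics)
  if (is.null(ids)) ids <- as.character(seq_along(soz_ics))
  for (i in seq_along(soz_ics)) {
    cl <- soz_ics[[i]]
    if (length(cl) == 0L) {
      out[[i]] <- structure(
        list(ic_id = ids[i], clusters = list(), largest = NULL,
             tile_index = NA_integer_, centroid = c(NA_real_, NA_real_),
             unlocalizable = TRUE,
             reason = "no activation cluster above the retention threshold"),
        class = "soz_localization")
      next
    }
    sizes <- vapply(cl, function(x) x$size_px, 0)
    tiles <- vapply(cl, function(x) as.numeric(x$tile_index), 0)
    rows <- vapply(cl, function(x) x$centroid[["row"]], 0)
    ord <- order(-sizes, tiles, rows)
    best <- cl[[ord[1]]]
    out[[i]] <- structure(
      list(ic_id = ids[i], clusters = cl, largest = best,
           tile_index = best$tile_index, centroid = best$centroid,
           unlocalizable = FALSE, reason = NA_character_),
      class = "soz_localization")
  }
  out
}

#' @export
print.soz_localization <- function(x, ...) {
  if (x$unlocalizable) {
    cat(sprintf("<soz_localization> IC %s: UNLOCALIZABLE (%s)\n", x$ic_id, x$reason))
  } else {
    cat(sprintf("<soz_localization> IC %s: largest cluster %d px, tile %d, centroid (%.1f, %.1f); %d cluster(s)\n",
                x$ic_id, x$largest$size_px, x$tile_index,
                x$centroid[1], x$centroid[2], length(x$clusters)))
  }
  invisible(x)
}
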