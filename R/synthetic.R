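#' Configuration for the synthetic IC cohort generator
#'
#' Defines the study conditions emulated by the generator: per-patient IC
#' counts, the NOISE/RSN/SOZ class mix, montage geometry and BOLD sampling.
#' The defaults mirror a pediatric rs-fMRI pre-surgical screening cohort:
#' ~51% noise ICs, 43% resting-state networks and ~6% seizure-onset-zone
#' ICs; 46 axial slice tiles rendered into a 709 x 1006 RGB montage; 600
#' BOLD samples at TR 2 s.
#'
#' @param seed Integer seed; the cohort is a pure function of (config, seed).
#' @param n_patients Number of synthetic patients.
#' @param ics_per_patient ICs per patient.
#' @param class_proportions Numeric 3-vector (NOISE, RSN, SOZ), summing to 1.
#' @param montage_grid c(rows, cols) of slice tiles; rows*cols >= n_slices.
#' @param native_size c(height, width) of the native montage in pixels.
#' @param n_slices Number of slice tiles (default 46), ordered base to apex.
#' @param n_timepoints BOLD samples per IC (default 600).
#' @param tr_seconds Repetition time (default 2).
#' @param separation Value in the unit interval: 1 renders textbook class geometry/spectra,
#'   lower values mix in ambiguous, rule-violating ICs.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_patients = 10L, ics_per_patient = 100L,
                             class_proportions = c(NOISE = 0.51, RSN = 0.43, SOZ = 0.06),
                             montage_grid = c(5L, 10L),
                             native_size = c(709L, 1006L),
                             n_slices = 46L,
                             n_timepoints = 600L, tr_seconds = 2,
                             separation = 1) {
  p <- as.numeric(class_proportions)
  if (length(p) != 3L || abs(sum(p) - 1) > 1e-9)
    stop("class_proportions must be a 3-vector summing to 1")
  if (n_patients > 0 && p[3] <= 0)
    stop("the SOZ fraction must be positive")
  if (separation < 0 || separation > 1) stop("separation must be in [0, 1]")
  if (prod(montage_grid) < n_slices)
    stop("montage_grid too small for n_slices tiles")
  cfg <- structure(list(
    seed = as.integer(seed), n_patients = as.integer(n_patients),
    ics_per_patient = as.integer(ics_per_patient),
    class_proportions = stats::setNames(p, c("NOISE", "RSN", "SOZ")),
    montage_grid = as.integer(montage_grid),
    native_size = as.integer(native_size), n_slices = as.integer(n_slices),
    n_timepoints = as.integer(n_timepoints), tr_seconds = tr_seconds,
    separation = separation), class = "synthetic_config")
  cc <- .class_counts(cfg)
  if (any(cc < 1))
    stop(sprintf("ics_per_patient = %d cannot honor the class proportions (per-patient counts %s); every class needs >= 1 IC",
                 cfg$ics_per_patient, paste(cc, collapse = "/")))
  cfg
}

# Deterministic per-patient class counts honoring the proportions
# (SOZ rounded but floored at 1 so patient-level sensitivity is defined).
.class_counts <- function(config) {
  n <- config$ics_per_patient
  p <- config$class_proportions
  n_soz <- max(1L, round(n * p[["SOZ"]]))
  n_rsn <- round(n * p[["RSN"]])
  n_noise <- n - n_rsn - n_soz
  c(NOISE = n_noise, RSN = n_rsn, SOZ = n_soz)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("<synthetic_config> seed %d | %d patients x %d ICs | mix %.0f/%.0f/%.0f%% | %d tiles in %dx%d grid | %d vols @ TR %.3gs | separation %.2f\n",
              x$seed, x$n_patients, x$ics_per_patient,
              100 * x$class_proportions[1], 100 * x$class_proportions[2],
              100 * x$class_proportions[3], x$n_slices, x$montage_grid[1],
              x$montage_grid[2], x$n_timepoints, x$tr_seconds, x$separation))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Tile geometry and pseudo-anatomy

#' Tile layout of a synthetic montage
#'
#' @param config A [synthetic_config()].
#' @return Data frame with one row per slice tile: `tile_index` (0-based,
#'   base to apex), 0-based `row0`/`col0` origins, `tile_h`, `tile_w`,
#'   size factor `s` and `is_base` (first third of the tile order).
#' @export
tile_layout <- function(config) {
  rows <- config$montage_grid[1]; cols <- config$montage_grid[2]
  th <- config$native_size[1] %/% rows
  tw <- config$native_size[2] %/% cols
  i <- seq_len(config$n_slices) - 1L
  data.frame(
    tile_index = i,
    row0 = (i %/% cols) * th,
    col0 = (i %% cols) * tw,
    tile_h = th, tile_w = tw,
    s = 0.65 + 0.35 * sin(pi * (i + 0.5) / config$n_slices),
    is_base = i < config$n_slices %/% 3L)
}

# Pseudo-anatomy of one tile: elliptical brain with a bright gray-matter
# ring, a prominent interior white-matter contour band, and (on base
# slices) two dark ventricle holes. Cached per (geometry) key since the
# anatomy is deterministic.
.anatomy_cache <- new.env(parent = emptyenv())

.tile_fields <- function(tile_h, tile_w, s, is_base) {
  key <- sprintf("%d_%d_%.6f_%d", tile_h, tile_w, s, is_base)
  hit <- .anatomy_cache[[key]]
  if (!is.null(hit)) return(hit)
  ch <- (tile_h + 1) / 2; cw <- (tile_w + 1) / 2
  a <- 0.44 * tile_h * s; b <- 0.42 * tile_w * s
  rr <- (seq_len(tile_h) - ch) / a
  cc <- (seq_len(tile_w) - cw) / b
  e <- sqrt(outer(rr^2, cc^2, `+`))
  theta <- atan2(outer(seq_len(tile_h) - ch, rep(1, tile_w)),
                 outer(rep(1, tile_h), seq_len(tile_w) - cw))
  # Intensity profile: dark background, flat mid-parenchyma, a smooth
  # interior falloff into the bright gray-matter ring (no sharp inner ring
  # edge, so the white-matter band stays the most prominent interior
  # contour under edge detection), sharp outer boundary.
  img <- matrix(0.02, tile_h, tile_w)
  brain <- e <= 1
  img[brain] <- 0.45
  grad <- e > 0.58 & e < 0.78
  img[grad] <- 0.45 + 0.47 * (e[grad] - 0.58) / 0.20
  ring <- e >= 0.78 & e <= 1
  img[ring] <- 0.92
  wm <- abs(e - 0.55) <= 0.045
  img[wm] <- 0.90
  holes <- matrix(FALSE, tile_h, tile_w)
  hole_centers <- NULL
  if (is_base) {
    for (sgn in c(-1, 1)) {
      hc <- cw + sgn * 0.055 * tile_w
      hr <- ch * 0.98
      ha <- 0.120 * tile_h * s; hb <- 0.062 * tile_w * s
      he <- sqrt(outer(((seq_len(tile_h) - hr) / ha)^2,
                       ((seq_len(tile_w) - hc) / hb)^2, `+`))
      holes <- holes | he <= 1
      hole_centers <- rbind(hole_centers, c(hr, hc))
    }
    img[holes] <- 0.03
  }
  out <- list(e = e, theta = theta, img = img, brain = brain, ring = ring,
              wm = wm, holes = holes, hole_centers = hole_centers,
              ch = ch, cw = cw, a = a, b = b)
  .anatomy_cache[[key]] <- out
  out
}

# Distance from every tile pixel to the segment p0 -> p1 (vectorized).
.capsule_mask <- function(tile_h, tile_w, p0, p1, half_width) {
  RR <- outer(seq_len(tile_h), rep(1, tile_w))
  CC <- outer(rep(1, tile_h), seq_len(tile_w))
  vr <- p1[1] - p0[1]; vc <- p1[2] - p0[2]
  len2 <- max(vr^2 + vc^2, 1e-9)
  t <- pmin(pmax(((RR - p0[1]) * vr + (CC - p0[2]) * vc) / len2, 0), 1)
  dr <- RR - (p0[1] + t * vr); dc <- CC - (p0[2] + t * vc)
  dr^2 + dc^2 <= half_width^2
}

.disc_mask <- function(tile_h, tile_w, center, radius) {
  RR <- outer(seq_len(tile_h), rep(1, tile_w))
  CC <- outer(rep(1, tile_h), seq_len(tile_w))
  (RR - center[1])^2 + (CC - center[2])^2 <= radius^2
}

# ---------------------------------------------------------------------------
# Montage generation

# Class geometry rules (native resolution, separation = 1):
#  SOZ   one thick activation capsule per involved base slice, confined to
#        one hemisphere, running from the gray-matter ring across the
#        white-matter contour into a ventricle hole.
#  RSN   >= 2 disc clusters mirrored across the slice midline at
#        mid-parenchyma radius; never reaching the ventricles.
#  NOISE rim arcs on/outside the brain boundary, scattered background
#        speckles, small white-matter speckles (below the cluster
#        retention threshold).

#' Generate one synthetic IC montage
#'
#' Renders a native-size RGB montage (grayscale pseudo-anatomy with a
#' warm-color activation overlay) following the class geometry rules.
#' Activation pixels are recoverable by the documented color-dominance rule
#' (see [activation_mask()]); the true overlay mask and tile layout are
#' attached as attributes for oracle checks.
#'
#' @param label "NOISE", "RSN" or "SOZ".
#' @param seed Integer seed; same (label, seed, config) gives an identical
#'   montage.
#' @param config A [synthetic_config()].
#' @param ic_id,patient_id Optional identifiers stored on the montage.
#' @return An [ic_montage()] with attributes `activation_mask` (logical
#'   H x W) and `layout` (the [tile_layout()] data frame).
#' @export
generate_montage <- function(label, seed, config = synthetic_config(),
                             ic_id = NA_character_, patient_id = NA_character_) {
  label <- match.arg(label, c("NOISE", "RSN", "SOZ"))
  rng <- .seeded_rng(seed)
  lay <- tile_layout(config)
  H <- config$native_size[1]; W <- config$native_size[2]
  gray <- matrix(0.02, H, W)
  act <- matrix(FALSE, H, W)

  fields <- lapply(seq_len(nrow(lay)), function(i)
    .tile_fields(lay$tile_h[i], lay$tile_w[i], lay$s[i], lay$is_base[i]))
  for (i in seq_len(nrow(lay))) {
    r <- lay$row0[i] + seq_len(lay$tile_h[i])
    c <- lay$col0[i] + seq_len(lay$tile_w[i])
    gray[r, c] <- fields[[i]]$img
  }

  ambiguous <- config$separation < 1 && rng$unif(1) > config$separation
  put <- function(tile_i, mask) {
    r <- lay$row0[tile_i] + seq_len(lay$tile_h[tile_i])
    c <- lay$col0[tile_i] + seq_len(lay$tile_w[tile_i])
    act[r, c] <<- act[r, c] | mask
  }

  base_idx <- which(lay$is_base)
  if (label == "SOZ") {
    hemi <- if (rng$unif(1) < 0.5) -1 else 1
    start <- base_idx[1] + floor(rng$unif(1, max = 4))
    run <- start:min(start + 5 + floor(rng$unif(1, max = 3)), max(base_idx))
    for (i in run) {
      f <- fields[[i]]
      hole_c <- f$hole_centers[if (hemi < 0) 1L else 2L, ]
      ring_pt <- c(f$ch + rng$norm(1, sd = 2),
                   f$cw + hemi * f$b * (0.97 + 0.05 * rng$unif(1)))
      mask <- .capsule_mask(lay$tile_h[i], lay$tile_w[i], ring_pt, hole_c,
                            half_width = 5.5 + rng$unif(1))
      if (ambiguous) {
        if (rng$unif(1) < 0.5) {
          # truncated: stops at the white-matter contour, no ventricle reach
          mask <- mask & f$e > 0.5
        } else {
          # contralateral mirror cluster appears (RSN-like symmetry)
          put(i, mask[, rev(seq_len(ncol(mask)))])
        }
      }
      put(i, mask)
    }
  } else if (label == "RSN") {
    n_pairs <- 2L + (rng$unif(1) < 0.4)
    start <- base_idx[length(base_idx)] - 2L + floor(rng$unif(1, max = 4))
    run <- start:min(start + 8L, nrow(lay))
    ang <- pi / 8 + rng$unif(n_pairs) * pi * 0.45
    rad <- 8.5 + 2 * rng$unif(n_pairs)
    drop_side <- if (ambiguous) floor(rng$unif(1, max = n_pairs)) + 1L else 0L
    for (i in run) {
      f <- fields[[i]]
      keep <- f$e >= 0.45 & f$e <= 1.02 & !f$holes  # never reach ventricles
      for (k in seq_len(n_pairs)) {
        rr0 <- f$ch - 0.70 * f$a * cos(ang[k])
        dc <- 0.70 * f$b * sin(ang[k])
        put(i, .disc_mask(lay$tile_h[i], lay$tile_w[i], c(rr0, f$cw + dc), rad[k]) & keep)
        if (k != drop_side)
          put(i, .disc_mask(lay$tile_h[i], lay$tile_w[i], c(rr0, f$cw - dc), rad[k]) & keep)
      }
    }
  } else { # NOISE
    n_arc_tiles <- 10L + floor(rng$unif(1, max = 8))
    tiles <- sort(unique(1L + floor(rng$unif(n_arc_tiles, max = nrow(lay)))))
    for (i in tiles) {
      f <- fields[[i]]
      th0 <- -pi + 2 * pi * rng$unif(1)
      halfw <- (25 + 30 * rng$unif(1)) * pi / 180
      d <- abs(((f$theta - th0 + pi) %% (2 * pi)) - pi)
      put(i, f$e >= 1.0 & f$e <= 1.13 & d <= halfw)
      if (rng$unif(1) < 0.5) {
        # sub-threshold white-matter speckle
        wm_px <- which(f$wm, arr.ind = TRUE)
        p <- wm_px[1L + floor(rng$unif(1, max = nrow(wm_px))), ]
        put(i, .disc_mask(lay$tile_h[i], lay$tile_w[i], p, 2.5 + 1.5 * rng$unif(1)))
      }
    }
    # scattered background speckles across the whole montage
    n_spk <- 25L + floor(rng$unif(1, max = 15))
    pr <- 1L + floor(rng$unif(n_spk, max = H - 3))
    pc <- 1L + floor(rng$unif(n_spk, max = W - 3))
    for (k in seq_len(n_spk)) {
      rs <- pr[k]:(pr[k] + 2L); cs <- pc[k]:(pc[k] + 2L)
      if (all(gray[rs, cs] <= 0.05)) act[rs, cs] <- TRUE
    }
    if (ambiguous) {
      # a large interior blob that mimics genuine signal
      i <- base_idx[2L + floor(rng$unif(1, max = 6))]
      f <- fields[[i]]
      put(i, .disc_mask(lay$tile_h[i], lay$tile_w[i],
                        c(f$ch - 0.4 * f$a, f$cw + 0.4 * f$b), 8))
    }
  }

  px <- array(0, c(H, W, 3))
  px[, , 1] <- gray; px[, , 2] <- gray; px[, , 3] <- gray
  g_col <- 0.25 + 0.3 * rng$unif(1)
  r_ch <- px[, , 1]; g_ch <- px[, , 2]; b_ch <- px[, , 3]
  r_ch[act] <- 0.95; g_ch[act] <- g_col; b_ch[act] <- 0.05
  px[, , 1] <- r_ch; px[, , 2] <- g_ch; px[, , 3] <- b_ch

  m <- ic_montage(px * 255, ic_id = ic_id, patient_id = patient_id,
                  label = label, native = TRUE)
  attr(m, "activation_mask") <- act
  attr(m, "layout") <- lay
  m
}

#' Generate one synthetic BOLD time course
#'
#' Class-conditional spectra in the 0.01-0.1 Hz band: SOZ series are sparse
#' (2-4 dominant sinusoids), RSN series dense (many in-band components),
#' NOISE series broadband with drift and spikes. A small noise floor keeps
#' the series non-constant. At separation < 1 a fraction of series is
#' blended with a draw from another class.
#'
#' @inheritParams generate_montage
#' @return A [bold_timecourse()].
#' @export
generate_timecourse <- function(label, seed, config = synthetic_config(),
                                ic_id = NA_character_) {
  label <- match.arg(label, c("NOISE", "RSN", "SOZ"))
  rng <- .seeded_rng(seed)
  n <- config$n_timepoints; tr <- config$tr_seconds
  t <- seq_len(n) * tr
  draw <- function(lab) {
    if (lab == "SOZ") {
      m <- 2L + floor(rng$unif(1, max = 3))            # 2-4 components
      fr <- 0.015 + rng$unif(m) * 0.08
      amp <- c(1, 0.55, 0.35, 0.25)[seq_len(m)]
      ph <- 2 * pi * rng$unif(m)
      rowSums(vapply(seq_len(m), function(k) amp[k] * sin(2 * pi * fr[k] * t + ph[k]),
                     numeric(n))) + rng$norm(n, sd = 0.08)
    } else if (lab == "RSN") {
      m <- 22L + floor(rng$unif(1, max = 8))           # dense in-band mixture
      fr <- 0.012 + rng$unif(m) * 0.085
      amp <- abs(rng$norm(m, sd = 0.35)) + 0.15
      ph <- 2 * pi * rng$unif(m)
      rowSums(vapply(seq_len(m), function(k) amp[k] * sin(2 * pi * fr[k] * t + ph[k]),
                     numeric(n))) + rng$norm(n, sd = 0.08)
    } else {
      x <- rng$norm(n, sd = 1)
      x <- x + seq(-1, 1, length.out = n) * (2 * rng$unif(1) - 1) * 1.5
      n_spk <- 4L + floor(rng$unif(1, max = 6))
      at <- 1L + floor(rng$unif(n_spk, max = n))
      x[at] <- x[at] + (2 * (rng$unif(n_spk) > 0.5) - 1) * (3 + 3 * rng$unif(n_spk))
      x
    }
  }
  x <- draw(label)
  if (config$separation < 1 && rng$unif(1) > config$separation) {
    other <- rng$pick(setdiff(c("NOISE", "RSN", "SOZ"), label), 1)
    x <- 0.55 * x + 0.45 * draw(other)
  }
  bold_timecourse(x, tr_seconds = tr, ic_id = ic_id)
}

#' Generate a labeled synthetic cohort
#'
#' Produces `n_patients` patients, each with `ics_per_patient` ICs whose
#' class counts follow the configured proportions (every patient keeps at
#' least one SOZ IC so patient-level sensitivity is defined). Time courses
#' are materialized; montages are stored as per-IC seeds and re-rendered on
#' demand by [cohort_montage()] so that cohorts of native-resolution
#' montages stay memory-bounded. The whole cohort is a pure function of
#' (config, seed).
#'
#' @param config A [synthetic_config()].
#' @return Object of class `synthetic_cohort` with `config`, `ics` (data
#'   frame: patient_id, ic_id, label, age_group, sex, montage_seed,
#'   tc_seed) and `timecourses` (named list of [bold_timecourse()]).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  rng <- .seeded_rng(config$seed)
  counts <- .class_counts(config)
  rows <- list()
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", p)
    # demographics tags mirroring the study's marginals (20/18/14 age split,
    # 55.8% female); plumbing for subgroup reports, no biological meaning
    age_group <- c("0-<5", "5-<13", "13-18")[1L + findInterval(rng$unif(1), cumsum(c(20, 18) / 52))]
    sex <- if (rng$unif(1) < 0.558) "F" else "M"
    labels <- rep(c("NOISE", "RSN", "SOZ"), times = counts)
    labels <- labels[order(rng$unif(length(labels)))]
    for (k in seq_along(labels)) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, ic_id = sprintf("%s_IC%03d", pid, k),
        label = labels[k], age_group = age_group, sex = sex,
        montage_seed = floor(rng$unif(1, max = 2^30)),
        tc_seed = floor(rng$unif(1, max = 2^30)))
    }
  }
  ics <- do.call(rbind, rows)
  tcs <- lapply(seq_len(nrow(ics)), function(i)
    generate_timecourse(ics$label[i], ics$tc_seed[i], config, ic_id = ics$ic_id[i]))
  names(tcs) <- ics$ic_id
  structure(list(config = config, ics = ics, timecourses = tcs),
            class = "synthetic_cohort")
}

#' Re-render the montage of one cohort IC
#'
#' @param cohort A [generate_cohort()] result.
#' @param ic_id IC identifier (row of `cohort$ics`).
#' @return The IC's [ic_montage()] (deterministic re-render).
#' @export
cohort_montage <- function(cohort, ic_id) {
  i <- match(ic_id, cohort$ics$ic_id)
  if (is.na(i)) stop("unknown ic_id: ", ic_id)
  generate_montage(cohort$ics$label[i], cohort$ics$montage_seed[i],
                   cohort$config, ic_id = cohort$ics$ic_id[i],
                   patient_id = cohort$ics$patient_id[i])
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(x$ics$label)
  cat(sprintf("<synthetic_cohort> %d patients, %d ICs (%s)\n",
              length(unique(x$ics$patient_id)), nrow(x$ics),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Write a cohort to disk (PNG montages, CSV manifest/time courses, JSON config)
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param montages Whether to render and write every montage PNG (slow for
#'   large cohorts; default TRUE).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, montages = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$ics[, c("patient_id", "ic_id", "label", "age_group", "sex")]
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  tc <- do.call(cbind, lapply(cohort$timecourses, function(x) x$samples))
  colnames(tc) <- names(cohort$timecourses)
  utils::write.csv(tc, file.path(dir, "timecourses.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$config[setdiff(names(cohort$config), "")],
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  if (montages) {
    dir.create(file.path(dir, "montages"), showWarnings = FALSE)
    for (id in cohort$ics$ic_id) {
      m <- cohort_montage(cohort, id)
      png::writePNG(m$pixels / 255, file.path(dir, "montages", paste0(id, ".png")))
    }
  }
  invisible(dir)
}
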