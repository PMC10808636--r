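#' Harmonic mean of precision and sensitivity (F1)
#'
#' @param precision,sensitivity Numeric (same scale, fraction or percent).
#' @return F1 on the same scale; NA if precision + sensitivity is 0.
#' @export
f1_score <- function(precision, sensitivity) {
  if (!is.finite(precision) || !is.finite(sensitivity)) return(NA_real_)
  if (precision + sensitivity <= 0) return(NA_real_)
  2 * precision * sensitivity / (precision + sensitivity)
}

#' Classification metrics for the SOZ-vs-rest decision
#'
#' Per-IC binary confusion on `positive_class`: precision = TP/(TP+FP),
#' sensitivity = TP/(TP+FN), accuracy = (TP+TN)/n, F1 = harmonic mean of
#' precision and sensitivity. Undefined ratios (zero denominator) are NA
#' with a flag.
#'
#' @param predictions,truths Character vectors of equal length.
#' @param positive_class Positive class (default "SOZ").
#' @return List of class `soz_metrics`: accuracy, precision, sensitivity,
#'   f1 (fractions in [0,1] or NA), counts (TP/FP/FN/TN), n,
#'   zero_denominator (character vector of affected metrics).
#' @export
compute_metrics <- function(predictions, truths, positive_class = "SOZ") {
  if (length(predictions) != length(truths)) stop("length mismatch")
  if (length(predictions) == 0L) stop("empty input")
  pp <- predictions == positive_class
  tp_ <- truths == positive_class
  TP <- sum(pp & tp_); FP <- sum(pp & !tp_)
  FN <- sum(!pp & tp_); TN <- sum(!pp & !tp_)
  zd <- character(0)
  precision <- if (TP + FP > 0) TP / (TP + FP) else { zd <- c(zd, "precision"); NA_real_ }
  sensitivity <- if (TP + FN > 0) TP / (TP + FN) else { zd <- c(zd, "sensitivity"); NA_real_ }
  f1 <- if (is.finite(precision) && is.finite(sensitivity) && precision + sensitivity > 0) {
    f1_score(precision, sensitivity)
  } else { zd <- c(zd, "f1"); NA_real_ }
  structure(list(accuracy = (TP + TN) / length(truths),
                 precision = precision, sensitivity = sensitivity, f1 = f1,
                 counts = c(TP = TP, FP = FP, FN = FN, TN = TN),
                 n = length(truths), zero_denominator = zd),
            class = "soz_metrics")
}

#' @export
print.soz_metrics <- function(x, ...) {
  pc <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", 100 * v)
  cat(sprintf("<soz_metrics> n=%d acc=%s prec=%s sens=%s F1=%s (TP=%d FP=%d FN=%d TN=%d)\n",
              x$n, pc(x$accuracy), pc(x$precision), pc(x$sensitivity), pc(x$f1),
              x$counts["TP"], x$counts["FP"], x$counts["FN"], x$counts["TN"]))
  invisible(x)
}

#' Effect-of-knowledge deltas between two metric sets
#'
#' Elementwise difference (first minus second) of accuracy, precision,
#' sensitivity and F1, quantifying what expert-knowledge integration adds
#' over the CNN-only baseline evaluated on the identical test set.
#'
#' @param metrics_full,metrics_baseline `soz_metrics` objects computed on
#'   the same number of ICs.
#' @return Named numeric vector of deltas.
#' @export
eok_delta <- function(metrics_full, metrics_baseline) {
  if (metrics_full$n != metrics_baseline$n)
    stop("metric sets were not computed on identical test sets")
  nm <- c("accuracy", "precision", "sensitivity", "f1")
  vapply(nm, function(k) {
    a <- metrics_full[[k]]; b <- metrics_baseline[[k]]
    if (is.na(a)) a <- 0; if (is.na(b)) b <- 0
    a - b
  }, 0)
}

#' Normality check and one-sided comparison of subgroup metrics
#'
#' For each method's metric values across test-data subgroups: a
#' Kolmogorov-Smirnov check against a normal distribution with the sample
#' moments, then a one-sided two-sample t-test (alternative: the first
#' method is greater). Zero-variance (degenerate) samples are reported as
#' such; for two exactly constant samples the t p-value is defined by the
#' sign of the mean difference (0.5 on equality).
#'
#' @param x,y Numeric metric samples (>= 3 each) for the two methods.
#' @param alpha Flagging level (default 0.05).
#' @return List: `ks_p` (length-2), `t_p`, `significant`, `degenerate`.
#' @export
significance_tests <- function(x, y, alpha = 0.05) {
  if (length(x) < 3L || length(y) < 3L) stop("need >= 3 subgroup samples per method")
  ks1 <- function(v) {
    if (stats::sd(v) == 0) return(NA_real_)
    suppressWarnings(stats::ks.test(v, "pnorm", mean(v), stats::sd(v))$p.value)
  }
  ks_p <- c(ks1(x), ks1(y))
  degenerate <- stats::sd(x) == 0 && stats::sd(y) == 0
  t_p <- if (degenerate) {
    d <- mean(x) - mean(y)
    if (d > 0) 0 else if (d < 0) 1 else 0.5
  } else {
    stats::t.test(x, y, alternative = "greater")$p.value
  }
  list(ks_p = ks_p, t_p = t_p, significant = is.finite(t_p) && t_p < alpha,
       degenerate = degenerate)
}

# ---------------------------------------------------------------------------
# Cohort-level feature extraction (one pass, shared by all experiments)

#' Extract features and CNN inputs for a whole cohort
#'
#' Single pass over the cohort: renders each IC's native montage, runs the
#' expert-feature pipeline ([ic_expert_features()]), stores the retained
#' clusters (for localization) and the CNN-ready image (resized to the
#' CNN's input size). This is the expensive step; its result feeds
#' [loocv()], [ablation_suite()] and prediction.
#'
#' @param cohort A [generate_cohort()] result.
#' @param cnn_cfg [cnn_config()] fixing the CNN input size.
#' @param dbscan [dbscan_params()].
#' @param progress Print a dot every 50 ICs.
#' @return Object of class `cohort_features`: `ics` (manifest), `features`
#'   (n x 4 matrix), `clusters` (per-IC list), `images` (per-IC array).
#' @export
cohort_features <- function(cohort, cnn_cfg = cnn_small_config(),
                            dbscan = dbscan_params(), progress = FALSE) {
  tpl <- slice_template(cohort$config)
  n <- nrow(cohort$ics)
  feats <- matrix(NA_real_, n, 4,
                  dimnames = list(cohort$ics$ic_id, .feature_names))
  clusters <- vector("list", n)
  images <- vector("list", n)
  tgt <- cnn_cfg$input_size
  for (i in seq_len(n)) {
    m <- cohort_montage(cohort, cohort$ics$ic_id[i])
    fx <- ic_expert_features(m, cohort$timecourses[[cohort$ics$ic_id[i]]],
                             template = tpl, config = cohort$config,
                             dbscan = dbscan)
    feats[i, ] <- fx$features$values
    clusters[[i]] <- fx$clusters
    # single bilinear reduction straight to the CNN input size (equivalent
    # to resizing for the CNN and downscaling again, minus one interpolation)
    img <- array(0, tgt)
    for (ch in 1:3) img[, , ch] <- .resize_mat(m$pixels[, , ch], tgt[1], tgt[2])
    images[[i]] <- img
    if (progress && i %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  structure(list(ics = cohort$ics, features = feats, clusters = clusters,
                 images = images, cnn_cfg = cnn_cfg),
            class = "cohort_features")
}

#' @export
print.cohort_features <- function(x, ...) {
  cat(sprintf("<cohort_features> %d ICs x %d features, CNN inputs %s\n",
              nrow(x$features), ncol(x$features),
              paste(x$cnn_cfg$input_size, collapse = "x")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Leave-one-patient-out cross-validation

#' Leave-one-patient-out cross-validation of the full pipeline
#'
#' For every fold, the CNN noise screen and the expert-knowledge model are
#' trained on all other patients (EKI on SMOTE-balanced RSN/SOZ features)
#' and the held-out patient's ICs are labeled by the fusion rule. Every IC
#' is predicted exactly once. The cost-sensitive 3-class CNN baseline uses
#' the same folds (`mode = "cnn3"`).
#'
#' @param feats A [cohort_features()] result.
#' @param mode "fused" (CNN + expert fusion) or "cnn3" (3-class CNN only).
#' @param feature_mask Logical 4-vector enabling expert features (ablation).
#' @param dl_cache Optional environment; per-fold CNN outputs are stored
#'   there and re-used when present (the CNN arm does not depend on the
#'   feature mask, so ablation variants share it).
#' @param seed Base seed; per-fold seeds are derived from it.
#' @param rho_threshold Fusion override threshold (default 0.9).
#' @return Object of class `evaluation_report`: `predictions` (data frame),
#'   `metrics` (SOZ-vs-rest `soz_metrics`), `per_patient_sensitivity`,
#'   `by_age`, `by_sex`, `mode`, `feature_mask`, `seed`.
#' @export
loocv <- function(feats, mode = c("fused", "cnn3"),
                  feature_mask = rep(TRUE, 4), dl_cache = NULL,
                  seed = 1L, rho_threshold = 0.9) {
  mode <- match.arg(mode)
  ics <- feats$ics
  patients <- unique(ics$patient_id)
  if (length(patients) < 2L) stop("leave-one-out needs >= 2 patients")
  preds <- vector("list", length(patients))
  for (k in seq_along(patients)) {
    pid <- patients[k]
    te <- which(ics$patient_id == pid)
    tr <- which(ics$patient_id != pid)
    key <- paste0(mode, "_", pid)
    dl_out <- if (!is.null(dl_cache)) dl_cache[[key]] else NULL
    if (is.null(dl_out)) {
      cfg <- feats$cnn_cfg
      cfg$seed <- as.integer(seed + 7L * k)
      cfg$n_classes <- if (mode == "cnn3") 3L else 1L
      cfg$class_weights <- NULL
      model <- build_model(cfg)
      if (mode == "cnn3") {
        cnn_train(model, feats$images[tr], ics$label[tr])
        dl_out <- vapply(te, function(i) predict_3class(model, feats$images[[i]])$label, "")
      } else {
        cnn_train(model, feats$images[tr], relabel_for_noise(ics$label[tr]))
        dl_out <- vapply(te, function(i) predict_noise(model, feats$images[[i]])$probability, 0)
      }
      if (!is.null(dl_cache)) dl_cache[[key]] <- dl_out
    }
    if (mode == "cnn3") {
      preds[[k]] <- data.frame(ic_id = ics$ic_id[te], patient_id = pid,
                               truth = ics$label[te], final = dl_out,
                               stringsAsFactors = FALSE)
      next
    }
    rs <- tr[ics$label[tr] %in% c("RSN", "SOZ")]
    if (sum(ics$label[rs] == "SOZ") < 2L)
      stop("fewer than 2 SOZ ICs in the training union; SMOTE is infeasible. ",
           "Increase ics_per_patient or the SOZ proportion.")
    fm <- as.logical(feature_mask)
    fx <- lapply(rs, function(i) expert_features(feats$features[i, ], mask = fm))
    pairs <- training_pairs(fx, ics$label[rs])
    pairs <- balance_with_smote(pairs, seed = seed + 31L * k)
    eki <- fit_weights(pairs, rho_threshold = rho_threshold, feature_mask = fm)
    fold <- lapply(seq_along(te), function(j) {
      i <- te[j]
      f <- expert_features(feats$features[i, ], mask = fm)
      ek <- classify_eki(eki, f)
      dl_label <- if (dl_out[j] >= 0.5) "NOISE-bar" else "NOISE"
      data.frame(ic_id = ics$ic_id[i], patient_id = pid, truth = ics$label[i],
                 dl_label = dl_label, dl_prob = dl_out[j],
                 eki_label = ek$label, rho = ek$rho,
                 final = fuse(dl_label, ek$label, ek$rho, rho_threshold),
                 explanation = ek$explanation, stringsAsFactors = FALSE)
    })
    preds[[k]] <- do.call(rbind, fold)
  }
  pred_df <- do.call(rbind, preds)
  pred_df <- merge(pred_df, unique(ics[, c("ic_id", "age_group", "sex")]),
                   by = "ic_id", sort = FALSE)
  met <- compute_metrics(pred_df$final, pred_df$truth)
  per_pat <- vapply(split(pred_df, pred_df$patient_id), function(d) {
    has_true <- any(d$truth == "SOZ")
    if (!has_true) return(NA_real_)
    as.numeric(any(d$final == "SOZ" & d$truth == "SOZ"))
  }, 0)
  by_group <- function(col) {
    lapply(split(pred_df, pred_df[[col]]), function(d)
      compute_metrics(d$final, d$truth))
  }
  structure(list(predictions = pred_df, metrics = met,
                 per_patient_sensitivity = mean(per_pat, na.rm = TRUE),
                 by_age = by_group("age_group"), by_sex = by_group("sex"),
                 mode = mode, feature_mask = as.logical(feature_mask),
                 seed = seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> mode=%s features=%s\n", x$mode,
              paste(ifelse(x$feature_mask, "+", "-"), collapse = "")))
  print(x$metrics)
  cat(sprintf("  per-patient SOZ sensitivity: %.1f%%\n",
              100 * x$per_patient_sensitivity))
  invisible(x)
}

#' Knowledge-ablation experiment
#'
#' Re-runs the leave-one-patient-out evaluation with each expert feature
#' masked in turn (plus the full model), re-using the per-fold CNN outputs
#' (the CNN arm is independent of the feature mask). Reports per-variant
#' metrics and F1/accuracy drops versus the full model.
#'
#' @param feats A [cohort_features()] result.
#' @param features_to_mask Character vector of feature names to ablate one
#'   at a time (default all four).
#' @param seed Base seed passed to [loocv()].
#' @param dl_cache Optional environment of per-fold CNN outputs (shared
#'   with a previous [loocv()] run to avoid retraining identical models).
#' @return List of class `ablation_result`: `full` (report), `variants`
#'   (named list of reports), `table` (data frame with accuracy, f1 and
#'   f1_drop in percentage points).
#' @export
ablation_suite <- function(feats, features_to_mask = .feature_names, seed = 1L,
                           dl_cache = NULL) {
  stopifnot(all(features_to_mask %in% .feature_names))
  cache <- if (is.null(dl_cache)) new.env(parent = emptyenv()) else dl_cache
  full <- loocv(feats, mode = "fused", dl_cache = cache, seed = seed)
  variants <- list()
  for (fn in features_to_mask) {
    mask <- .feature_names != fn
    variants[[paste0("without_", fn)]] <-
      loocv(feats, mode = "fused", feature_mask = mask, dl_cache = cache, seed = seed)
  }
  pct <- function(v) if (is.na(v)) 0 else 100 * v
  tab <- do.call(rbind, lapply(c(list(full_model = full), variants), function(r) {
    data.frame(accuracy = pct(r$metrics$accuracy), f1 = pct(r$metrics$f1))
  }))
  tab$f1_drop <- tab$f1[1] - tab$f1
  structure(list(full = full, variants = variants, table = tab),
            class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  cat("<ablation_result>\n")
  print(round(x$table, 1))
  invisible(x)
}
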