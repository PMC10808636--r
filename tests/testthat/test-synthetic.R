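test_that("config validation enforces the cohort invariants", {
  expect_error(synthetic_config(class_proportions = c(0.5, 0.4, 0.2)), "summing to 1")
  expect_error(synthetic_config(class_proportions = c(0.6, 0.4, 0)), "SOZ")
  expect_error(synthetic_config(ics_per_patient = 2), "honor")
  expect_error(synthetic_config(separation = 1.5), "separation")
  expect_error(synthetic_config(montage_grid = c(2, 3)), "grid")
})

test_that("realized class counts stay within 2% of the configured mix", {
  cfg <- synthetic_config(seed = 7, n_patients = 10, ics_per_patient = 100,
                          class_proportions = c(0.51, 0.43, 0.06))
  cohort <- generate_cohort(cfg)
  tab <- table(cohort$ics$label)
  expect_equal(nrow(cohort$ics), 1000L)
  expect_lte(abs(tab[["NOISE"]] - 510), 20)
  expect_lte(abs(tab[["RSN"]] - 430), 20)
  expect_lte(abs(tab[["SOZ"]] - 60), 20)
  # every patient keeps at least one SOZ IC
  per_pat <- tapply(cohort$ics$label == "SOZ", cohort$ics$patient_id, sum)
  expect_true(all(per_pat >= 1))
})

test_that("cohort generation is a pure function of (config, seed)", {
  cfg <- synthetic_config(seed = 99, n_patients = 2, ics_per_patient = 12)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$ics, b$ics)
  expect_identical(a$timecourses, b$timecourses)
  id <- a$ics$ic_id[5]
  expect_identical(cohort_montage(a, id), cohort_montage(b, id))
})

test_that("montage class geometry obeys the expert rules at separation 1", {
  cfg <- synthetic_config(seed = 3, n_patients = 2, ics_per_patient = 12)
  lay <- tile_layout(cfg)
  for (k in 1:4) {
    m <- generate_montage("SOZ", 300 + k, cfg)
    act <- attr(m, "activation_mask")
    # asymmetric: all activation on one side of each involved tile
    sides <- c()
    for (i in seq_len(nrow(lay))) {
      sub <- act[lay$row0[i] + seq_len(lay$tile_h[i]),
                 lay$col0[i] + seq_len(lay$tile_w[i])]
      if (!any(sub)) next
      mid <- (lay$tile_w[i] + 1) / 2
      cols <- which(sub, arr.ind = TRUE)[, 2]
      side_frac <- max(mean(cols > mid), mean(cols < mid))
      sides <- c(sides, sign(mean(sign(cols - mid))))
      expect_gte(side_frac, 0.97)   # lateralized (capsule tip may graze midline)
    }
    expect_true(length(unique(sides)) == 1)   # same hemisphere on all slices
  }
  m <- generate_montage("RSN", 11, cfg)
  act <- attr(m, "activation_mask")
  for (i in seq_len(nrow(lay))) {
    sub <- act[lay$row0[i] + seq_len(lay$tile_h[i]),
               lay$col0[i] + seq_len(lay$tile_w[i])]
    if (!any(sub)) next
    # mirrored across the tile midline: reflection overlaps well
    refl <- sub[, rev(seq_len(ncol(sub)))]
    expect_gt(sum(sub & refl) / sum(sub), 0.8)
  }
})

test_that("noise montages keep activation off the brain parenchyma", {
  cfg <- synthetic_config(seed = 3, n_patients = 2, ics_per_patient = 12)
  lay <- tile_layout(cfg)
  m <- generate_montage("NOISE", 17, cfg)
  act <- attr(m, "activation_mask")
  # classify every activation pixel against the tile's elliptical geometry:
  # it must be on/outside the boundary rim or a small white-matter speckle
  ok <- 0; total <- 0
  for (i in seq_len(nrow(lay))) {
    sub <- act[lay$row0[i] + seq_len(lay$tile_h[i]),
               lay$col0[i] + seq_len(lay$tile_w[i])]
    if (!any(sub)) next
    f <- sozloc:::.tile_fields(lay$tile_h[i], lay$tile_w[i], lay$s[i],
                               lay$is_base[i])
    good <- sub & (f$e >= 0.95 | abs(f$e - 0.55) <= 0.13)
    ok <- ok + sum(good); total <- total + sum(sub)
  }
  # plus montage-background speckles outside any tile ellipse, all counted ok
  expect_gte(ok / total, 0.97)
})

test_that("time courses have the declared length, TR, and a noise floor", {
  cfg <- synthetic_config(seed = 3, n_patients = 2, ics_per_patient = 12)
  for (lab in c("NOISE", "RSN", "SOZ")) {
    tc <- generate_timecourse(lab, 5, cfg)
    expect_length(tc$samples, 600L)
    expect_equal(tc$tr_seconds, 2)
    expect_gt(stats::sd(tc$samples), 0)
  }
})

test_that("cohort export writes the declared plain-text artifacts", {
  cohort <- tiny_cohort()
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir, montages = FALSE)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), nrow(cohort$ics))
  expect_named(man, c("patient_id", "ic_id", "label", "age_group", "sex"))
  tc <- read.csv(file.path(dir, "timecourses.csv"))
  expect_equal(dim(tc), c(600L, nrow(cohort$ics)))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"))
  expect_equal(cfg$seed, 42L)
})
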