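# Minimal hand-built slice/cluster scaffolding for the scoring rules.
fake_slice <- function(h = 60, w = 60) {
  bm <- matrix(FALSE, h, w); bm[10:50, 10:50] <- TRUE
  structure(list(pixels = array(0, c(h, w, 3)), tile_index = 0L,
                 origin = c(row = 0L, col = 0L), brain_mask = bm,
                 is_base_slice = TRUE), class = "brain_slice")
}

fake_cluster <- function(rows, cols, tile = 0L) {
  px <- as.matrix(expand.grid(row = rows, col = cols))
  structure(list(pixels = px, size_px = nrow(px),
                 centroid = c(row = mean(px[, 1]), col = mean(px[, 2])),
                 tile_index = tile, overlaps_white_matter = NA,
                 reaches_ventricle = NA), class = "activation_cluster")
}

test_that("cluster-count score follows the documented formula", {
  s <- fake_slice()
  # one cluster entirely left of the brain-centroid midline -> 1
  one_left <- list(list(slice = s, clusters = list(fake_cluster(20:30, 12:22))))
  expect_equal(f_clusters(one_left), 1)
  # two equal clusters mirrored across the midline -> symmetric, score <= 0.25
  mirrored <- list(list(slice = s, clusters = list(
    fake_cluster(20:30, 12:22), fake_cluster(20:30, 38:48))))
  expect_lte(f_clusters(mirrored), 0.25)
  # no clusters -> 0
  expect_equal(f_clusters(list(list(slice = s, clusters = list()))), 0)
})

test_that("cluster-count score is invariant to content translation", {
  s1 <- fake_slice()
  cl1 <- list(fake_cluster(20:30, 12:22), fake_cluster(33:40, 15:20))
  s2 <- fake_slice()
  s2$brain_mask <- matrix(FALSE, 60, 60); s2$brain_mask[15:55, 14:54] <- TRUE
  cl2 <- list(fake_cluster(25:35, 16:26), fake_cluster(38:45, 19:24))
  expect_equal(f_clusters(list(list(slice = s1, clusters = cl1))),
               f_clusters(list(list(slice = s2, clusters = cl2))),
               tolerance = 1e-12)
})

test_that("white-matter/ventricle feature counts qualifying clusters", {
  dims <- c(60, 60)
  vent <- matrix(FALSE, dims[1], dims[2]); vent[28:32, 28:32] <- TRUE
  wm <- as.matrix(expand.grid(row = 20, col = 15:45))  # horizontal contour
  anat <- structure(list(boundary_contours = list(),
                         white_matter_contour = wm,
                         ventricle_region = vent), class = "slice_anatomy")
  # cluster crossing the contour and ending in the ventricle region
  hit <- fake_cluster(18:32, 29:31)
  # cluster far from both
  miss <- fake_cluster(45:55, 45:55)
  both <- f_wm_ventricle(list(list(anatomy = anat, clusters = list(hit, miss))))
  expect_equal(both$score, 0.5)
  flags <- both$slices[[1]]$clusters
  expect_true(flags[[1]]$overlaps_white_matter && flags[[1]]$reaches_ventricle)
  expect_false(flags[[2]]$overlaps_white_matter || flags[[2]]$reaches_ventricle)
  # contour-only cluster does not qualify
  ring_only <- f_wm_ventricle(list(list(anatomy = anat, clusters = list(
    fake_cluster(19:21, 16:20)))))
  expect_equal(ring_only$score, 0)
  # no clusters anywhere -> 0
  expect_equal(f_wm_ventricle(list(list(anatomy = anat, clusters = list())))$score, 0)
})

test_that("textbook synthetic ICs earn their designed feature values", {
  cfg <- synthetic_config(seed = 12, n_patients = 2, ics_per_patient = 12)
  tpl <- slice_template(cfg)
  for (k in 1:3) {
    soz <- ic_expert_features(generate_montage("SOZ", 500 + k, cfg),
                              generate_timecourse("SOZ", 500 + k, cfg), tpl, cfg)
    expect_equal(soz$features$values[1], 1)     # single asymmetric cluster
    expect_equal(soz$features$values[2], 1)     # ring -> contour -> ventricle
    rsn <- ic_expert_features(generate_montage("RSN", 600 + k, cfg),
                              generate_timecourse("RSN", 600 + k, cfg), tpl, cfg)
    expect_lte(rsn$features$values[1], 0.25)    # mirrored multiples
    expect_equal(rsn$features$values[2], 0)     # never reaches ventricles
  }
})
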