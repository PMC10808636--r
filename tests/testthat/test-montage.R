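cfg <- synthetic_config(seed = 8, n_patients = 2, ics_per_patient = 12)
tpl <- slice_template(cfg)

test_that("resize maps native montages to 270x470 and refuses double resize", {
  m <- generate_montage("RSN", 21, cfg)
  r <- resize_montage(m)
  expect_equal(dim(r$pixels), c(270L, 470L, 3L))
  expect_false(r$native)
  expect_equal(r$ic_id, m$ic_id)
  expect_error(resize_montage(r), "already resized")
  # interpolation preserves constants
  const <- ic_montage(array(119, c(709, 1006, 3)))
  expect_true(all(abs(resize_montage(const)$pixels - 119) < 1e-9))
})

test_that("template matching recovers the generator's tile grid", {
  lay <- tile_layout(cfg)
  for (lab in c("NOISE", "RSN", "SOZ")) {
    m <- generate_montage(lab, 31, cfg)
    sl <- extract_brain_slices(m, tpl)
    expect_length(sl, 46L)
    or <- t(vapply(sl, function(s) s$origin, c(0, 0)))
    expect_lte(max(abs(or - cbind(lay$row0, lay$col0))), 2)
    expect_equal(vapply(sl, function(s) s$tile_index, 0L), 0:45)
    expect_equal(sum(vapply(sl, function(s) s$is_base_slice, TRUE)), 15L)
  }
})

test_that("a blanked tile is dropped and an all-black montage matches nothing", {
  m <- generate_montage("RSN", 32, cfg)
  lay <- tile_layout(cfg)
  i <- 20
  m$pixels[lay$row0[i + 1] + seq_len(lay$tile_h[i + 1]),
           lay$col0[i + 1] + seq_len(lay$tile_w[i + 1]), ] <- 0
  expect_length(extract_brain_slices(m, tpl), 45L)
  black <- ic_montage(array(0, c(709, 1006, 3)))
  expect_warning(sl <- extract_brain_slices(black, tpl), "no slice tile")
  expect_length(sl, 0L)
})

test_that("activation mask matches the generator overlay and is idempotent", {
  m <- generate_montage("SOZ", 33, cfg)
  truth <- attr(m, "activation_mask")
  got <- activation_mask(m)
  expect_lt(mean(xor(got, truth)), 0.01)
  # grayscale-only montage -> empty mask
  g <- generate_montage("RSN", 34, cfg)
  gm <- g$pixels[, , 2]
  gray_only <- ic_montage(array(rep(gm, 3), c(dim(gm), 3)))
  expect_false(any(activation_mask(gray_only)))
  # idempotent under re-application on a mask render
  sl <- extract_brain_slices(m, tpl)
  s <- sl[[6]]
  m1 <- activation_mask(s)
  s2 <- s; s2$pixels[, , 1][!m1] <- s$pixels[, , 1][!m1]
  expect_identical(activation_mask(s2), m1)
})

test_that("activation removal erases the overlay and survives degenerate input", {
  m <- generate_montage("SOZ", 35, cfg)
  sl <- extract_brain_slices(m, tpl)
  s <- sl[[which.max(vapply(sl, function(x) sum(activation_mask(x)), 0))]]
  before <- activation_mask(s)
  expect_gt(sum(before), 100)
  clean <- remove_activation(s)
  expect_lt(sum(activation_mask(clean)) / sum(before), 0.01)
  # no-activation slice passes through with unchanged geometry
  s0 <- sl[[46]]
  expect_false(any(activation_mask(s0)))
  expect_equal(remove_activation(s0)$pixels[, , 1], pmin(
    s0$pixels[, , 1], s0$pixels[, , 2], s0$pixels[, , 3]))
  # fully saturated red tile: inpainting falls back, no crash
  sat <- s
  sat$pixels[, , 1] <- 255; sat$pixels[, , 2] <- 80; sat$pixels[, , 3] <- 10
  expect_silent(out <- remove_activation(sat))
  expect_true(all(is.finite(out$pixels)))
})

test_that("anatomy detection finds ventricles on base slices only", {
  m <- generate_montage("RSN", 36, cfg)
  sl <- extract_brain_slices(m, tpl)
  base <- detect_anatomy(remove_activation(sl[[3]]))
  expect_gt(sum(base$ventricle_region), 0)
  expect_gt(nrow(base$white_matter_contour), 100)
  # ventricle region contains the rendered hole centroids
  f <- sozloc:::.tile_fields(141L, 100L, tile_layout(cfg)$s[3], TRUE)
  hc <- round(f$hole_centers)
  expect_true(any(base$ventricle_region[hc[1, 1] + (-2:2), hc[1, 2] + (-2:2)]))
  expect_true(any(base$ventricle_region[hc[2, 1] + (-2:2), hc[2, 2] + (-2:2)]))
  apex <- detect_anatomy(remove_activation(sl[[46]]))
  expect_equal(sum(apex$ventricle_region), 0)
  # blank slice: no interior structure, no ventricles
  blank <- sl[[46]]
  blank$pixels[] <- 2
  blank$brain_mask[] <- FALSE
  an <- detect_anatomy(remove_activation(blank))
  expect_equal(sum(an$ventricle_region), 0)
  expect_equal(nrow(an$white_matter_contour), 0)
})

test_that("ventricle region never touches a boundary contour and sits in their hull", {
  for (lab in c("RSN", "SOZ")) {
    m <- generate_montage(lab, 37, cfg)
    sl <- extract_brain_slices(m, tpl)
    for (s in sl[c(2, 5, 9, 14)]) {
      an <- detect_anatomy(remove_activation(s))
      if (!any(an$ventricle_region)) next
      bpx <- do.call(rbind, an$boundary_contours)
      vr <- which(an$ventricle_region, arr.ind = TRUE)
      expect_equal(nrow(merge(as.data.frame(vr), as.data.frame(bpx))), 0L)
      for (j in sample(nrow(vr), min(5, nrow(vr))))
        expect_true(in_convex_hull(vr[j, ], bpx))
    }
  }
})
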