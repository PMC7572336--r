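test_that("normalized depth is 0 at the ventricular surface and 1 at the cortex", {
  m <- toy_box_masks()
  depth <- normalized_depth(m$vent, m$cortex, m$wm)
  # voxels face-adjacent to the ventricle slab
  expect_true(all(depth[7, 10:20, 10:20] == 0))
  # voxels face-adjacent to the cortex slab
  expect_true(all(depth[24, 10:20, 10:20] == 1))
  # slab midpoint voxels are equidistant in the interior
  mid_lo <- depth[15, 14:16, 14:16]
  mid_hi <- depth[16, 14:16, 14:16]
  expect_true(all(mid_lo < 0.5 & mid_hi > 0.5))
  expect_equal(as.numeric(mid_lo + mid_hi), rep(1, 9), tolerance = 1e-12)
  expect_true(all(depth[m$wm] >= 0 & depth[m$wm] <= 1))
  expect_true(all(is.na(depth[!m$wm])))
})

test_that("depth and layer assignment match the brute-force oracle on a 32^3 toy", {
  m <- toy_box_masks(n = 32L, vent_to = 5L, wm_to = 22L, cortex_to = 27L)
  depth <- normalized_depth(m$vent, m$cortex, m$wm)
  oracle <- oracle_depth(m$vent, m$cortex, m$wm)
  expect_equal(depth, oracle, tolerance = 1e-12)
  layers <- assign_layers(depth, 4L)
  oracle_layers <- array(NA_integer_, dim(depth))
  w <- which(m$wm)
  oracle_layers[w] <- as.integer(ifelse(oracle[w] >= 1, 4, 1 + floor(oracle[w] * 4)))
  expect_identical(layers, oracle_layers)
})

test_that("layer binning follows the half-open quartile convention", {
  d <- array(c(0, 0.10, 0.249, 0.25, 0.50, 0.749, 0.75, 0.999, 1),
             c(9, 1, 1))
  expect_equal(as.vector(assign_layers(d, 4L)),
               c(1L, 1L, 1L, 2L, 3L, 3L, 4L, 4L, 4L))
  expect_error(assign_layers(d, 0L), class = "bullseye_parameter_error")
})

test_that("geometry errors are raised for overlapping or degenerate masks", {
  m <- toy_box_masks()
  expect_error(normalized_depth(m$vent, m$cortex, m$vent),
               class = "bullseye_geometry_error")
  # a domain voxel sandwiched directly between both surfaces
  n <- 10L
  vent <- array(FALSE, c(n, n, n)); vent[4, 5, 5] <- TRUE
  cortex <- array(FALSE, c(n, n, n)); cortex[6, 5, 5] <- TRUE
  wm <- array(FALSE, c(n, n, n)); wm[5, 5, 5] <- TRUE
  expect_error(normalized_depth(vent, cortex, wm),
               class = "bullseye_geometry_error")
})

test_that("the default phantom yields all 36 bullseye regions", {
  ph <- make_phantom(phantom_spec(seed = 1))
  parc <- bullseye_parcellate(ph)
  expect_equal(nrow(parc$lookup), 36L)
  expect_true(all(parc$lookup$n_voxels > 0))
  expect_equal(parc$n_unassigned, 0L)
  # partition: region voxel counts sum to the layered-voxel count
  expect_equal(sum(parc$lookup$n_voxels) + parc$n_unassigned,
               sum(!is.na(parc$labels)))
})

test_that("removing lobes removes exactly their regions", {
  ph <- make_phantom(small_phantom_spec(seed = 2))
  wm_bg <- ph$tissue == 2L | ph$tissue == 4L
  depth <- normalized_depth(ph$tissue == 1L, ph$tissue == 3L, wm_bg,
                            ph$voxel_size)
  layers <- assign_layers(depth)

  baseline <- build_parcellation(layers, ph$lobes)
  occ_ids <- bullseye_region_lookup()$region_id[
    bullseye_region_lookup()$lobe %in% c("OR", "OL")]
  n_occ <- sum(baseline$lookup$n_voxels[occ_ids] > 0)

  lob <- ph$lobes
  lob[lob %in% c(7L, 8L)] <- 0L  # drop both occipital lobes
  parc <- build_parcellation(layers, lob)
  present <- parc$lookup$region_id[parc$lookup$n_voxels > 0]
  expect_equal(length(present),
               sum(baseline$lookup$n_voxels > 0) - n_occ)
  expect_true(all(parc$lookup$n_voxels[occ_ids] == 0))
  expect_gt(parc$n_unassigned, 0)

  single <- array(0L, dim(lob))
  single[wm_bg] <- 1L
  parc1 <- build_parcellation(layers, single)
  expect_equal(sum(parc1$lookup$n_voxels > 0), 4L)
})

test_that("basal ganglia form one lobar segment crossed with the four layers", {
  ph <- make_phantom(small_phantom_spec(seed = 3))
  bg <- basal_ganglia_region(ph$tissue)
  expect_gt(sum(bg), 0)
  # disjoint from the 8 cortical-lobe WM segments
  expect_true(all(ph$lobes[bg] == 9L))
  expect_true(all(ph$lobes[ph$tissue == 2L] != 9L))

  parc <- bullseye_parcellate(ph)
  bg_rows <- parc$lookup[parc$lookup$lobe == "BG", ]
  expect_equal(sum(bg_rows$n_voxels), sum(bg))
  expect_true(all(bg_rows$n_voxels > 0))
  # BG voxels adjacent to the ventricle land in (BG, layer 1)
  touch <- bullseyeWMH:::touching_voxels(bg, ph$tissue == 1L)
  expect_true(any(touch))
  expect_true(all(parc$labels[touch] == (9L - 1L) * 4L + 1L))

  no_bg <- ph$tissue
  no_bg[no_bg == 4L] <- 2L
  expect_error(basal_ganglia_region(no_bg),
               class = "bullseye_configuration_error")
})

test_that("equidistant layers have comparable volumes on a slab geometry", {
  # with planar surfaces, equal depth width implies equal volume up to
  # discretization; concentric shells would not satisfy this
  m <- toy_box_masks(n = 36L, vent_to = 6L, wm_to = 30L, cortex_to = 34L)
  depth <- normalized_depth(m$vent, m$cortex, m$wm)
  layers <- assign_layers(depth)
  vols <- table(layers[!is.na(layers)])
  expect_equal(length(vols), 4L)
  expect_lt((max(vols) - min(vols)) / min(vols), 0.15)
})

test_that("shrinking the ventricle never decreases depth", {
  m <- toy_box_masks()
  depth1 <- normalized_depth(m$vent, m$cortex, m$wm)
  vent_small <- m$vent
  vent_small[6, , ] <- FALSE  # erode the ventricle's face towards WM
  depth2 <- normalized_depth(vent_small, m$cortex, m$wm)
  expect_true(all(depth2[m$wm] >= depth1[m$wm] - 1e-12))
})

test_that("parcellation is deterministic", {
  ph <- make_phantom(small_phantom_spec(seed = 4))
  p1 <- bullseye_parcellate(ph)
  p2 <- bullseye_parcellate(ph)
  expect_identical(p1$labels, p2$labels)
  expect_identical(p1$lookup, p2$lookup)
})
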