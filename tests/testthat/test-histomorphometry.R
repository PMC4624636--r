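test_that("slide tiling is half-open with exact offsets and pad masks", {
  img <- array(runif(80 * 80 * 3), c(80, 80, 3))
  t1 <- tile_slide(img, 80)
  expect_equal(length(t1), 1)
  expect_equal(t1[[1]]$offset_px, c(0, 0))
  expect_false(any(t1[[1]]$pad_mask))

  img2 <- array(0, c(160, 80, 3))
  t2 <- tile_slide(img2, 80)
  expect_equal(length(t2), 2)
  expect_equal(t2[[2]]$offset_px, c(80, 0))

  # 90 x 90 with 80-px tiles: 4 tiles, margins of 70 px padded
  img3 <- array(1, c(90, 90, 3))
  t3 <- tile_slide(img3, 80)
  expect_equal(length(t3), 4)
  corner <- t3[[4]]
  expect_equal(corner$offset_px, c(80, 80))
  expect_equal(sum(!corner$pad_mask), 10 * 10)
  expect_equal(sum(corner$pad_mask[11:80, ]), 70 * 80)
  # padded pixels are zero, content pixels preserved
  expect_true(all(corner$data[corner$pad_mask] == 0))
  expect_true(all(corner$data[!corner$pad_mask] == 1))
})

test_that("HSI segmentation applies the window literally", {
  img <- array(runif(30 * 30 * 3), c(30, 30, 3))
  expect_true(all(hsi_segment(img, hsi_window())))
  expect_false(any(hsi_segment(img, hsi_window(h = c(0.4, 0.4001),
                                               s = c(0.99999, 1), i = c(0, 1e-9)))))
  # wrap-around hue window catches reds on both sides of 0
  reds <- array(0, c(2, 1, 3))
  reds[1, 1, ] <- c(1, 0.05, 0.05)   # hue just above 0
  reds[2, 1, ] <- c(1, 0.05, 0.12)   # hue just below 1
  w <- hsi_window(h = c(0.95, 0.05), s = c(0.5, 1), i = c(0.5, 1))
  expect_true(all(hsi_segment(reds, w)))
})

test_that("Crofton perimeters hit analytic values and add over objects", {
  expect_equal(nrow(object_perimeters(matrix(FALSE, 10, 10), 1)$perimeters), 0)
  expect_equal(object_perimeters(matrix(FALSE, 10, 10), 1)$total_um, 0)

  # filled circle r = 100 px at 0.42 um/px: within 5% of 2*pi*100*0.42
  m <- disk_mask(220, c(110, 110), 100)
  vm <- object_perimeters(m, 0.42)
  expect_equal(nrow(vm$perimeters), 1)
  expect_lt(abs(vm$total_um / (2 * pi * 100 * 0.42) - 1), 0.05)

  # two disjoint objects: totals add
  m2 <- disk_mask(400, c(100, 100), 60) | disk_mask(400, c(300, 300), 40)
  vm2 <- object_perimeters(m2, 0.42)
  expect_equal(nrow(vm2$perimeters), 2)
  single <- object_perimeters(disk_mask(400, c(100, 100), 60), 0.42)$total_um +
    object_perimeters(disk_mask(400, c(300, 300), 40), 0.42)$total_um
  expect_equal(vm2$total_um, single, tolerance = 1e-12)

  # annulus: one 8-connected component, hole boundary included
  ring <- disk_mask(200, c(100, 100), 80) & !disk_mask(200, c(100, 100), 40)
  vr <- object_perimeters(ring, 0.42)
  expect_equal(nrow(vr$perimeters), 1)
  expect_lt(abs(vr$total_um / (2 * pi * (80 + 40) * 0.42) - 1), 0.05)

  # scale consistency: doubling the pitch doubles every perimeter
  vm_2x <- object_perimeters(m, 0.84)
  expect_equal(vm_2x$perimeters$perimeter_um, 2 * vm$perimeters$perimeter_um)
})

test_that("block TVP maps conserve the whole-mask total exactly", {
  set.seed(9)
  mask <- matrix(runif(300 * 300) < 0.2, 300, 300)
  vm <- object_perimeters(mask, 1)
  bm <- tvp_block_map(mask, pixel_pitch_um = 1, block_size_mm = 0.1)  # 100-px blocks
  expect_equal(dim(bm$tvp_um), c(3, 3))
  expect_lt(abs(sum(bm$tvp_um) / vm$total_um - 1), 1e-9)
  expect_true(all(bm$tvp_um >= 0))

  # translation-periodic pattern with period = block side: equal blocks
  cellm <- matrix(FALSE, 100, 100); cellm[40:60, 40:60] <- TRUE
  per <- rbind(cbind(cellm, cellm, cellm), cbind(cellm, cellm, cellm),
               cbind(cellm, cellm, cellm))
  bmp <- tvp_block_map(per, pixel_pitch_um = 1, block_size_mm = 0.1)
  expect_equal(length(unique(as.vector(bmp$tvp_um))), 1)

  # non-pixel-aligned block size is rejected
  expect_error(tvp_block_map(mask, pixel_pitch_um = 0.42, block_size_mm = 0.1),
               "whole number")
})

test_that("lesion block selection follows the overlap rule boundary", {
  mask <- matrix(FALSE, 200, 200)
  mask[50, 50] <- TRUE
  bm <- tvp_block_map(mask, pixel_pitch_um = 1, block_size_mm = 0.1)

  all_lesion <- matrix(TRUE, 200, 200)
  expect_equal(nrow(select_lesion_blocks(bm, all_lesion)), 4)
  expect_equal(nrow(select_lesion_blocks(bm, matrix(FALSE, 200, 200))), 0)

  # block exactly half covered: selected at rule 0.5, not at 0.51
  half <- matrix(FALSE, 200, 200)
  half[1:50, 1:100] <- TRUE  # covers half of block (1,1) only
  expect_true(any(apply(select_lesion_blocks(bm, half, 0.5), 1, identical, c(row = 1L, col = 1L))))
  expect_equal(nrow(select_lesion_blocks(bm, half, 0.51)), 0)
})

test_that("lesional TVP/area follows the block arithmetic", {
  bm <- structure(list(tvp_um = matrix(1000, 4, 4), block_size_mm = 0.84,
                       block_area_mm2 = 0.84^2, block_px = 2000,
                       pixel_pitch_um = 0.42, mask_dim = c(8000L, 8000L)),
                  class = "tvp_block_map")
  sel3 <- cbind(c(1, 2, 3), c(1, 1, 1))
  r3 <- lesional_tvp_per_area(bm, sel3)
  expect_equal(r3$area_mm2, 3 * 0.7056)
  expect_equal(r3$ratio_um_per_mm2, 3000 / 2.1168, tolerance = 1e-12)

  # all blocks: ratio = whole-slide TVP / slide area
  all_sel <- which(matrix(TRUE, 4, 4), arr.ind = TRUE)
  r_all <- lesional_tvp_per_area(bm, all_sel)
  expect_equal(r_all$ratio_um_per_mm2, 16000 / (16 * 0.7056))

  # empty selection: explicitly undefined
  r0 <- lesional_tvp_per_area(bm, matrix(integer(), 0, 2))
  expect_true(r0$undefined)
  expect_true(is.na(r0$ratio_um_per_mm2))

  expect_error(lesional_tvp_per_area(bm, cbind(5, 1)), "outside")
})

test_that("measured lesional TVP/area matches generator ground truth", {
  # vessels confined to a known lesion disk; blocks 250 px at 1 um/px
  vessels <- list(
    list(kind = "disk", center_px = c(260, 260), r_px = 30),
    list(kind = "annulus", center_px = c(370, 300), r_px = 35, r_in_px = 15),
    list(kind = "disk", center_px = c(300, 400), r_px = 25))
  hs <- histology_spec(tile_px = 750, pixel_pitch_um = 1, vessels = vessels,
                       lesion = list(center_px = c(330, 330), radius_px = 180))
  hp <- generate_histology(hs, seed = 1)
  mask <- hsi_segment(hp$rgb, hp$stain_window)
  bm <- tvp_block_map(mask, pixel_pitch_um = 1, block_size_mm = 0.25)
  sel <- select_lesion_blocks(bm, hp$lesion_mask, min_overlap = 0.05)
  res <- lesional_tvp_per_area(bm, sel)
  # every vessel lies in a selected block, so TVP should match analytic truth
  expect_lt(abs(res$tvp_um / sum(hp$vessel_truth$perimeter_um) - 1), 0.05)

  # density invariance: replicating the field over twice the blocks leaves
  # TVP/area unchanged within 2%
  m_rep <- rbind(cbind(mask, mask), cbind(mask, mask))
  bm_rep <- tvp_block_map(m_rep, pixel_pitch_um = 1, block_size_mm = 0.25)
  all_blocks <- which(bm$tvp_um >= 0, arr.ind = TRUE)
  all_blocks_rep <- which(bm_rep$tvp_um >= 0, arr.ind = TRUE)
  r1 <- lesional_tvp_per_area(bm, all_blocks)
  r2 <- lesional_tvp_per_area(bm_rep, all_blocks_rep)
  expect_lt(abs(r2$ratio_um_per_mm2 / r1$ratio_um_per_mm2 - 1), 0.02)
})
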