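test_that("absorption inversion is the exact inverse of the pressure model", {
  g <- 0.20
  phi <- pam_volume(array(runif(64, 0.5, 2), c(4, 4, 4)), 1, kind = "fluence")
  p0 <- pam_volume(g * phi$data, 1, wavelength_nm = 756, kind = "p0")
  mua <- estimate_absorption(p0, phi, g)
  expect_equal(mua$data, array(1, c(4, 4, 4)), tolerance = 1e-12)

  p00 <- pam_volume(array(0, c(4, 4, 4)), 1, wavelength_nm = 756, kind = "p0")
  expect_true(all(estimate_absorption(p00, phi, g)$data == 0))

  bad_phi <- phi; bad_phi$data[1] <- 0
  expect_error(estimate_absorption(p0, bad_phi, g), "positive")
})

test_that("two-wavelength unmixing solves the extinction system", {
  dims <- c(10, 10, 10)
  # identity-like extinction: concentrations pass through
  eps_id <- extinction_table(c(756, 797), eps_hbo2 = c(1, 1e-9), eps_hb = c(1e-9, 1))
  mua1 <- pam_volume(array(0.3, dims), 1, wavelength_nm = 756)
  mua2 <- pam_volume(array(0.7, dims), 1, wavelength_nm = 797)
  un <- unmix_chromophores(mua1, mua2, eps_id)
  expect_equal(un$c_hbo$data, array(0.3, dims), tolerance = 1e-8)
  expect_equal(un$c_hb$data, array(0.7, dims), tolerance = 1e-8)

  # forward-compose from random concentrations, then invert: exact recovery
  set.seed(11)
  eps <- test_eps()
  c_hbo <- array(runif(prod(dims), 0, 1e-4), dims)
  c_hb <- array(runif(prod(dims), 0, 1e-4), dims)
  m1 <- pam_volume(eps$eps_hbo2[1] * c_hbo + eps$eps_hb[1] * c_hb, 1, wavelength_nm = 756)
  m2 <- pam_volume(eps$eps_hbo2[2] * c_hbo + eps$eps_hb[2] * c_hb, 1, wavelength_nm = 797)
  un2 <- unmix_chromophores(m1, m2, eps)
  expect_equal(un2$c_hbo$data, c_hbo, tolerance = 1e-10)
  expect_equal(un2$c_hb$data, c_hb, tolerance = 1e-10)

  # isosbestic second wavelength: THC = mua(l2) / eps regardless of l1
  eps_iso <- extinction_table(c(756, 797), eps_hbo2 = c(620, 800), eps_hb = c(1590, 800))
  un3 <- unmix_chromophores(m1, m2, eps_iso)
  thc <- un3$c_hbo$data + un3$c_hb$data
  expect_equal(thc, m2$data / 800, tolerance = 1e-10)

  # singular pair is rejected with its condition number
  eps_sing <- extinction_table(c(756, 797), eps_hbo2 = c(600, 600), eps_hb = c(1200, 1200))
  expect_error(unmix_chromophores(m1, m2, eps_sing), "condition")
})

test_that("SO2 map is the concentration ratio with validity and flag accounting", {
  dims <- c(6, 6, 6)
  mk <- function(x) pam_volume(array(x, dims), 1)
  # equal concentrations: 0.5 everywhere
  s1 <- so2_from_concentrations(mk(1e-4), mk(1e-4), thc_floor = 0)
  expect_true(all(s1$so2$data == 0.5))

  # pure oxyhemoglobin: 1.0
  s2 <- so2_from_concentrations(mk(1e-4), mk(0), thc_floor = 0)
  expect_true(all(s2$so2$data == 1))

  # scale invariance: 0.85/0.15 split at any total
  for (t in c(1e-6, 1e-4, 3.7)) {
    s <- so2_from_concentrations(mk(0.85 * t), mk(0.15 * t), thc_floor = 0)
    expect_equal(unique(as.vector(s$so2$data)), 0.85, tolerance = 1e-12)
  }

  # voxels under the THC floor are invalid, out-of-range values are flagged
  c_hbo <- mk(1e-4); c_hbo$data[1, 1, 1] <- 1e-9; c_hbo$data[2, 1, 1] <- -2e-4
  c_hb <- mk(1e-5); c_hb$data[1, 1, 1] <- 1e-9; c_hb$data[2, 1, 1] <- 3e-4
  s3 <- so2_from_concentrations(c_hbo, c_hb, thc_floor = 1e-6)
  expect_false(s3$valid[1, 1, 1])
  expect_true(is.na(s3$so2$data[1, 1, 1]))
  expect_true(s3$so2$data[2, 1, 1] < 0)  # kept, not clipped
  expect_equal(s3$n_flagged, 1)
})

test_that("ROI statistics summarize only valid voxels", {
  dims <- c(10, 10, 10)
  c_hbo <- pam_volume(array(0.8e-4, dims), 1)
  c_hb <- pam_volume(array(0.2e-4, dims), 1)
  s <- so2_from_concentrations(c_hbo, c_hb, thc_floor = 0)
  roi <- roi_spec("lesion", "sphere", center_mm = c(5, 5, 5), radius_mm = 3)
  rs <- roi_statistics(s, roi)
  expect_equal(rs$median, 0.8)
  expect_equal(rs$mean, 0.8)
  expect_false(rs$empty)

  # fully invalid ROI: explicit empty result
  s_inv <- so2_from_concentrations(pam_volume(array(0, dims), 1),
                                   pam_volume(array(0, dims), 1), thc_floor = 1e-6)
  rs_inv <- roi_statistics(s_inv, roi)
  expect_true(rs_inv$empty)
  expect_true(is.na(rs_inv$median))
  expect_equal(rs_inv$n_valid, 0)

  # quartiles match a sort-based oracle
  set.seed(5)
  vals <- array(runif(prod(dims)), dims)
  s_r <- so2_from_concentrations(pam_volume(vals * 1e-4, 1),
                                 pam_volume((1 - vals) * 1e-4, 1), thc_floor = 0)
  box <- roi_spec("lesion", "box", center_mm = c(5, 5, 5), half_size_mm = c(2, 2, 2))
  rs_r <- roi_statistics(s_r, box)
  inbox <- s_r$so2$data[4:7, 4:7, 4:7]
  expect_equal(rs_r$n_valid, length(inbox))
  expect_equal(rs_r$median, unname(quantile(as.vector(inbox), 0.5)))
  expect_equal(rs_r$q1, unname(quantile(as.vector(inbox), 0.25)))
  expect_equal(rs_r$q3, unname(quantile(as.vector(inbox), 0.75)))

  expect_error(roi_statistics(s, roi_spec("lesion", "sphere",
                                          center_mm = c(50, 50, 50), radius_mm = 1)),
               "intersect")
})

test_that("signal classifier separates vessels from microvessel-rich foci", {
  mk_mip <- function(img) {
    structure(list(slabs = list(img), slab_bounds_mm = matrix(c(0, 2), 1),
                   axis = 3, slab_thickness_mm = 2, pixel_pitch_mm = 0.25),
              class = "mip_stack")
  }
  # straight bright bar 40 x 2 px (10 mm x 0.5 mm): a vessel
  bar <- matrix(0, 64, 64)
  bar[12:51, 30:31] <- 1
  res_bar <- classify_pam_signals(mk_mip(bar), intensity_threshold = 0.5)
  expect_equal(nrow(res_bar), 1)
  expect_equal(res_bar$label, "vessel")

  # 12 scattered 3-px dots within the clustering radius: one group
  dots <- matrix(0, 64, 64)
  set.seed(2)
  pts <- cbind(sample(28:36, 12, replace = TRUE), sample(28:36, 12, replace = TRUE))
  pts <- unique(pts)
  while (nrow(pts) < 12) {
    pts <- unique(rbind(pts, c(sample(26:38, 1), sample(26:38, 1))))
  }
  for (i in seq_len(12)) dots[pts[i, 1], pts[i, 2]] <- 1
  res_dots <- classify_pam_signals(mk_mip(dots), intensity_threshold = 0.5)
  expect_true(all(res_dots$label %in% c("microvessel_rich", "vessel")))
  expect_gte(sum(res_dots$label == "microvessel_rich"), 5)

  # composite: bar plus a distant dot cluster
  comp <- matrix(0, 128, 128)
  comp[10:49, 20:21] <- 1
  for (i in seq_len(12)) comp[pts[i, 1] + 70, pts[i, 2] + 70] <- 1
  res_c <- classify_pam_signals(mk_mip(comp), intensity_threshold = 0.5)
  expect_equal(sum(res_c$label == "vessel"), 1)
  expect_gte(sum(res_c$label == "microvessel_rich"), 5)

  # empty image: empty labeling
  res_e <- classify_pam_signals(mk_mip(matrix(0, 16, 16)), intensity_threshold = 0.5)
  expect_equal(nrow(res_e), 0)
})
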