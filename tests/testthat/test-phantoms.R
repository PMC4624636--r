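test_that("phantom chromophore maps follow the structure placement rule", {
  # no structures: uniform zero hemoglobin (background optics live elsewhere)
  spec0 <- phantom_spec(c(8, 8, 8), 1, background_mua = c("756" = 0.05, "797" = 0.05))
  ph0 <- build_breast_phantom(spec0, seed = 1)
  expect_true(all(ph0$c_hbo$data == 0))
  expect_true(all(ph0$c_hb$data == 0))

  # sphere of so2 0.7, THC t: center voxel splits as 0.7t / 0.3t
  t_hc <- 2.3e-4
  spec <- phantom_spec(c(16, 16, 16), 1,
                       structures = list(lesion_sphere(c(8, 8, 8), 3, t_hc, 0.7)))
  ph <- build_breast_phantom(spec, seed = 1)
  cen <- c(9, 9, 9)  # voxel whose center is (8.5,8.5,8.5); (8,8,8) falls in voxel 8 too
  expect_equal(ph$c_hbo$data[8, 8, 8], 0.7 * t_hc)
  expect_equal(ph$c_hb$data[8, 8, 8], 0.3 * t_hc)

  # determinism: identical spec+seed gives bit-identical phantoms
  ph2 <- build_breast_phantom(spec, seed = 1)
  expect_identical(ph$c_hbo$data, ph2$c_hbo$data)
  expect_identical(ph$c_hb$data, ph2$c_hb$data)

  # non-negative concentrations everywhere
  expect_true(all(ph$c_hbo$data >= 0) && all(ph$c_hb$data >= 0))
})

test_that("structures outside the grid are rejected with their id", {
  spec <- phantom_spec(c(16, 16, 16), 1,
                       structures = list(lesion_sphere(c(15, 8, 8), 3, 1e-4, 0.5,
                                                       id = "edge_lesion")))
  expect_error(build_breast_phantom(spec, 1), "edge_lesion")
})

test_that("dual-sided fluence model matches its closed form", {
  # mu_eff = 0: uniform fluence 2 * Phi0
  spec <- phantom_spec(c(8, 8, 40), 1, background_mua = c("756" = 0, "797" = 0))
  ph <- build_breast_phantom(spec, 1)
  illum <- illumination_config(surface_fluence = 1.5)
  phi <- fluence_map(ph, illum, 756)
  expect_equal(unique(as.vector(phi$data)), 3.0)

  # mu_eff = 1 /cm, L = 40 mm: midplane value 2 exp(-2) Phi0, and symmetry
  illum1 <- illumination_config(surface_fluence = 1,
                                mu_eff = list("756" = 1, "797" = 1))
  phi1 <- fluence_map(ph, illum1, 756)
  prof <- phi1$data[1, 1, ]
  mid <- prof[20]  # voxel center z = 19.5 mm
  z_cm <- 1.95; L_cm <- 4
  expect_equal(mid, exp(-z_cm) + exp(-(L_cm - z_cm)))
  expect_equal(prof, rev(prof))          # Phi(z) = Phi(L - z)
  expect_true(all(phi1$data > 0))

  expect_error(fluence_map(ph, illum, 800), "756")
})

test_that("initial pressure is Grueneisen * mua * fluence", {
  # mua = 1 /cm uniform, Phi = 1, G = 0.20 -> P0 = 0.20
  spec <- phantom_spec(c(6, 6, 6), 1, background_mua = c("756" = 1, "797" = 1),
                       grueneisen = 0.20)
  ph <- build_breast_phantom(spec, 1)
  phi1 <- pam_volume(array(1, c(6, 6, 6)), 1, units = "J/cm^2", kind = "fluence")
  p0 <- initial_pressure_map(ph, phi1, 756, test_eps())
  expect_equal(unique(as.vector(p0$data)), 0.20)

  # mua = 0 -> P0 = 0
  spec0 <- phantom_spec(c(6, 6, 6), 1, background_mua = c("756" = 0, "797" = 0))
  ph0 <- build_breast_phantom(spec0, 1)
  p00 <- initial_pressure_map(ph0, phi1, 756, test_eps())
  expect_true(all(p00$data == 0))

  # random phantom: matches an independent scalar triple-loop oracle
  eps <- test_eps()
  spec_r <- phantom_spec(c(5, 5, 5), 1, background_mua = c("756" = 0.03, "797" = 0.02),
                         structures = list(lesion_sphere(c(2.5, 2.5, 2.5), 1.4, 8e-5, 0.65)))
  phr <- build_breast_phantom(spec_r, 1)
  set.seed(42)
  phi_r <- pam_volume(array(runif(125, 0.5, 2), c(5, 5, 5)), 1, kind = "fluence")
  p0r <- initial_pressure_map(phr, phi_r, 756, eps)
  oracle <- array(0, c(5, 5, 5))
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    mua <- eps$eps_hbo2[1] * phr$c_hbo$data[i, j, k] +
      eps$eps_hb[1] * phr$c_hb$data[i, j, k] + 0.03
    oracle[i, j, k] <- 0.20 * mua * phi_r$data[i, j, k]
  }
  expect_equal(p0r$data, oracle, tolerance = 1e-12)

  expect_error(initial_pressure_map(ph, pam_volume(array(1, c(4, 4, 4)), 1), 756),
               "match")
})

test_that("forward acoustic model honors retarded time, linearity and determinism", {
  arr <- small_array()
  z0 <- array(0, c(16, 16, 16))
  p0a <- pam_volume(z0, 1, wavelength_nm = 756, kind = "p0"); p0a$data[4, 4, 8] <- 1
  p0b <- pam_volume(z0, 1, wavelength_nm = 756, kind = "p0"); p0b$data[12, 12, 5] <- 2
  p0ab <- pam_volume(z0, 1, wavelength_nm = 756, kind = "p0")
  p0ab$data[4, 4, 8] <- 1; p0ab$data[12, 12, 5] <- 2

  # zero source -> zero traces
  sg0 <- simulate_sinogram(pam_volume(z0, 1, kind = "p0"), arr,
                           time_window_us = c(0, 20))
  expect_true(all(sg0$data == 0))

  # N-pulse support midpoint at t = d / c for each element
  sga <- simulate_sinogram(p0a, arr, time_window_us = c(0, 20))
  pos <- element_positions(arr)
  src_mm <- c(3.5, 3.5, 7.5)
  dt <- sga$time_us[2] - sga$time_us[1]
  for (e in c(1, 25, 49)) {
    d <- sqrt(sum((pos[e, ] - src_mm)^2))
    nz <- range(which(sga$data[e, ] != 0))
    mid_t <- mean(sga$time_us[nz])
    expect_lt(abs(mid_t - d / arr$speed_of_sound), dt)
  }

  # linearity of superposed sources
  sgb <- simulate_sinogram(p0b, arr, time_window_us = c(0, 20))
  sgab <- simulate_sinogram(p0ab, arr, time_window_us = c(0, 20))
  expect_equal(sgab$data, sga$data + sgb$data, tolerance = 1e-10)

  # determinism of the seeded noise stream
  n1 <- simulate_sinogram(p0a, arr, seed = 9, noise_sd = 0.1, time_window_us = c(0, 20))
  n2 <- simulate_sinogram(p0a, arr, seed = 9, noise_sd = 0.1, time_window_us = c(0, 20))
  expect_identical(n1$data, n2$data)

  # short window names the required length
  expect_error(simulate_sinogram(p0a, arr, time_window_us = c(0, 2)), "us")
})

test_that("analytic sphere forward matches the voxel path at a single voxel", {
  arr <- small_array()
  z0 <- array(0, c(16, 16, 16))
  p0 <- pam_volume(z0, 1, wavelength_nm = 756, kind = "p0")
  p0$data[8, 8, 8] <- 1
  sg_vox <- simulate_sinogram(p0, arr, time_window_us = c(0, 20))
  a_eq <- 1 * (3 / (4 * pi))^(1 / 3)
  sph <- data.frame(x = 7.5, y = 7.5, z = 7.5, radius_mm = a_eq, p0 = 1)
  sg_an <- simulate_sphere_sinogram(sph, arr, time_window_us = c(0, 20),
                                    wavelength_nm = 756)
  expect_equal(sg_an$data, sg_vox$data, tolerance = 1e-12)
})

test_that("histology generator renders analytic-perimeter truth", {
  # zero vessels: no truth, no stained pixels
  hs0 <- histology_spec(tile_px = 300, vessels = list())
  hp0 <- generate_histology(hs0, seed = 1)
  expect_equal(sum(hp0$vessel_truth$perimeter_um), 0)
  expect_false(any(hsi_segment(hp0$rgb, hp0$stain_window)))

  # one filled circle r = 100 px at 0.42 um/px: truth 2*pi*100*0.42
  hs1 <- histology_spec(tile_px = 300,
                        vessels = list(list(kind = "disk", center_px = c(150, 150),
                                            r_px = 100)))
  hp1 <- generate_histology(hs1, seed = 1)
  expect_equal(hp1$vessel_truth$perimeter_um, 2 * pi * 100 * 0.42, tolerance = 1e-12)

  # annulus: outer plus lumen circumference
  hs2 <- histology_spec(tile_px = 300,
                        vessels = list(list(kind = "annulus", center_px = c(150, 150),
                                            r_px = 80, r_in_px = 40)))
  hp2 <- generate_histology(hs2, seed = 1)
  expect_equal(hp2$vessel_truth$perimeter_um, 2 * pi * (80 + 40) * 0.42,
               tolerance = 1e-12)
  expect_true(hp2$vessel_truth$lumen)

  # rendered positives equal the vessel set exactly under the shared window
  mask <- hsi_segment(hp1$rgb, hp1$stain_window)
  expect_equal(sum(mask), sum(disk_mask(300, c(150, 150), 100)))

  # background color inside the stain window is rejected
  expect_error(histology_spec(tile_px = 100, background_rgb = c(139, 69, 19) / 255),
               "unresolvable")
})

test_that("cohort sampler realizes its configured effect sizes", {
  # zero shift, zero noise: lesional equals contralateral per case
  sp0 <- cohort_spec(lesion_shift = 0, noise_sd = 0)
  tab0 <- cohort_sampler(sp0, seed = 3)
  expect_equal(tab0$so2_lesion, tab0$so2_contralateral)

  # visibility probability 1: all visible
  tab1 <- cohort_sampler(cohort_spec(visibility_prob = 1), seed = 3)
  expect_true(all(tab1$visible))

  # determinism
  expect_identical(cohort_sampler(cohort_spec(), seed = 11),
                   cohort_sampler(cohort_spec(), seed = 11))

  # large-n recovery of the lesion shift (law of large numbers)
  spn <- cohort_spec(n_ibc = 5000, n_dcis = 0, lesion_shift = -0.15, noise_sd = 0.08)
  tabn <- cohort_sampler(spn, seed = 5)
  d <- tabn$so2_lesion - tabn$so2_contralateral
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - (-0.15)), 3 * se)

  expect_error(cohort_spec(visibility_prob = 1.2), "probabilities")
})

test_that("volume and sinogram containers round-trip through disk", {
  vol <- pam_volume(array(rnorm(60), c(3, 4, 5)), 0.25, origin = c(1, 2, 3),
                    wavelength_nm = 756, units = "cm^-1", kind = "mua")
  pre <- file.path(tempdir(), "vol_roundtrip")
  write_pam_volume(vol, pre)
  vol2 <- read_pam_volume(pre)
  expect_equal(vol2$data, vol$data)
  expect_equal(vol2$pitch_mm, vol$pitch_mm)
  expect_equal(vol2$origin, vol$origin)

  arr <- small_array()
  p0 <- pam_volume(array(0, c(8, 8, 8)), 1, wavelength_nm = 797, kind = "p0")
  p0$data[4, 4, 4] <- 1
  sg <- simulate_sinogram(p0, arr, time_window_us = c(0, 15))
  pre2 <- file.path(tempdir(), "sino_roundtrip")
  write_sinogram(sg, pre2)
  sg2 <- read_sinogram(pre2)
  expect_equal(sg2$data, sg$data)
  expect_equal(sg2$time_us, sg$time_us)
  expect_equal(sg2$array$n_elements, sg$array$n_elements)
})
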