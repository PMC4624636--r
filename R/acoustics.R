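#' Planar ultrasound detector array configuration
#'
#' A rectangular array in the detector plane z = 0 (the caudal compression
#' plate): by default 15 elements horizontally (x) by 23 vertically (y) at
#' 2 mm pitch — 345 elements covering 30 x 46 mm per scan position — with
#' 1 MHz central frequency. Lateral scan positions (x offsets, mm) replicate
#' the array to cover up to 120 x 46 mm. Elements are treated as points at
#' their centers; a 2 mm aperture can be approximated by `aperture_n`-point
#' sub-element averaging.
#'
#' @param n_horizontal,n_vertical element counts (defaults 15 and 23).
#' @param element_pitch_mm center-to-center pitch (default 2 mm).
#' @param central_frequency_mhz transducer center frequency (default 1 MHz).
#' @param fractional_bandwidth -6 dB fractional bandwidth (default 0.7).
#' @param sampling_rate_mhz temporal sampling rate (default 20 MHz; must
#'   exceed twice the central frequency).
#' @param speed_of_sound speed of sound, mm/us (default 1.54, soft tissue).
#' @param scan_positions_mm numeric vector of lateral x offsets (default 0).
#' @param center_mm (x, y) position of the array center at scan offset 0.
#' @param max_depth_mm field-of-view depth limit of the hardware (default 50).
#' @param aperture_n sub-element samples per axis for finite-aperture
#'   integration; 1 (default) means point elements.
#' @return a `detector_array` list; `n_elements` gives the per-scan count.
#' @export
detector_array <- function(n_horizontal = 15, n_vertical = 23,
                           element_pitch_mm = 2, central_frequency_mhz = 1,
                           fractional_bandwidth = 0.7, sampling_rate_mhz = 20,
                           speed_of_sound = 1.54, scan_positions_mm = 0,
                           center_mm = NULL, max_depth_mm = 50, aperture_n = 1L) {
  stopifnot(n_horizontal >= 1, n_vertical >= 1)
  assert_scalar_pos(element_pitch_mm, "element_pitch_mm")
  assert_scalar_pos(central_frequency_mhz, "central_frequency_mhz")
  assert_scalar_pos(sampling_rate_mhz, "sampling_rate_mhz")
  assert_scalar_pos(speed_of_sound, "speed_of_sound")
  if (sampling_rate_mhz <= 2 * central_frequency_mhz) {
    stop("sampling_rate_mhz must exceed twice the central frequency (Nyquist)", call. = FALSE)
  }
  if (is.null(center_mm)) {
    center_mm <- c(n_horizontal, n_vertical) * element_pitch_mm / 2
  }
  structure(list(n_horizontal = as.integer(n_horizontal),
                 n_vertical = as.integer(n_vertical),
                 n_elements = as.integer(n_horizontal) * as.integer(n_vertical),
                 element_pitch_mm = element_pitch_mm,
                 central_frequency_mhz = central_frequency_mhz,
                 fractional_bandwidth = fractional_bandwidth,
                 sampling_rate_mhz = sampling_rate_mhz,
                 speed_of_sound = speed_of_sound,
                 scan_positions_mm = as.numeric(scan_positions_mm),
                 center_mm = as.numeric(center_mm),
                 max_depth_mm = max_depth_mm,
                 aperture_n = as.integer(aperture_n)),
            class = "detector_array")
}

#' Element center positions across all scan offsets
#'
#' @param array a [detector_array()].
#' @return matrix with columns x, y, z (mm); one row per element per scan
#'   position, elements varying fastest horizontally.
#' @export
element_positions <- function(array) {
  stopifnot(inherits(array, "detector_array"))
  px <- (seq_len(array$n_horizontal) - (array$n_horizontal + 1) / 2) * array$element_pitch_mm
  py <- (seq_len(array$n_vertical) - (array$n_vertical + 1) / 2) * array$element_pitch_mm
  base <- cbind(x = rep(px, times = array$n_vertical) + array$center_mm[1],
                y = rep(py, each = array$n_horizontal) + array$center_mm[2],
                z = 0)
  do.call(rbind, lapply(array$scan_positions_mm, function(off) {
    m <- base; m[, "x"] <- m[, "x"] + off; m
  }))
}

#' Per-wavelength detector sinogram
#'
#' @param data numeric matrix, elements x time samples.
#' @param time_us strictly increasing, uniformly spaced time axis (us).
#' @param array the [detector_array()] that recorded it.
#' @param wavelength_nm wavelength tag.
#' @return a `sinogram` object.
#' @export
sinogram <- function(data, time_us, array, wavelength_nm = NA_real_) {
  stopifnot(is.matrix(data), inherits(array, "detector_array"))
  n_total <- array$n_elements * length(array$scan_positions_mm)
  if (nrow(data) != n_total) {
    stop(sprintf("sinogram has %d rows but the array defines %d element positions",
                 nrow(data), n_total), call. = FALSE)
  }
  if (ncol(data) != length(time_us)) stop("time axis length must match data columns", call. = FALSE)
  dt <- diff(time_us)
  if (length(dt) > 0 && (any(dt <= 0) || diff(range(dt)) > 1e-9 * mean(dt))) {
    stop("time_us must be strictly increasing with uniform step", call. = FALSE)
  }
  structure(list(data = data, time_us = as.numeric(time_us), array = array,
                 wavelength_nm = wavelength_nm),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d elements x %d samples, dt = %.4g us [%s]\n",
              nrow(x$data), ncol(x$data),
              if (ncol(x$data) > 1) x$time_us[2] - x$time_us[1] else NA,
              if (is.na(x$wavelength_nm)) "no wavelength" else paste0(x$wavelength_nm, " nm")))
  invisible(x)
}

# Gaussian band-pass mimicking the transducer's frequency response
bandpass_trace_matrix <- function(data, dt_us, f0_mhz, frac_bw) {
  n <- ncol(data)
  freq <- (seq_len(n) - 1) / (n * dt_us)        # MHz, unwrapped
  freq <- pmin(freq, 1 / dt_us - freq)          # two-sided magnitude
  sigma <- f0_mhz * frac_bw / 2.355             # -6 dB width -> gaussian sd
  H <- exp(-(freq - f0_mhz)^2 / (2 * sigma^2))
  t(apply(data, 1, function(tr) Re(stats::fft(stats::fft(tr) * H, inverse = TRUE)) / n))
}

#' Simulate a detector sinogram from an initial-pressure volume
#'
#' Each nonzero voxel radiates the analytic N-shaped pulse of a uniform
#' sphere of equivalent volume: at distance d from a source voxel with
#' pressure P0, p(t) = P0 (d - c t) / (2 d) for |d - c t| <= a, where a is
#' the voxel's equivalent-sphere radius. Element traces are the retarded-time
#' superposition over all source voxels (linear in P0), optionally band-passed
#' by a Gaussian response at the array's central frequency, with optional
#' seeded additive Gaussian noise.
#'
#' @param p0 initial-pressure [pam_volume].
#' @param array a [detector_array()].
#' @param seed integer seed for the noise stream.
#' @param noise_sd additive Gaussian noise SD (model pressure units; 0 = none).
#' @param bandlimit apply the transducer band-pass (default FALSE, keeping the
#'   trace analytic for validation).
#' @param time_window_us optional c(t0, t1); must contain the farthest source,
#'   otherwise an error states the required window.
#' @param supersample integer source-subdivision factor per axis (default 1).
#'   Each source voxel is split into `supersample`^3 sub-spheres, so the
#'   simulated field converges to the exact solution for extended uniform
#'   sources; 1 keeps the per-voxel analytic oracle exact.
#' @return a [sinogram()].
#' @export
simulate_sinogram <- function(p0, array, seed = 1L, noise_sd = 0,
                              bandlimit = FALSE, time_window_us = NULL,
                              supersample = 1L) {
  stopifnot(inherits(p0, "pam_volume"), inherits(array, "detector_array"))
  supersample <- as.integer(supersample)
  stopifnot(supersample >= 1L)
  c_mmus <- array$speed_of_sound
  dt <- 1 / array$sampling_rate_mhz
  pos <- element_positions(array)
  n_el <- nrow(pos)

  src <- which(p0$data != 0)
  pitch <- p0$pitch_mm / supersample
  a_mm <- pitch * (3 / (4 * pi))^(1 / 3)  # equivalent-volume sphere radius
  if (length(src) > 0) {
    ijk <- arrayInd(src, dim(p0$data))
    sx <- p0$origin[1] + (ijk[, 1] - 0.5) * p0$pitch_mm
    sy <- p0$origin[2] + (ijk[, 2] - 0.5) * p0$pitch_mm
    sz <- p0$origin[3] + (ijk[, 3] - 0.5) * p0$pitch_mm
    amp <- p0$data[src]
    if (supersample > 1L) {
      sub <- (seq_len(supersample) - (supersample + 1) / 2) * pitch
      grid <- expand.grid(dx = sub, dy = sub, dz = sub)
      ns <- nrow(grid)
      sx <- rep(sx, each = ns) + rep(grid$dx, times = length(src))
      sy <- rep(sy, each = ns) + rep(grid$dy, times = length(src))
      sz <- rep(sz, each = ns) + rep(grid$dz, times = length(src))
      amp <- rep(amp, each = ns)
    }
    radii <- rep(a_mm, length(sx))
  } else {
    sx <- sy <- sz <- amp <- radii <- numeric(0)
  }
  data <- npulse_sinogram_data(sx, sy, sz, radii, amp, pos, array, time_window_us)
  finish_sinogram(data$traces, data$time_us, array, p0$wavelength_nm,
                  seed, noise_sd, bandlimit)
}

#' Simulate a sinogram from analytic uniform spherical absorbers
#'
#' Exact forward model for a set of uniform spheres: each sphere of radius R
#' and initial pressure P0 contributes the closed-form N-shaped pulse
#' p(t) = P0 (d - c t) / (2 d) for |d - c t| <= R at distance d. This is the
#' classical analytic validation source for back-projection reconstruction —
#' unlike a voxelized source, the traces carry no rasterization granularity,
#' so reconstruction error isolates the algorithm itself.
#'
#' @param spheres data.frame with columns `x`, `y`, `z` (mm), `radius_mm` and
#'   `p0` (one row per sphere).
#' @inheritParams simulate_sinogram
#' @param wavelength_nm wavelength tag for the sinogram.
#' @return a [sinogram()].
#' @export
simulate_sphere_sinogram <- function(spheres, array, seed = 1L, noise_sd = 0,
                                     bandlimit = FALSE, time_window_us = NULL,
                                     wavelength_nm = NA_real_) {
  stopifnot(inherits(array, "detector_array"),
            all(c("x", "y", "z", "radius_mm", "p0") %in% names(spheres)))
  pos <- element_positions(array)
  data <- npulse_sinogram_data(spheres$x, spheres$y, spheres$z,
                               spheres$radius_mm, spheres$p0, pos, array,
                               time_window_us)
  finish_sinogram(data$traces, data$time_us, array, wavelength_nm,
                  seed, noise_sd, bandlimit)
}

#' Analytic sphere sources of a phantom at one wavelength
#'
#' Converts every spherical structure of a phantom into an analytic source
#' row (center, radius, uniform P0 = Grueneisen * mua(center) * Phi(center
#' depth)) for [simulate_sphere_sinogram()]. Requires all structures to be
#' spheres.
#'
#' @param phantom an `optical_phantom`.
#' @param illum an [illumination_config()].
#' @param wavelength_nm wavelength in nm.
#' @param eps an [extinction_table].
#' @return data.frame with columns x, y, z, radius_mm, p0.
#' @export
sphere_sources_from_phantom <- function(phantom, illum, wavelength_nm,
                                        eps = default_extinction()) {
  kinds <- vapply(phantom$structures, `[[`, "", "kind")
  if (any(kinds != "lesion_sphere")) {
    stop("analytic sphere sources require all structures to be spheres", call. = FALSE)
  }
  idx <- match(wavelength_nm, eps$wavelengths_nm)
  if (is.na(idx)) stop("wavelength not in extinction table", call. = FALSE)
  phi <- fluence_map(phantom, illum, wavelength_nm)
  bg <- phantom$background_mua[[as.character(wavelength_nm)]]
  if (is.null(bg)) bg <- 0
  rows <- lapply(phantom$structures, function(s) {
    thc <- s$total_hemoglobin
    mua <- eps$eps_hbo2[idx] * s$so2_true * thc +
      eps$eps_hb[idx] * (1 - s$so2_true) * thc + bg
    zi <- min(max(1L, round(s$center_mm[3] / phantom$voxel_pitch_mm + 0.5)),
              phantom$grid_shape[3])
    data.frame(x = s$center_mm[1], y = s$center_mm[2], z = s$center_mm[3],
               radius_mm = s$radius_mm,
               p0 = phantom$grueneisen * mua * phi$data[1, 1, zi])
  })
  do.call(rbind, rows)
}

# shared N-pulse accumulation over (source, element) pairs
npulse_sinogram_data <- function(sx, sy, sz, radii, amp, pos, array,
                                 time_window_us) {
  c_mmus <- array$speed_of_sound
  dt <- 1 / array$sampling_rate_mhz
  n_el <- nrow(pos)
  if (length(sx) > 0) {
    dmax <- 0
    for (e in seq_len(n_el)) {
      d <- sqrt((sx - pos[e, 1])^2 + (sy - pos[e, 2])^2 + (sz - pos[e, 3])^2)
      dmax <- max(dmax, max(d + radii))
    }
  } else dmax <- 0
  t_need <- (dmax + max(radii, 0)) / c_mmus
  if (is.null(time_window_us)) {
    time_window_us <- c(0, t_need + 5 * dt)
  } else if (time_window_us[2] < t_need) {
    stop(sprintf("time window ends at %.3f us but the farthest source needs %.3f us",
                 time_window_us[2], t_need), call. = FALSE)
  }
  time_us <- seq(time_window_us[1], time_window_us[2], by = dt)
  nt <- length(time_us)
  if (nt < 3) stop("time window too short: fewer than 3 samples", call. = FALSE)
  traces <- matrix(0, nrow = n_el, ncol = nt)
  if (length(sx) > 0) {
    for (e in seq_len(n_el)) {
      d <- sqrt((sx - pos[e, 1])^2 + (sy - pos[e, 2])^2 + (sz - pos[e, 3])^2)
      d <- pmax(d, 1e-9)
      tr <- numeric(nt)
      i_lo <- pmax(1L, ceiling(((d - radii) / c_mmus - time_us[1]) / dt) + 1L)
      i_hi <- pmin(nt, floor(((d + radii) / c_mmus - time_us[1]) / dt) + 1L)
      for (v in seq_along(d)) {
        if (i_hi[v] < i_lo[v]) next
        idx <- i_lo[v]:i_hi[v]
        tv <- time_us[idx]
        tr[idx] <- tr[idx] + amp[v] * (d[v] - c_mmus * tv) / (2 * d[v])
      }
      traces[e, ] <- tr
    }
  }
  list(traces = traces, time_us = time_us)
}

finish_sinogram <- function(data, time_us, array, wavelength_nm, seed,
                            noise_sd, bandlimit) {
  if (bandlimit) {
    data <- bandpass_trace_matrix(data, time_us[2] - time_us[1],
                                  array$central_frequency_mhz,
                                  array$fractional_bandwidth)
  }
  if (noise_sd > 0) {
    data <- data + with_seed(seed, matrix(stats::rnorm(length(data), sd = noise_sd),
                                          nrow(data), ncol(data)))
  }
  sinogram(data, time_us, array, wavelength_nm = wavelength_nm)
}
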