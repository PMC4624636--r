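#' Universal back projection filter term
#'
#' Computes b(t) = 2 p(t) - 2 t dp/dt per element trace, the quantity that
#' universal back projection (UBP) integrates over the detection aperture.
#' The time derivative uses central differences, one-sided at the trace ends.
#'
#' @param sino a [sinogram()].
#' @return a sinogram-shaped object whose `data` holds b(t).
#' @export
backprojection_term <- function(sino) {
  stopifnot(inherits(sino, "sinogram"))
  nt <- ncol(sino$data)
  if (nt < 3) stop("backprojection term needs at least 3 time samples", call. = FALSE)
  t_us <- sino$time_us
  dt <- t_us[2] - t_us[1]
  p <- sino$data
  dp <- matrix(0, nrow(p), nt)
  dp[, 2:(nt - 1)] <- (p[, 3:nt] - p[, 1:(nt - 2)]) / (2 * dt)
  dp[, 1] <- (p[, 2] - p[, 1]) / dt
  dp[, nt] <- (p[, nt] - p[, nt - 1]) / dt
  b <- 2 * p - 2 * sweep(dp, 2, t_us, "*")
  out <- sino
  out$data <- b
  out$kind <- "ubp_term"
  out
}

#' Reconstruction grid specification
#'
#' @param extent_mm length-3 physical extent (mm) per axis.
#' @param voxel_pitch_mm voxel pitch, default 0.25 mm.
#' @param origin_mm low corner of the grid (mm), default the coordinate origin.
#' @return a `recon_grid` list with the derived voxel counts.
#' @export
recon_grid <- function(extent_mm, voxel_pitch_mm = 0.25, origin_mm = c(0, 0, 0)) {
  stopifnot(length(extent_mm) == 3, all(extent_mm > 0))
  assert_scalar_pos(voxel_pitch_mm, "voxel_pitch_mm")
  structure(list(extent_mm = as.numeric(extent_mm),
                 voxel_pitch_mm = voxel_pitch_mm,
                 origin_mm = as.numeric(origin_mm),
                 shape = as.integer(round(extent_mm / voxel_pitch_mm))),
            class = "recon_grid")
}

#' Grid matching an existing volume
#' @param vol a [pam_volume].
#' @rdname recon_grid
#' @export
recon_grid_like <- function(vol) {
  stopifnot(inherits(vol, "pam_volume"))
  recon_grid(dim(vol$data) * vol$pitch_mm, vol$pitch_mm, vol$origin)
}

#' Universal back projection reconstruction
#'
#' Back-projects b(t) = 2p - 2t dp/dt along spherical shells: every voxel r
#' accumulates, over all element positions r0, the filter term evaluated at
#' the retarded time t = |r - r0| / c, weighted by the planar-detector solid
#' angle d_Omega ~ cos(theta) / d^2 = z / d^3 (z the voxel's height above the
#' detector plane). With `normalize = TRUE` each voxel is divided by its
#' summed weight, flattening aperture sensitivity so that an ideal spherical
#' source reconstructs its true P0 at its center. Retarded times falling
#' outside the recorded window are skipped and counted; a warning is raised
#' when the skipped fraction exceeds `skip_warn_fraction`. Linear in the
#' sinogram. Values at interpolation are linear in time.
#'
#' @param sino a [sinogram()].
#' @param grid a [recon_grid()].
#' @param normalize divide by summed solid-angle weights (default TRUE).
#' @param skip_warn_fraction warning threshold on the skipped-contribution
#'   fraction (default 0.05).
#' @return a [pam_volume] of reconstructed P0 with a `skip_fraction` attribute.
#' @export
ubp_reconstruct <- function(sino, grid, normalize = TRUE, skip_warn_fraction = 0.05) {
  stopifnot(inherits(sino, "sinogram"), inherits(grid, "recon_grid"))
  bterm <- backprojection_term(sino)
  b <- bterm$data
  t_us <- sino$time_us
  dt <- t_us[2] - t_us[1]
  nt <- length(t_us)
  c_mmus <- sino$array$speed_of_sound
  pos <- element_positions(sino$array)

  n <- grid$shape
  p <- grid$voxel_pitch_mm
  vx <- grid$origin_mm[1] + (seq_len(n[1]) - 0.5) * p
  vy <- grid$origin_mm[2] + (seq_len(n[2]) - 0.5) * p
  vz <- grid$origin_mm[3] + (seq_len(n[3]) - 0.5) * p
  nvox <- prod(n)
  # flattened voxel coordinates, x fastest (column-major array order)
  X <- rep(vx, times = n[2] * n[3])
  Y <- rep(rep(vy, each = n[1]), times = n[3])
  Z <- rep(vz, each = n[1] * n[2])

  num <- numeric(nvox)
  den <- numeric(nvox)
  n_skip <- 0
  for (e in seq_len(nrow(pos))) {
    dx <- X - pos[e, 1]; dy <- Y - pos[e, 2]; dz <- Z - pos[e, 3]
    d2 <- dx * dx + dy * dy + dz * dz
    d <- sqrt(d2)
    w <- abs(dz) / pmax(d2 * d, 1e-12)   # planar solid-angle weight
    fi <- (d / c_mmus - t_us[1]) / dt + 1
    i0 <- floor(fi)
    ok <- i0 >= 1 & i0 < nt
    n_skip <- n_skip + sum(!ok)
    frac <- fi - i0
    i0ok <- i0[ok]
    row <- b[e, ]
    val <- row[i0ok] * (1 - frac[ok]) + row[i0ok + 1] * frac[ok]
    num[ok] <- num[ok] + w[ok] * val
    den[ok] <- den[ok] + w[ok]
  }
  skip_frac <- n_skip / (nvox * nrow(pos))
  if (skip_frac > skip_warn_fraction) {
    warning(sprintf("%.1f%% of (voxel, element) contributions fell outside the recorded time window",
                    100 * skip_frac), call. = FALSE)
  }
  rec <- if (normalize) num / pmax(den, .Machine$double.eps) else num
  vol <- pam_volume(array(rec, dim = n), p, origin = grid$origin_mm,
                    wavelength_nm = sino$wavelength_nm,
                    units = "model pressure", kind = "recon_p0")
  attr(vol, "skip_fraction") <- skip_frac
  attr(vol, "algorithm") <- list(method = "universal back projection",
                                 weights = "planar cos(theta)/d^2",
                                 normalized = normalize)
  vol
}

#' Maximum-intensity-projection slab stack
#'
#' Partitions the volume along `axis` into consecutive slabs of
#' `slab_thickness_mm` (the last slab may be thinner) and takes the per-pixel
#' maximum over each slab's voxels — the 2-mm MIP rendering used for visual
#' vessel assessment.
#'
#' @param volume a [pam_volume].
#' @param slab_thickness_mm slab thickness, mm; must be >= the voxel pitch.
#' @param axis projection axis: 1 (x), 2 (y) or 3 (z); default 3.
#' @return a `mip_stack`: list of 2-D matrices `slabs`, slab bounds (mm),
#'   `axis`, and the source pitch.
#' @export
mip_slabs <- function(volume, slab_thickness_mm = 2, axis = 3) {
  stopifnot(inherits(volume, "pam_volume"))
  if (!axis %in% 1:3) stop("axis must be 1, 2 or 3", call. = FALSE)
  p <- volume$pitch_mm
  if (slab_thickness_mm < p) {
    stop("slab_thickness_mm must be at least the voxel pitch", call. = FALSE)
  }
  n <- dim(volume$data)[axis]
  per <- max(1L, floor(slab_thickness_mm / p))
  starts <- seq(1L, n, by = per)
  slabs <- vector("list", length(starts))
  bounds <- matrix(0, length(starts), 2)
  for (s in seq_along(starts)) {
    idx <- starts[s]:min(starts[s] + per - 1L, n)
    sub <- switch(axis,
                  volume$data[idx, , , drop = FALSE],
                  volume$data[, idx, , drop = FALSE],
                  volume$data[, , idx, drop = FALSE])
    slabs[[s]] <- apply(sub, setdiff(1:3, axis), max)
    bounds[s, ] <- volume$origin[axis] + c(min(idx) - 1, max(idx)) * p
  }
  structure(list(slabs = slabs, slab_bounds_mm = bounds, axis = axis,
                 slab_thickness_mm = slab_thickness_mm, pixel_pitch_mm = p),
            class = "mip_stack")
}
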