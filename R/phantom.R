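#' Ground-truth structures for optical breast phantoms
#'
#' Three structure kinds are supported: `lesion_sphere` (a spherical tumor
#' region), `vessel_tube` (a finite cylinder, e.g. a deep vessel used as a
#' contralateral-normal stand-in) and `subcutaneous_vessel` (same geometry as
#' a tube, tagged as the shallow high-SO2 reference vasculature). Each carries
#' total hemoglobin concentration (THC, mol/L) and a true oxygen saturation
#' `so2_true` in [0,1], which together define the oxy/deoxy split:
#' C_HbO = so2 * THC, C_Hb = (1 - so2) * THC.
#'
#' @param center_mm length-3 center (mm).
#' @param radius_mm structure radius (mm).
#' @param total_hemoglobin THC inside the structure (mol/L).
#' @param so2_true true oxygen saturation fraction in [0,1].
#' @param id optional structure id (string).
#' @return a `gt_structure` list.
#' @export
lesion_sphere <- function(center_mm, radius_mm, total_hemoglobin, so2_true,
                          id = "lesion") {
  new_structure("lesion_sphere", id, center_mm = center_mm, radius_mm = radius_mm,
                total_hemoglobin = total_hemoglobin, so2_true = so2_true)
}

#' @param axis_mm length-3 direction vector of the tube axis (normalized internally).
#' @param half_length_mm half the tube length (mm).
#' @rdname lesion_sphere
#' @export
vessel_tube <- function(center_mm, axis_mm, radius_mm, half_length_mm,
                        total_hemoglobin, so2_true, id = "vessel") {
  s <- new_structure("vessel_tube", id, center_mm = center_mm, radius_mm = radius_mm,
                     total_hemoglobin = total_hemoglobin, so2_true = so2_true)
  stopifnot(length(axis_mm) == 3, sum(axis_mm^2) > 0)
  assert_scalar_pos(half_length_mm, "half_length_mm")
  s$axis_mm <- axis_mm / sqrt(sum(axis_mm^2))
  s$half_length_mm <- half_length_mm
  s
}

#' @rdname lesion_sphere
#' @export
subcutaneous_vessel <- function(center_mm, axis_mm, radius_mm, half_length_mm,
                                total_hemoglobin, so2_true, id = "subcutaneous") {
  s <- vessel_tube(center_mm, axis_mm, radius_mm, half_length_mm,
                   total_hemoglobin, so2_true, id = id)
  s$kind <- "subcutaneous_vessel"
  s
}

new_structure <- function(kind, id, center_mm, radius_mm, total_hemoglobin, so2_true) {
  stopifnot(length(center_mm) == 3)
  assert_scalar_pos(radius_mm, "radius_mm")
  assert_scalar_pos(total_hemoglobin, "total_hemoglobin")
  if (!is.numeric(so2_true) || so2_true < 0 || so2_true > 1) {
    stop("`so2_true` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(kind = kind, id = id, center_mm = as.numeric(center_mm),
                 radius_mm = radius_mm, total_hemoglobin = total_hemoglobin,
                 so2_true = so2_true),
            class = "gt_structure")
}

#' Phantom configuration
#'
#' Defines the voxel grid, background optical properties and ground-truth
#' structures of a digital breast phantom. The grid is axis-aligned: x is the
#' lateral scan direction, y vertical, z the plate-to-plate (compression)
#' axis, with the detector plane at z = 0 and illumination entering from both
#' plates. Voxel centers sit at (i - 0.5) * pitch, i = 1..n (half-open voxel
#' intervals).
#'
#' @param grid_shape integer length-3, voxels per axis (x, y, z).
#' @param voxel_pitch_mm isotropic voxel pitch, mm.
#' @param background_mua named numeric: background absorption (cm^-1) per
#'   wavelength, names are wavelengths in nm.
#' @param background_musp reduced scattering coefficient (cm^-1), shared
#'   across wavelengths.
#' @param grueneisen dimensionless Grueneisen (thermoelastic) parameter;
#'   default 0.20, the soft-tissue value at body temperature.
#' @param breast_thickness_mm plate-to-plate thickness L; defaults to the
#'   grid's z extent.
#' @param structures list of [lesion_sphere()]/[vessel_tube()] objects.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape, voxel_pitch_mm,
                         background_mua = c("756" = 0, "797" = 0),
                         background_musp = 10,
                         grueneisen = 0.20,
                         breast_thickness_mm = NULL,
                         structures = list()) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1))
  assert_scalar_pos(voxel_pitch_mm, "voxel_pitch_mm")
  assert_scalar_pos(grueneisen, "grueneisen")
  stopifnot(all(background_mua >= 0), background_musp >= 0)
  if (is.null(names(background_mua)) || any(!nzchar(names(background_mua)))) {
    stop("`background_mua` must be named by wavelength (nm)", call. = FALSE)
  }
  if (is.null(breast_thickness_mm)) breast_thickness_mm <- grid_shape[3] * voxel_pitch_mm
  assert_scalar_pos(breast_thickness_mm, "breast_thickness_mm")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_pitch_mm = voxel_pitch_mm,
                 background_mua = background_mua,
                 background_musp = background_musp,
                 grueneisen = grueneisen,
                 breast_thickness_mm = breast_thickness_mm,
                 structures = structures),
            class = "phantom_spec")
}

# voxel-membership mask of one structure on the phantom grid
structure_mask <- function(s, cx, cy, cz) {
  if (s$kind == "lesion_sphere") {
    dx <- cx - s$center_mm[1]; dy <- cy - s$center_mm[2]; dz <- cz - s$center_mm[3]
    outer3_sum(dx^2, dy^2, dz^2) <= s$radius_mm^2
  } else { # finite cylinder
    a <- s$axis_mm
    # coordinates of every voxel center relative to tube center
    X <- outer3_sum(cx - s$center_mm[1], 0 * cy, 0 * cz)
    Y <- outer3_sum(0 * cx, cy - s$center_mm[2], 0 * cz)
    Z <- outer3_sum(0 * cx, 0 * cy, cz - s$center_mm[3])
    t_ax <- X * a[1] + Y * a[2] + Z * a[3]
    r2 <- (X - t_ax * a[1])^2 + (Y - t_ax * a[2])^2 + (Z - t_ax * a[3])^2
    (abs(t_ax) <= s$half_length_mm) & (r2 <= s$radius_mm^2)
  }
}

# sum of three vectors broadcast over a 3-D grid: A[i,j,k] = x[i]+y[j]+z[k]
outer3_sum <- function(x, y, z) {
  outer(outer(x, y, "+"), z, "+")
}

# bounding check: does the structure lie inside [0, n*pitch) on every axis?
structure_inside <- function(s, extent_mm) {
  reach <- if (s$kind == "lesion_sphere") rep(s$radius_mm, 3) else {
    # cylinder bounding box: |axis|*half_length + radius*sqrt(1-axis^2) per axis
    abs(s$axis_mm) * s$half_length_mm + s$radius_mm * sqrt(pmax(0, 1 - s$axis_mm^2))
  }
  all(s$center_mm - reach >= 0) && all(s$center_mm + reach <= extent_mm)
}

#' Build an optical breast phantom
#'
#' Rasterizes the configured structures onto the voxel grid. Chromophore maps
#' are additive: each structure contributes C_HbO = so2_true * THC and
#' C_Hb = (1 - so2_true) * THC to the voxels whose centers fall inside its
#' geometry; the background contributes no hemoglobin (background absorption
#' is carried separately as `background_mua`). The build is deterministic for
#' a fixed spec and seed.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed (recorded; reserved for stochastic spec options).
#' @return an `optical_phantom` list: `c_hbo`, `c_hb` ([pam_volume]s, mol/L),
#'   the configuration fields, and the retained ground-truth `structures`.
#' @export
build_breast_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  extent <- spec$grid_shape * spec$voxel_pitch_mm
  for (s in spec$structures) {
    if (!structure_inside(s, extent)) {
      stop(sprintf("structure '%s' (%s) extends outside the phantom grid (extent %s mm)",
                   s$id, s$kind, paste(round(extent, 2), collapse = " x ")), call. = FALSE)
    }
  }
  n <- spec$grid_shape
  p <- spec$voxel_pitch_mm
  cx <- (seq_len(n[1]) - 0.5) * p
  cy <- (seq_len(n[2]) - 0.5) * p
  cz <- (seq_len(n[3]) - 0.5) * p
  c_hbo <- array(0, dim = n)
  c_hb <- array(0, dim = n)
  for (s in spec$structures) {
    m <- structure_mask(s, cx, cy, cz)
    c_hbo <- c_hbo + m * (s$so2_true * s$total_hemoglobin)
    c_hb <- c_hb + m * ((1 - s$so2_true) * s$total_hemoglobin)
  }
  structure(list(
    c_hbo = pam_volume(c_hbo, p, units = "mol/L", kind = "c_hbo"),
    c_hb = pam_volume(c_hb, p, units = "mol/L", kind = "c_hb"),
    grid_shape = n, voxel_pitch_mm = p,
    background_mua = spec$background_mua,
    background_musp = spec$background_musp,
    grueneisen = spec$grueneisen,
    breast_thickness_mm = spec$breast_thickness_mm,
    structures = spec$structures,
    seed = as.integer(seed)
  ), class = "optical_phantom")
}

#' Dual-sided illumination configuration
#'
#' @param wavelengths_nm exactly two wavelengths (default 756 and 797 nm, a
#'   deoxyhemoglobin-sensitive / near-isosbestic pair).
#' @param surface_fluence incident fluence per side, J/cm^2 (model units are
#'   arbitrary: no absolute laser energies are modeled).
#' @param mu_eff optional named numeric (per wavelength, cm^-1) overriding the
#'   effective attenuation; when `NULL` it is derived from the phantom's
#'   background optics as sqrt(3 * mua * (mua + musp)).
#' @param dual_sided illuminate from both compression plates (default TRUE).
#' @return an `illumination_config` list.
#' @export
illumination_config <- function(wavelengths_nm = c(756, 797), surface_fluence = 1,
                                mu_eff = NULL, dual_sided = TRUE) {
  if (length(wavelengths_nm) != 2) {
    stop("exactly two wavelengths are required for two-chromophore unmixing", call. = FALSE)
  }
  assert_scalar_pos(surface_fluence, "surface_fluence")
  assert_flag(dual_sided, "dual_sided")
  structure(list(wavelengths_nm = as.numeric(wavelengths_nm),
                 surface_fluence = surface_fluence,
                 mu_eff = mu_eff, dual_sided = dual_sided),
            class = "illumination_config")
}

#' Optical fluence field of a compressed breast
#'
#' One-dimensional dual-sided diffusion-regime model along the compression
#' axis z: Phi(z) = Phi0 * [exp(-mu_eff z) + exp(-mu_eff (L - z))] with
#' L the plate-to-plate thickness, so the field is symmetric about the
#' mid-plane. mu_eff defaults to sqrt(3 mua (mua + musp')) from the phantom's
#' background optics at the requested wavelength.
#'
#' @param phantom an `optical_phantom`.
#' @param illum an [illumination_config()].
#' @param wavelength_nm one of `illum$wavelengths_nm`.
#' @return a [pam_volume] of fluence (J/cm^2), strictly positive.
#' @export
fluence_map <- function(phantom, illum, wavelength_nm) {
  stopifnot(inherits(phantom, "optical_phantom"), inherits(illum, "illumination_config"))
  if (!wavelength_nm %in% illum$wavelengths_nm) {
    stop(sprintf("wavelength %g nm not configured (available: %s)",
                 wavelength_nm, paste(illum$wavelengths_nm, collapse = ", ")), call. = FALSE)
  }
  wl <- as.character(wavelength_nm)
  mu_eff <- if (!is.null(illum$mu_eff)) {
    if (is.null(illum$mu_eff[[wl]])) {
      stop(sprintf("mu_eff has no entry for %s nm", wl), call. = FALSE)
    }
    illum$mu_eff[[wl]]
  } else {
    mua <- phantom$background_mua[[wl]]
    if (is.null(mua)) {
      stop(sprintf("background_mua has no entry for %s nm", wl), call. = FALSE)
    }
    sqrt(3 * mua * (mua + phantom$background_musp))
  }
  n <- phantom$grid_shape
  p <- phantom$voxel_pitch_mm
  z_cm <- ((seq_len(n[3]) - 0.5) * p) / 10  # mm -> cm
  L_cm <- phantom$breast_thickness_mm / 10
  prof <- illum$surface_fluence * (exp(-mu_eff * z_cm) +
                                   if (illum$dual_sided) exp(-mu_eff * (L_cm - z_cm)) else 0)
  phi <- array(rep(prof, each = n[1] * n[2]), dim = n)
  pam_volume(phi, p, wavelength_nm = wavelength_nm, units = "J/cm^2", kind = "fluence")
}

#' True absorption coefficient map of a phantom
#'
#' mua(lambda) = eps_HbO2(lambda) C_HbO + eps_Hb(lambda) C_Hb + background
#' absorption at that wavelength. This is simulation ground truth, used both
#' by the forward model and as the reconstruction-free reference in tests.
#'
#' @param phantom an `optical_phantom`.
#' @param wavelength_nm wavelength in nm.
#' @param eps an [extinction_table].
#' @return a [pam_volume] of mua (cm^-1).
#' @export
true_absorption_map <- function(phantom, wavelength_nm, eps = default_extinction()) {
  idx <- match(wavelength_nm, eps$wavelengths_nm)
  if (is.na(idx)) {
    stop(sprintf("wavelength %g nm not in extinction table (available: %s)",
                 wavelength_nm, paste(eps$wavelengths_nm, collapse = ", ")), call. = FALSE)
  }
  bg <- phantom$background_mua[[as.character(wavelength_nm)]]
  if (is.null(bg)) bg <- 0
  mua <- eps$eps_hbo2[idx] * phantom$c_hbo$data + eps$eps_hb[idx] * phantom$c_hb$data + bg
  pam_volume(mua, phantom$voxel_pitch_mm, wavelength_nm = wavelength_nm,
             units = "cm^-1", kind = "mua")
}

#' Initial photoacoustic pressure map
#'
#' P0 = Grueneisen * mua * Phi, voxel-wise: the thermoelastic pressure rise
#' produced by one laser pulse at the given wavelength.
#'
#' @param phantom an `optical_phantom`.
#' @param fluence fluence [pam_volume] on the same grid (from [fluence_map()]).
#' @param wavelength_nm wavelength in nm.
#' @param eps an [extinction_table].
#' @return a [pam_volume] of P0 (model pressure units).
#' @export
initial_pressure_map <- function(phantom, fluence, wavelength_nm,
                                 eps = default_extinction()) {
  stopifnot(inherits(fluence, "pam_volume"))
  mua <- true_absorption_map(phantom, wavelength_nm, eps)
  if (!identical(dim(mua$data), dim(fluence$data))) {
    stop(sprintf("fluence grid (%s) does not match phantom grid (%s)",
                 paste(dim(fluence$data), collapse = "x"),
                 paste(dim(mua$data), collapse = "x")), call. = FALSE)
  }
  p0 <- phantom$grueneisen * mua$data * fluence$data
  pam_volume(p0, phantom$voxel_pitch_mm, wavelength_nm = wavelength_nm,
             units = "model pressure", kind = "p0")
}
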