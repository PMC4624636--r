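#' Invert the photoacoustic pressure equation for absorption
#'
#' Voxel-wise mua = P0 / (Grueneisen * Phi): the fluence-compensated
#' absorption coefficient at one wavelength. The fluence must be strictly
#' positive on the whole grid.
#'
#' @param volume reconstructed (or true) P0 [pam_volume].
#' @param fluence fluence [pam_volume] on the same grid.
#' @param grueneisen Grueneisen parameter (default 0.20).
#' @return a [pam_volume] of mua estimates (cm^-1 when P0 is in consistent
#'   model units; otherwise to scale).
#' @export
estimate_absorption <- function(volume, fluence, grueneisen = 0.20) {
  stopifnot(inherits(volume, "pam_volume"), inherits(fluence, "pam_volume"))
  assert_scalar_pos(grueneisen, "grueneisen")
  if (!identical(dim(volume$data), dim(fluence$data))) {
    stop("fluence grid does not match the volume grid", call. = FALSE)
  }
  if (any(fluence$data <= 0)) {
    stop("fluence must be strictly positive everywhere to invert P0 = G * mua * Phi",
         call. = FALSE)
  }
  mua <- volume$data / (grueneisen * fluence$data)
  pam_volume(mua, volume$pitch_mm, origin = volume$origin,
             wavelength_nm = volume$wavelength_nm, units = "cm^-1", kind = "mua_est")
}

#' Two-wavelength linear spectral unmixing
#'
#' Solves, per voxel, the 2x2 system
#' mua(l1) = eps_HbO(l1) C_HbO + eps_Hb(l1) C_Hb;
#' mua(l2) = eps_HbO(l2) C_HbO + eps_Hb(l2) C_Hb
#' by the closed-form inverse. Negative concentrations are permitted (they
#' arise from noise and fluence-model error) and counted, never clipped.
#'
#' @param mua1,mua2 absorption [pam_volume]s at the two wavelengths (same grid).
#' @param eps an [extinction_table] covering both wavelengths.
#' @return list with `c_hbo`, `c_hb` ([pam_volume]s, mol/L),
#'   `n_negative` (voxels with any negative concentration) and
#'   `condition_number` of the extinction matrix.
#' @export
unmix_chromophores <- function(mua1, mua2, eps = default_extinction()) {
  stopifnot(inherits(mua1, "pam_volume"), inherits(mua2, "pam_volume"))
  if (!identical(dim(mua1$data), dim(mua2$data))) {
    stop("the two absorption maps must share one grid", call. = FALSE)
  }
  m <- extinction_matrix(eps, c(mua1$wavelength_nm, mua2$wavelength_nm))
  dt <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  c_hbo <- (m[2, 2] * mua1$data - m[1, 2] * mua2$data) / dt
  c_hb <- (-m[2, 1] * mua1$data + m[1, 1] * mua2$data) / dt
  list(c_hbo = pam_volume(c_hbo, mua1$pitch_mm, origin = mua1$origin,
                          units = "mol/L", kind = "c_hbo_est"),
       c_hb = pam_volume(c_hb, mua1$pitch_mm, origin = mua1$origin,
                         units = "mol/L", kind = "c_hb_est"),
       n_negative = sum(c_hbo < 0 | c_hb < 0),
       condition_number = attr(m, "condition_number"))
}

#' Oxygen saturation map from chromophore concentrations
#'
#' SO2 = C_HbO / (C_HbO + C_Hb), evaluated only where total hemoglobin (THC)
#' reaches `thc_floor` — elsewhere the voxel is invalid (NA) rather than a
#' noise-driven ratio. Values outside [0, 1] are kept and counted, not
#' clipped: measured SO2 can exceed 100% when pressure or fluence estimates
#' err, and that excess is itself diagnostic.
#'
#' @param c_hbo,c_hb concentration [pam_volume]s on one grid.
#' @param thc_floor validity floor on THC (mol/L); default 5% of the maximum
#'   THC in the map.
#' @return an `so2_map`: `so2` and `thc` [pam_volume]s, logical `valid` mask,
#'   `n_valid`, `n_flagged` (valid voxels outside [0,1]) and the floor used.
#' @export
so2_from_concentrations <- function(c_hbo, c_hb, thc_floor = NULL) {
  stopifnot(inherits(c_hbo, "pam_volume"), inherits(c_hb, "pam_volume"))
  if (!identical(dim(c_hbo$data), dim(c_hb$data))) {
    stop("concentration grids must be congruent", call. = FALSE)
  }
  thc <- c_hbo$data + c_hb$data
  if (is.null(thc_floor)) thc_floor <- 0.05 * max(thc, na.rm = TRUE)
  valid <- is.finite(thc) & thc >= thc_floor & thc > 0
  so2 <- array(NA_real_, dim = dim(thc))
  so2[valid] <- c_hbo$data[valid] / thc[valid]
  structure(list(
    so2 = pam_volume(so2, c_hbo$pitch_mm, origin = c_hbo$origin,
                     units = "fraction", kind = "so2"),
    thc = pam_volume(thc, c_hbo$pitch_mm, origin = c_hbo$origin,
                     units = "mol/L", kind = "thc"),
    valid = valid,
    n_valid = sum(valid),
    n_flagged = sum(valid & (so2 < 0 | so2 > 1), na.rm = TRUE),
    thc_floor = thc_floor
  ), class = "so2_map")
}

#' Region-of-interest specification
#'
#' Boxes or spheres in physical mm coordinates. Contralateral-normal ROIs are
#' conventionally placed at the same depth (z) as the lesion ROI they mirror.
#'
#' @param kind one of "lesion", "subcutaneous_vessel", "contralateral_normal".
#' @param shape "sphere" or "box".
#' @param center_mm length-3 center.
#' @param radius_mm sphere radius (shape = "sphere").
#' @param half_size_mm length-3 box half-sizes (shape = "box").
#' @return an `roi_spec` list.
#' @export
roi_spec <- function(kind = c("lesion", "subcutaneous_vessel", "contralateral_normal"),
                     shape = c("sphere", "box"), center_mm,
                     radius_mm = NULL, half_size_mm = NULL) {
  kind <- match.arg(kind)
  shape <- match.arg(shape)
  stopifnot(length(center_mm) == 3)
  if (shape == "sphere") assert_scalar_pos(radius_mm, "radius_mm")
  if (shape == "box") stopifnot(length(half_size_mm) == 3, all(half_size_mm > 0))
  structure(list(kind = kind, shape = shape, center_mm = as.numeric(center_mm),
                 radius_mm = radius_mm, half_size_mm = half_size_mm,
                 depth_mm = center_mm[3]),
            class = "roi_spec")
}

roi_mask <- function(so2map, roi) {
  vol <- so2map$so2
  n <- dim(vol$data)
  cx <- axis_centers(vol, 1); cy <- axis_centers(vol, 2); cz <- axis_centers(vol, 3)
  if (roi$shape == "sphere") {
    outer3_sum((cx - roi$center_mm[1])^2, (cy - roi$center_mm[2])^2,
               (cz - roi$center_mm[3])^2) <= roi$radius_mm^2
  } else {
    inx <- abs(cx - roi$center_mm[1]) <= roi$half_size_mm[1]
    iny <- abs(cy - roi$center_mm[2]) <= roi$half_size_mm[2]
    inz <- abs(cz - roi$center_mm[3]) <= roi$half_size_mm[3]
    outer(outer(inx, iny, "&"), inz, "&")
  }
}

#' Summarize SO2 over a region of interest
#'
#' Median, mean and quartiles over the ROI's valid voxels only. An ROI with
#' no valid voxels returns an explicit empty result (`empty = TRUE`, all
#' statistics NA) rather than silently reporting zero.
#'
#' @param so2map an `so2_map` from [so2_from_concentrations()].
#' @param roi an [roi_spec()].
#' @return an `roi_summary` list: kind, n_voxels (geometric), n_valid,
#'   median/mean/q1/q3, n_flagged (valid voxels outside [0,1]), empty flag.
#' @export
roi_statistics <- function(so2map, roi) {
  stopifnot(inherits(so2map, "so2_map"), inherits(roi, "roi_spec"))
  m <- roi_mask(so2map, roi)
  if (!any(m)) stop("ROI does not intersect the volume grid", call. = FALSE)
  vals <- so2map$so2$data[m & so2map$valid]
  if (length(vals) == 0) {
    return(structure(list(kind = roi$kind, n_voxels = sum(m), n_valid = 0L,
                          median = NA_real_, mean = NA_real_,
                          q1 = NA_real_, q3 = NA_real_, n_flagged = 0L,
                          empty = TRUE), class = "roi_summary"))
  }
  q <- stats::quantile(vals, c(0.25, 0.5, 0.75), names = FALSE)
  structure(list(kind = roi$kind, n_voxels = sum(m), n_valid = length(vals),
                 median = q[2], mean = mean(vals), q1 = q[1], q3 = q[3],
                 n_flagged = sum(vals < 0 | vals > 1), empty = FALSE),
            class = "roi_summary")
}

#' @export
print.roi_summary <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("<roi_summary> %s: EMPTY (%d voxels, 0 valid)\n", x$kind, x$n_voxels))
  } else {
    cat(sprintf("<roi_summary> %s: median %.3f [Q1 %.3f, Q3 %.3f], mean %.3f over %d/%d valid voxels (%d outside [0,1])\n",
                x$kind, x$median, x$q1, x$q3, x$mean, x$n_valid, x$n_voxels, x$n_flagged))
  }
  invisible(x)
}
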