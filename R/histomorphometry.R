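#' HSI threshold window
#'
#' Closed intervals on hue, saturation and intensity, each on [0, 1]. The
#' hue interval may wrap around 1 (lo > hi selects [lo, 1] U [0, hi]).
#' Conversion from RGB uses the hexcone convention of [rgb_to_hsi()].
#'
#' @param h,s,i length-2 numeric intervals in [0, 1].
#' @return an `hsi_window` list.
#' @export
hsi_window <- function(h = c(0, 1), s = c(0, 1), i = c(0, 1)) {
  for (rng in list(h, s, i)) {
    stopifnot(length(rng) == 2, all(rng >= 0), all(rng <= 1))
  }
  if (s[1] > s[2] || i[1] > i[2]) {
    stop("saturation and intensity intervals must be ordered lo <= hi", call. = FALSE)
  }
  structure(list(h = as.numeric(h), s = as.numeric(s), i = as.numeric(i)),
            class = "hsi_window")
}

#' Hexcone RGB to HSI conversion
#'
#' Fixed convention so segmentation masks are bit-reproducible: hue and
#' saturation from the hexcone (HSV) model via [grDevices::rgb2hsv()], with
#' intensity taken as the hexcone value V = max(R, G, B). All channels are
#' scaled to [0, 1]; hue 0 is red.
#'
#' @param rgb numeric array (rows x cols x 3) or a 3-row channel matrix,
#'   values in [0, 1] or 8-bit [0, 255] (auto-detected).
#' @return 3-row matrix (h, s, i), one column per pixel (column-major).
#' @export
rgb_to_hsi <- function(rgb) {
  if (is.array(rgb) && length(dim(rgb)) == 3) {
    npx <- prod(dim(rgb)[1:2])
    m <- rbind(as.vector(rgb[, , 1]), as.vector(rgb[, , 2]), as.vector(rgb[, , 3]))
  } else if (is.matrix(rgb) && nrow(rgb) == 3) {
    m <- rgb
  } else stop("rgb must be an (rows x cols x 3) array or 3-row matrix", call. = FALSE)
  mx <- if (max(m) > 1) 255 else 1
  out <- grDevices::rgb2hsv(m, maxColorValue = mx)
  rownames(out) <- c("h", "s", "i")
  out
}

hue_in <- function(h, rng) {
  if (rng[1] <= rng[2]) h >= rng[1] & h <= rng[2] else h >= rng[1] | h <= rng[2]
}

hsi_in_window <- function(hsi, window) {
  hue_in(hsi["h", ], window$h) &
    hsi["s", ] >= window$s[1] & hsi["s", ] <= window$s[2] &
    hsi["i", ] >= window$i[1] & hsi["i", ] <= window$i[2]
}

#' Segment stained structures by HSI thresholding
#'
#' A pixel is positive iff its (hue, saturation, intensity) triple lies inside
#' the window — the binarization step of CD31 whole-slide analysis, where the
#' operator picks the window that captures the most stained structures.
#'
#' @param tile RGB array (rows x cols x 3), 8-bit or [0,1].
#' @param window an [hsi_window()].
#' @return logical matrix of positive pixels.
#' @export
hsi_segment <- function(tile, window) {
  stopifnot(inherits(window, "hsi_window"), length(dim(tile)) == 3)
  hsi <- rgb_to_hsi(tile)
  matrix(hsi_in_window(hsi, window), dim(tile)[1], dim(tile)[2])
}

#' Tile a whole-slide image into fixed-size squares
#'
#' Half-open tiling from the image origin; edge tiles are zero-padded to the
#' full side and carry a pad mask. Offsets are exact pixel offsets (0-based)
#' of each tile's first pixel in the source image.
#'
#' @param wsi RGB array (rows x cols x 3) or single-channel matrix.
#' @param tile_side_px tile side in pixels.
#' @return list of tiles; each element has `data`, `offset_px` (row, col,
#'   0-based), and `pad_mask` (logical matrix, TRUE where padded).
#' @export
tile_slide <- function(wsi, tile_side_px) {
  assert_scalar_pos(tile_side_px, "tile_side_px")
  tile_side_px <- as.integer(tile_side_px)
  d <- dim(wsi)
  nr <- d[1]; nc <- d[2]
  nch <- if (length(d) == 3) d[3] else 1L
  tiles <- list()
  for (r0 in seq(0L, nr - 1L, by = tile_side_px)) {
    for (c0 in seq(0L, nc - 1L, by = tile_side_px)) {
      rr <- (r0 + 1L):min(r0 + tile_side_px, nr)
      cc <- (c0 + 1L):min(c0 + tile_side_px, nc)
      pad <- matrix(TRUE, tile_side_px, tile_side_px)
      pad[seq_along(rr), seq_along(cc)] <- FALSE
      if (nch == 1L) {
        data <- matrix(0, tile_side_px, tile_side_px)
        data[seq_along(rr), seq_along(cc)] <- wsi[rr, cc]
      } else {
        data <- array(0, dim = c(tile_side_px, tile_side_px, nch))
        data[seq_along(rr), seq_along(cc), ] <- wsi[rr, cc, ]
      }
      tiles[[length(tiles) + 1]] <- list(data = data, offset_px = c(r0, c0),
                                         pad_mask = pad)
    }
  }
  tiles
}

# Per-pixel Crofton perimeter contributions (pixel units).
#
# 4-direction Cauchy-Crofton estimate: P = (pi/8) h [N0 + N90 + (N45+N135)/sqrt(2)]
# where N_theta counts foreground/background transitions along scan lines in
# direction theta (image border treated as background). Every transition is
# attributed to its foreground pixel, so block sums conserve the total
# exactly and component sums include interior hole boundaries.
perimeter_contributions <- function(mask) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  cr <- 2:(nr + 1); cc <- 2:(nc + 1)
  n_axis <- (!pad[cr, cc - 1]) + (!pad[cr, cc + 1]) +
            (!pad[cr - 1, cc]) + (!pad[cr + 1, cc])
  n_diag <- (!pad[cr - 1, cc - 1]) + (!pad[cr - 1, cc + 1]) +
            (!pad[cr + 1, cc - 1]) + (!pad[cr + 1, cc + 1])
  (pi / 8) * mask * (n_axis + n_diag / sqrt(2))
}

#' Per-object perimeters of a binary vessel mask
#'
#' Components are 8-connected; each component's perimeter is the Crofton
#' (4-direction) estimate of its boundary length, including interior lumen
#' boundaries, scaled to micrometers by the pixel pitch.
#'
#' @param mask logical matrix of positive pixels.
#' @param pixel_pitch_um pixel pitch in micrometers.
#' @return a `vessel_mask`: `labels` (integer matrix), `perimeters`
#'   (data.frame: component, n_pixels, perimeter_um), `total_um`, the mask
#'   and pitch. Empty mask gives an empty table and total 0.
#' @export
object_perimeters <- function(mask, pixel_pitch_um) {
  stopifnot(is.matrix(mask))
  assert_scalar_pos(pixel_pitch_um, "pixel_pitch_um")
  mode(mask) <- "logical"
  lab <- label_components_8(mask)
  contrib <- perimeter_contributions(mask) * pixel_pitch_um
  if (!any(mask)) {
    per <- data.frame(component = integer(), n_pixels = integer(),
                      perimeter_um = numeric())
  } else {
    idx <- which(mask)
    agg <- rowsum(contrib[idx], lab[idx])
    cnt <- rowsum(rep(1L, length(idx)), lab[idx])
    per <- data.frame(component = as.integer(rownames(agg)),
                      n_pixels = as.integer(cnt[, 1]),
                      perimeter_um = agg[, 1])
  }
  structure(list(mask = mask, labels = lab, perimeters = per,
                 total_um = sum(per$perimeter_um),
                 pixel_pitch_um = pixel_pitch_um),
            class = "vessel_mask")
}

#' Block-wise total vessel perimeter map
#'
#' Divides the mask into square blocks of `block_size_mm` (default 0.84 mm,
#' i.e. 2,000 px at 0.42 um/px, 16 blocks per 8,000-px tile) and sums each
#' pixel's Crofton perimeter contribution into the block containing that
#' pixel. Assignment is by pixel membership, so the block sums conserve the
#' whole-mask total exactly even for boundary-crossing vessels. Edge blocks
#' may be partial when the mask is not an exact multiple of the block side.
#'
#' @param mask logical matrix, or a `vessel_mask` from [object_perimeters()].
#' @param pixel_pitch_um pixel pitch, micrometers (taken from a `vessel_mask`).
#' @param block_size_mm block side in mm; must be an integer number of pixels.
#' @return a `tvp_block_map`: `tvp_um` (block-grid matrix of TVP in um),
#'   `block_size_mm`, `block_area_mm2`, `block_px`, and `pixel_pitch_um`.
#' @export
tvp_block_map <- function(mask, pixel_pitch_um = NULL, block_size_mm = 0.84) {
  if (inherits(mask, "vessel_mask")) {
    pixel_pitch_um <- mask$pixel_pitch_um
    mask <- mask$mask
  }
  stopifnot(is.matrix(mask))
  assert_scalar_pos(pixel_pitch_um, "pixel_pitch_um")
  mode(mask) <- "logical"
  block_px_real <- block_size_mm * 1000 / pixel_pitch_um
  block_px <- round(block_px_real)
  if (abs(block_px_real - block_px) > 1e-6 || block_px < 1) {
    stop(sprintf("block size %.4g mm is not a whole number of %.4g-um pixels",
                 block_size_mm, pixel_pitch_um), call. = FALSE)
  }
  contrib <- perimeter_contributions(mask) * pixel_pitch_um
  nbr <- ceiling(nrow(mask) / block_px)
  nbc <- ceiling(ncol(mask) / block_px)
  tvp <- matrix(0, nbr, nbc)
  idx <- which(contrib > 0, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    br <- (idx[, 1] - 1L) %/% block_px + 1L
    bc <- (idx[, 2] - 1L) %/% block_px + 1L
    flat <- br + (bc - 1L) * nbr
    agg <- rowsum(contrib[idx], flat)
    tvp[as.integer(rownames(agg))] <- agg[, 1]
  }
  structure(list(tvp_um = tvp, block_size_mm = block_size_mm,
                 block_area_mm2 = block_size_mm^2, block_px = block_px,
                 pixel_pitch_um = pixel_pitch_um,
                 mask_dim = dim(mask)),
            class = "tvp_block_map")
}

#' Select the blocks overlapping a lesion
#'
#' A block is selected when the fraction of its pixels covered by the lesion
#' mask is at least `min_overlap` — the digital analog of marking lesional
#' blocks against the HE slide.
#'
#' @param blockmap a [tvp_block_map()].
#' @param lesion_mask logical matrix congruent with the segmented slide.
#' @param min_overlap required lesion cover fraction per block (default 0.5).
#' @return integer matrix (n x 2) of selected block (row, col) indices.
#' @export
select_lesion_blocks <- function(blockmap, lesion_mask, min_overlap = 0.5) {
  stopifnot(inherits(blockmap, "tvp_block_map"), is.matrix(lesion_mask))
  if (!identical(dim(lesion_mask), as.integer(blockmap$mask_dim))) {
    stop("lesion mask must be congruent with the segmented slide grid", call. = FALSE)
  }
  bp <- blockmap$block_px
  nbr <- nrow(blockmap$tvp_um); nbc <- ncol(blockmap$tvp_um)
  sel <- matrix(FALSE, nbr, nbc)
  for (i in seq_len(nbr)) {
    rr <- ((i - 1L) * bp + 1L):min(i * bp, nrow(lesion_mask))
    for (j in seq_len(nbc)) {
      cc <- ((j - 1L) * bp + 1L):min(j * bp, ncol(lesion_mask))
      sel[i, j] <- mean(lesion_mask[rr, cc]) >= min_overlap
    }
  }
  which(sel, arr.ind = TRUE)
}

#' Lesional TVP per unit area
#'
#' Sums the TVP of the selected blocks and divides by the lesional area
#' (selected block count times the block area, 0.7056 mm^2 for 0.84-mm
#' blocks), giving the study's per-lesion angiogenesis marker in um/mm^2.
#'
#' @param blockmap a [tvp_block_map()].
#' @param selection integer (n x 2) block indices from [select_lesion_blocks()].
#' @return a `lesion_tvp_result`: selected indices, `tvp_um`, `area_mm2`,
#'   `ratio_um_per_mm2` (NA with `undefined = TRUE` for an empty selection).
#' @export
lesional_tvp_per_area <- function(blockmap, selection) {
  stopifnot(inherits(blockmap, "tvp_block_map"))
  selection <- matrix(as.integer(selection), ncol = 2)
  if (nrow(selection) > 0) {
    if (any(selection[, 1] < 1 | selection[, 1] > nrow(blockmap$tvp_um) |
            selection[, 2] < 1 | selection[, 2] > ncol(blockmap$tvp_um))) {
      stop("selection contains block indices outside the block grid", call. = FALSE)
    }
  }
  if (nrow(selection) == 0) {
    return(structure(list(selection = selection, tvp_um = 0, area_mm2 = 0,
                          ratio_um_per_mm2 = NA_real_, undefined = TRUE),
                     class = "lesion_tvp_result"))
  }
  tvp <- sum(blockmap$tvp_um[selection])
  area <- nrow(selection) * blockmap$block_area_mm2
  structure(list(selection = selection, tvp_um = tvp, area_mm2 = area,
                 ratio_um_per_mm2 = tvp / area, undefined = FALSE),
            class = "lesion_tvp_result")
}
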