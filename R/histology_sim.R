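#' Synthetic CD31 histology tile configuration
#'
#' Describes one tile of a DAB-like (brown) immunostained slide: tile size,
#' pixel pitch, the stain HSI window shared with the segmenter, and either an
#' explicit vessel list or sampling parameters for random non-overlapping
#' vessels. The defaults emulate whole-slide scans: 8,000 x 8,000 px tiles at
#' 0.42 um/px, so one 0.84-mm analysis block is exactly 2,000 px and a tile
#' holds a 4 x 4 block grid.
#'
#' @param tile_px tile side in pixels (default 8000).
#' @param pixel_pitch_um pixel pitch (default 0.42 um).
#' @param vessels explicit list of vessel descriptors, each a list with
#'   `kind` ("disk", "annulus" or "ellipse"), `center_px` (length 2),
#'   `r_px` (disk/annulus outer radius), `r_in_px` (annulus lumen radius),
#'   `a_px`,`b_px`,`theta` (ellipse semi-axes and rotation). `NULL` to sample.
#' @param n_vessels number of random vessels when `vessels` is NULL.
#' @param radius_range_px sampled outer-radius range.
#' @param lumen_prob probability a sampled vessel is an annulus.
#' @param lesion optional list(center_px, radius_px) defining a circular
#'   lesion region mask.
#' @param stain_window [hsi_window()] of the rendered stain (default a DAB
#'   brown window).
#' @param stain_rgb rendered vessel color (must fall inside `stain_window`).
#' @param background_rgb tile background color (must fall outside the window).
#' @return a `histology_spec` list.
#' @export
histology_spec <- function(tile_px = 8000, pixel_pitch_um = 0.42,
                           vessels = NULL, n_vessels = 30,
                           radius_range_px = c(25, 80), lumen_prob = 0.5,
                           lesion = NULL,
                           stain_window = hsi_window(h = c(0.02, 0.15),
                                                     s = c(0.5, 1),
                                                     i = c(0.25, 0.85)),
                           stain_rgb = c(139, 69, 19) / 255,
                           background_rgb = c(0.96, 0.87, 0.90)) {
  assert_scalar_pos(tile_px, "tile_px")
  assert_scalar_pos(pixel_pitch_um, "pixel_pitch_um")
  stopifnot(inherits(stain_window, "hsi_window"),
            length(stain_rgb) == 3, length(background_rgb) == 3)
  stain_hsi <- rgb_to_hsi(matrix(stain_rgb, 3, 1))
  bg_hsi <- rgb_to_hsi(matrix(background_rgb, 3, 1))
  if (!hsi_in_window(stain_hsi, stain_window)) {
    stop("stain_rgb does not fall inside stain_window: rendered vessels would be unsegmentable",
         call. = FALSE)
  }
  if (hsi_in_window(bg_hsi, stain_window)) {
    stop("background color lies inside the stain window: segmentation would be unresolvable",
         call. = FALSE)
  }
  structure(list(tile_px = as.integer(tile_px), pixel_pitch_um = pixel_pitch_um,
                 vessels = vessels, n_vessels = n_vessels,
                 radius_range_px = radius_range_px, lumen_prob = lumen_prob,
                 lesion = lesion, stain_window = stain_window,
                 stain_rgb = stain_rgb, background_rgb = background_rgb),
            class = "histology_spec")
}

# analytic perimeter (um) of one vessel descriptor
vessel_perimeter_um <- function(v, pitch_um) {
  switch(v$kind,
    disk = 2 * pi * v$r_px * pitch_um,
    annulus = 2 * pi * (v$r_px + v$r_in_px) * pitch_um,
    ellipse = ellipse_perimeter(v$a_px, v$b_px) * pitch_um,
    stop(sprintf("unknown vessel kind '%s'", v$kind), call. = FALSE))
}

# exact ellipse circumference by numeric quadrature of the arc-length integral
ellipse_perimeter <- function(a, b) {
  4 * stats::integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                       0, pi / 2, rel.tol = 1e-10)$value
}

vessel_bbox_radius <- function(v) {
  switch(v$kind,
    disk = v$r_px, annulus = v$r_px,
    ellipse = max(v$a_px, v$b_px))
}

vessel_pixel_mask <- function(v, X, Y) {
  dx <- X - v$center_px[1]; dy <- Y - v$center_px[2]
  switch(v$kind,
    disk = dx^2 + dy^2 <= v$r_px^2,
    annulus = {
      r2 <- dx^2 + dy^2
      r2 <= v$r_px^2 & r2 >= v$r_in_px^2
    },
    ellipse = {
      u <- dx * cos(v$theta) + dy * sin(v$theta)
      w <- -dx * sin(v$theta) + dy * cos(v$theta)
      (u / v$a_px)^2 + (w / v$b_px)^2 <= 1
    })
}

#' Generate a synthetic CD31-stained histology tile
#'
#' Renders non-overlapping vessel cross-sections (filled disks, annuli with
#' lumina, rotated ellipses) in the stain color on a uniform background, and
#' records each object's analytic perimeter — outer plus lumen circumference
#' for annuli — as ground truth. Sampled layouts are placed by seeded
#' rejection sampling with a separation margin so rendered components map
#' one-to-one onto truth objects.
#'
#' @param spec a [histology_spec()].
#' @param seed integer seed for sampled layouts.
#' @return a `histology_phantom`: `rgb` (tile_px x tile_px x 3, values in
#'   [0,1]), `pixel_pitch_um`, `vessel_truth` (data.frame: id, kind,
#'   perimeter_um, lumen), `lesion_mask` (logical matrix or NULL),
#'   `stain_window`, and the placed `vessels`.
#' @export
generate_histology <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "histology_spec"))
  n <- spec$tile_px
  vessels <- spec$vessels
  if (is.null(vessels)) {
    vessels <- with_seed(seed, sample_vessel_layout(spec))
  }
  for (v in vessels) {
    r <- vessel_bbox_radius(v)
    if (any(v$center_px - r < 1) || any(v$center_px + r > n)) {
      stop(sprintf("vessel at (%g, %g) extends outside the %d-px tile",
                   v$center_px[1], v$center_px[2], n), call. = FALSE)
    }
  }
  rgb <- array(rep(spec$background_rgb, each = n * n), dim = c(n, n, 3))
  for (v in vessels) {
    r <- ceiling(vessel_bbox_radius(v)) + 1L
    rr <- max(1L, floor(v$center_px[1] - r)):min(n, ceiling(v$center_px[1] + r))
    cc <- max(1L, floor(v$center_px[2] - r)):min(n, ceiling(v$center_px[2] + r))
    X <- matrix(rr, length(rr), length(cc))
    Y <- matrix(cc, length(rr), length(cc), byrow = TRUE)
    m <- vessel_pixel_mask(v, X, Y)
    for (ch in 1:3) {
      sub <- rgb[rr, cc, ch]
      sub[m] <- spec$stain_rgb[ch]
      rgb[rr, cc, ch] <- sub
    }
  }
  truth <- if (length(vessels) > 0) {
    data.frame(id = seq_along(vessels),
               kind = vapply(vessels, `[[`, "", "kind"),
               perimeter_um = vapply(vessels, vessel_perimeter_um, 0,
                                     pitch_um = spec$pixel_pitch_um),
               lumen = vapply(vessels, function(v) v$kind == "annulus", TRUE))
  } else {
    data.frame(id = integer(), kind = character(), perimeter_um = numeric(),
               lumen = logical())
  }
  lesion_mask <- NULL
  if (!is.null(spec$lesion)) {
    X <- matrix(seq_len(n), n, n)
    Y <- t(X)
    lesion_mask <- (X - spec$lesion$center_px[1])^2 +
      (Y - spec$lesion$center_px[2])^2 <= spec$lesion$radius_px^2
  }
  structure(list(rgb = rgb, pixel_pitch_um = spec$pixel_pitch_um,
                 vessel_truth = truth, lesion_mask = lesion_mask,
                 stain_window = spec$stain_window, vessels = vessels,
                 seed = as.integer(seed)),
            class = "histology_phantom")
}

# rejection-sample non-overlapping vessel descriptors (RNG already seeded)
sample_vessel_layout <- function(spec) {
  n <- spec$tile_px
  placed <- list()
  centers <- matrix(0, 0, 2)
  radii <- numeric(0)
  tries <- 0
  while (length(placed) < spec$n_vessels && tries < 200 * spec$n_vessels) {
    tries <- tries + 1
    r <- stats::runif(1, spec$radius_range_px[1], spec$radius_range_px[2])
    margin <- r + 3
    ctr <- stats::runif(2, margin + 1, n - margin - 1)
    if (nrow(centers) > 0 &&
        any(sqrt((centers[, 1] - ctr[1])^2 + (centers[, 2] - ctr[2])^2) <
            radii + r + 4)) next
    v <- if (stats::runif(1) < spec$lumen_prob) {
      list(kind = "annulus", center_px = ctr, r_px = r,
           r_in_px = r * stats::runif(1, 0.35, 0.6))
    } else {
      list(kind = "disk", center_px = ctr, r_px = r)
    }
    placed[[length(placed) + 1]] <- v
    centers <- rbind(centers, ctr)
    radii <- c(radii, r)
  }
  if (length(placed) < spec$n_vessels) {
    stop("could not place the requested vessels without overlap; reduce n_vessels or radii",
         call. = FALSE)
  }
  placed
}
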