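# Portable binary container: little-endian float64 .bin plus a JSON sidecar
# describing shape, pitch, units and wavelength.

#' Write / read a gridded volume
#'
#' @param vol a [pam_volume].
#' @param prefix file path without extension; writes `<prefix>.bin` and
#'   `<prefix>.json`.
#' @return `write_pam_volume` returns the two paths invisibly;
#'   `read_pam_volume` returns the volume.
#' @export
write_pam_volume <- function(vol, prefix) {
  stopifnot(inherits(vol, "pam_volume"))
  bin <- paste0(prefix, ".bin"); side <- paste0(prefix, ".json")
  con <- file(bin, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.numeric(vol$data), con, size = 8, endian = "little")
  meta <- list(container = "pamoxi_volume", shape = dim(vol$data),
               pitch_mm = vol$pitch_mm, origin_mm = vol$origin,
               wavelength_nm = vol$wavelength_nm, units = vol$units,
               kind = vol$kind, dtype = "float64_le")
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(c(bin, side))
}

#' @rdname write_pam_volume
#' @export
read_pam_volume <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  n <- prod(meta$shape)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con), add = TRUE)
  vals <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  pam_volume(array(vals, dim = meta$shape), meta$pitch_mm, meta$origin_mm,
             wavelength_nm = if (is.null(meta$wavelength_nm)) NA_real_ else meta$wavelength_nm,
             units = meta$units, kind = meta$kind)
}

#' Write / read a sinogram in the binary + sidecar container
#'
#' @param sino a [sinogram()].
#' @param prefix path prefix (no extension).
#' @return paths invisibly / the sinogram.
#' @export
write_sinogram <- function(sino, prefix) {
  stopifnot(inherits(sino, "sinogram"))
  bin <- paste0(prefix, ".bin"); side <- paste0(prefix, ".json")
  con <- file(bin, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.numeric(sino$data), con, size = 8, endian = "little")
  meta <- list(container = "pamoxi_sinogram", shape = dim(sino$data),
               time_us = sino$time_us, wavelength_nm = sino$wavelength_nm,
               array = sino$array[setdiff(names(sino$array), "n_elements")],
               dtype = "float64_le")
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(c(bin, side))
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con), add = TRUE)
  vals <- readBin(con, "numeric", n = prod(meta$shape), size = 8, endian = "little")
  arr <- do.call(detector_array, meta$array)
  sinogram(matrix(vals, meta$shape[1], meta$shape[2]), meta$time_us, arr,
           wavelength_nm = meta$wavelength_nm)
}

#' Export MIP slabs as a multi-page TIFF
#'
#' Slabs are min-max normalized jointly and written as 8-bit grayscale pages.
#' Requires the optional `tiff` package.
#'
#' @param mip a `mip_stack`.
#' @param path output .tif path.
#' @return the path, invisibly.
#' @export
write_mip_tiff <- function(mip, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to write TIFF output", call. = FALSE)
  }
  rng <- range(unlist(lapply(mip$slabs, range)))
  scale <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(mip$slabs, function(s) (s - rng[1]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}
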