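# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG to `seed`, evaluates `expr`, and restores the caller's RNG
#' state on exit, so generators are bit-reproducible without clobbering the
#' global random stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# scalar type checks used by constructors
assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name), call. = FALSE)
  }
  invisible(x)
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1 || is.na(x)) {
    stop(sprintf("`%s` must be TRUE or FALSE", name), call. = FALSE)
  }
  invisible(x)
}

#' Lightweight gridded-volume container
#'
#' A 3-D numeric array plus its voxel pitch (mm), physical origin (mm, the
#' low corner of voxel \code{[1,1,1]}) and bookkeeping fields. Voxel centers
#' are at \code{origin + (i - 0.5) * pitch} along each axis (0-based voxel
#' \code{i-1} owning the half-open interval \code{[(i-1)p, ip)}). Used for
#' chromophore maps, fluence, initial pressure, reconstructions and SO2 maps.
#'
#' @param data 3-D numeric array.
#' @param pitch_mm voxel pitch in mm (isotropic).
#' @param origin length-3 numeric, mm.
#' @param wavelength_nm optional wavelength tag.
#' @param units free-text unit string.
#' @param kind free-text content tag (e.g. "p0", "fluence", "mua").
#' @return an object of class `pam_volume`.
#' @export
pam_volume <- function(data, pitch_mm, origin = c(0, 0, 0),
                       wavelength_nm = NA_real_, units = "", kind = "") {
  stopifnot(is.array(data), length(dim(data)) == 3)
  assert_scalar_pos(pitch_mm, "pitch_mm")
  stopifnot(length(origin) == 3, is.numeric(origin))
  structure(list(data = data, pitch_mm = pitch_mm, origin = as.numeric(origin),
                 wavelength_nm = wavelength_nm, units = units, kind = kind),
            class = "pam_volume")
}

#' @export
print.pam_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<pam_volume> %s  %dx%dx%d voxels @ %.3g mm  [%s]\n",
              x$kind, d[1], d[2], d[3], x$pitch_mm,
              if (is.na(x$wavelength_nm)) "no wavelength" else paste0(x$wavelength_nm, " nm")))
  invisible(x)
}

#' Voxel-center coordinates of a volume along one axis (mm)
#' @keywords internal
axis_centers <- function(vol, axis) {
  n <- dim(vol$data)[axis]
  vol$origin[axis] + (seq_len(n) - 0.5) * vol$pitch_mm
}

# stable hash of an R config object: canonical JSON (recursively sorted keys)
# hashed with md5. Stable under key reordering.
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x) && !is.null(names(x)) && length(x) > 0) {
      x <- x[order(names(x))]
      lapply(x, canon)
    } else if (is.list(x)) {
      lapply(x, canon)
    } else x
  }
  js <- jsonlite::toJSON(canon(config), auto_unbox = TRUE, digits = NA, null = "null")
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}
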