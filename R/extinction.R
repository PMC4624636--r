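#' Hemoglobin molar extinction table
#'
#' Holds epsilon_HbO2 and epsilon_Hb (L mol^-1 cm^-1) per wavelength and, for
#' a chosen wavelength pair, the 2x2 unmixing matrix. The shipped default is
#' an approximate standard compiled tabulation of adult hemoglobin in the
#' near-infrared; it is a convenience only — analyses that matter should pass
#' their own calibrated values, and every computation here takes the table
#' explicitly.
#'
#' @param wavelengths_nm numeric vector of wavelengths.
#' @param eps_hbo2,eps_hb numeric vectors, same length, L mol^-1 cm^-1.
#' @return object of class `extinction_table`.
#' @examples
#' eps <- extinction_table(c(756, 797), eps_hbo2 = c(620, 766), eps_hb = c(1590, 761))
#' extinction_matrix(eps, c(756, 797))
#' @export
extinction_table <- function(wavelengths_nm, eps_hbo2, eps_hb) {
  stopifnot(length(wavelengths_nm) == length(eps_hbo2),
            length(wavelengths_nm) == length(eps_hb),
            all(eps_hbo2 > 0), all(eps_hb > 0))
  structure(list(wavelengths_nm = as.numeric(wavelengths_nm),
                 eps_hbo2 = as.numeric(eps_hbo2),
                 eps_hb = as.numeric(eps_hb)),
            class = "extinction_table")
}

#' Default near-infrared hemoglobin extinction values
#'
#' Approximate compiled values at the two operating wavelengths. 797 nm is
#' close to the Hb/HbO2 isosbestic point, so absorption there tracks total
#' hemoglobin; 756 nm sits on a deoxyhemoglobin absorption peak, giving the
#' pair its SO2 sensitivity.
#'
#' @return an [extinction_table].
#' @export
default_extinction <- function() {
  extinction_table(c(756, 797), eps_hbo2 = c(620, 766), eps_hb = c(1590, 761))
}

#' Extract the 2x2 extinction matrix for a wavelength pair
#'
#' Rows are wavelengths, columns are (HbO2, Hb). The matrix condition number
#' is attached as attribute `condition_number`; a (near-)singular pair is an
#' error because the two-wavelength unmixing system would be unsolvable.
#'
#' @param eps an [extinction_table].
#' @param wavelengths_nm length-2 wavelength pair present in `eps`.
#' @param max_condition condition number above which the pair is rejected.
#' @return 2x2 numeric matrix with dimnames and `condition_number` attribute.
#' @export
extinction_matrix <- function(eps, wavelengths_nm, max_condition = 1e12) {
  stopifnot(inherits(eps, "extinction_table"), length(wavelengths_nm) == 2)
  idx <- match(wavelengths_nm, eps$wavelengths_nm)
  if (anyNA(idx)) {
    stop(sprintf("wavelength(s) %s not in extinction table (available: %s)",
                 paste(wavelengths_nm[is.na(idx)], collapse = ", "),
                 paste(eps$wavelengths_nm, collapse = ", ")), call. = FALSE)
  }
  m <- cbind(hbo2 = eps$eps_hbo2[idx], hb = eps$eps_hb[idx])
  rownames(m) <- as.character(wavelengths_nm)
  kn <- kappa(m, exact = TRUE)
  if (!is.finite(kn) || kn > max_condition || abs(det(m)) < .Machine$double.xmin) {
    stop(sprintf("extinction matrix for (%s) nm is singular or ill-conditioned (condition number %.3g)",
                 paste(wavelengths_nm, collapse = ", "), kn), call. = FALSE)
  }
  attr(m, "condition_number") <- kn
  m
}
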