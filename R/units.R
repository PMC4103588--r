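# Unit conversions. All frequencies are rad/s internally; the user-facing
# boundary is ppm (shift differences), Hz (nu_cpmg, omega1/2pi) and 1/s (rates).

# |gamma_X / gamma_1H| for the supported isotopes
.gamma_ratio <- c("1H" = 1.0, "15N" = 0.10136767, "13C" = 0.25144953)

#' Gyromagnetic ratio of an isotope relative to the proton
#'
#' @param isotope One of `"1H"`, `"15N"`, `"13C"`.
#' @return The absolute ratio `|gamma_X / gamma_1H|`.
#' @export
gamma_ratio <- function(isotope) {
  if (!all(isotope %in% names(.gamma_ratio))) {
    stop("unknown isotope(s): ",
         paste(setdiff(isotope, names(.gamma_ratio)), collapse = ", "),
         "; no gyromagnetic-ratio entry", call. = FALSE)
  }
  unname(.gamma_ratio[isotope])
}

#' Convert a chemical-shift difference from ppm to angular frequency
#'
#' The shift difference is referenced to the static field, given as the proton
#' Larmor frequency in MHz, and scaled by the isotope's gyromagnetic ratio:
#' `dw[rad/s] = |dw[ppm]| * 2 * pi * field_h1_mhz * |gamma_X/gamma_1H|`.
#'
#' @param delta_ppm Shift difference in ppm (the sign is discarded; 2-site
#'   dispersion data do not determine it).
#' @param field_h1_mhz Proton Larmor frequency of the spectrometer in MHz.
#' @param isotope Isotope of the observed nucleus.
#' @return Non-negative angular frequency in rad/s.
#' @examples
#' ppm_to_rad_per_s(1, 600, "1H")   # 2*pi*600
#' ppm_to_rad_per_s(1, 600, "15N")  # approx 382.1
#' @export
ppm_to_rad_per_s <- function(delta_ppm, field_h1_mhz, isotope) {
  abs(delta_ppm) * 2 * pi * field_h1_mhz * gamma_ratio(isotope)
}

# Signed variant, used for resonance offsets where the sign is physical.
shift_ppm_to_rad_per_s <- function(delta_ppm, field_h1_mhz, isotope) {
  delta_ppm * 2 * pi * field_h1_mhz * gamma_ratio(isotope)
}
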