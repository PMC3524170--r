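#' @keywords internal
"_PACKAGE"

## Gas constant in kcal K-1 mol-1 (1.987 cal K-1 mol-1); free energies are
## carried in kcal mol-1 throughout.
R_GAS_KCAL <- 1.987e-3

## gammaN/gammaH for 15N/1H; negative because gammaN < 0.  The sign is carried
## explicitly so that NOE < 1 yields a positive cross-relaxation rate.
GAMMA_RATIO_NH <- -0.10136

## Effective high-frequency convention for reduced spectral density mapping:
## J(omegaH) is reported at 0.87*omegaH.
HIGH_FREQ_SCALE <- 0.87

#' Dipolar and CSA interaction constants for a spectrometer field
#'
#' Builds the set of angular frequencies and interaction constants needed for
#' reduced spectral density mapping at a given proton Larmor frequency.
#' The dipolar constant d2 is field independent; the 15N CSA constant c2
#' scales with the square of the field and is pinned to its conventional
#' values at 600- and 800-MHz-class fields.
#'
#' @param field_mhz proton Larmor frequency in MHz (> 0).
#' @return an object of class `field_constants`: a list with `field_mhz`,
#'   `omega_H` and `omega_N` (rad/s), `d2` and `c2` ((rad/s)^2) and
#'   `gamma_ratio` (gammaN/gammaH, dimensionless, negative).
#' @examples
#' fc <- make_field_constants(600.51)
#' fc$omega_N / (2 * pi) / 1e6  # ~60.87 MHz
#' @export
make_field_constants <- function(field_mhz) {
  stopifnot(is.numeric(field_mhz), length(field_mhz) == 1L, field_mhz > 0)
  omega_H <- 2 * pi * field_mhz * 1e6
  omega_N <- abs(GAMMA_RATIO_NH) * omega_H
  d2 <- 1.35e9
  c2 <- if (abs(field_mhz - 600.51) < 25) {
    1.25e9
  } else if (abs(field_mhz - 800.12) < 25) {
    2.25e9
  } else {
    (field_mhz / 600.51)^2 * 1.25e9
  }
  structure(
    list(field_mhz = field_mhz, omega_H = omega_H, omega_N = omega_N,
         d2 = d2, c2 = c2, gamma_ratio = GAMMA_RATIO_NH),
    class = "field_constants"
  )
}

#' @export
print.field_constants <- function(x, ...) {
  cat(sprintf(
    "<field_constants> 1H %.2f MHz | omegaN/2pi %.2f MHz | d2 %.3g c2 %.3g (rad/s)^2\n",
    x$field_mhz, x$omega_N / (2 * pi) / 1e6, x$d2, x$c2))
  invisible(x)
}

## One-letter <-> three-letter amino-acid code tables.
AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")
AA3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
         "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")

aa_three_to_one <- function(x) {
  idx <- match(toupper(x), AA3)
  out <- AA1[idx]
  out
}

#' Random-coil Ca/Cb chemical-shift reference table
#'
#' Random-coil 13Ca and 13Cb shifts (ppm) per residue type, from Wishart et
#' al. (1995) J. Biomol. NMR 5:67 (cysteine in its reduced form). Glycine has
#' no Cb. Used as the reference for secondary chemical shifts
#' (delta-Ca minus delta-Cb); a custom table with the same columns can be
#' supplied wherever this one is accepted.
#'
#' @return data.frame with columns `aa` (one-letter code), `ca`, `cb` (ppm;
#'   `cb` is `NA` for Gly) and attribute `source_label`.
#' @export
random_coil_shifts <- function() {
  out <- data.frame(
    aa = c("A","R","N","D","C","Q","E","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V"),
    ca = c(52.5, 56.0, 53.1, 54.2, 58.2, 55.7, 56.6, 45.1, 55.0, 61.1,
           55.1, 56.2, 55.4, 57.7, 63.3, 58.3, 61.8, 57.5, 57.9, 62.2),
    cb = c(19.1, 30.9, 38.9, 41.1, 28.0, 29.4, 29.9, NA, 29.0, 38.8,
           42.4, 33.1, 32.9, 39.6, 31.7, 63.8, 69.8, 29.6, 38.8, 32.9),
    stringsAsFactors = FALSE
  )
  attr(out, "source_label") <- "Wishart-1995-random-coil"
  out
}

#' Mean-area-buried-upon-folding scale
#'
#' Per-residue average area buried upon folding (A^2), the hydrophobic-burial
#' scale of Rose et al. (1985) Science 229:834 (values as distributed by
#' ExPASy ProtScale). The basis for [aabuf_profile()].
#'
#' @return named numeric vector over the 20 one-letter codes.
#' @export
aabuf_scale <- function() {
  c(A = 86.6, R = 162.2, N = 103.3, D = 97.8, C = 132.3,
    Q = 119.2, E = 113.9, G = 62.9, H = 155.8, I = 158.0,
    L = 164.1, K = 115.5, M = 172.9, F = 194.1, P = 92.9,
    S = 85.6, T = 106.5, W = 224.6, Y = 177.7, V = 141.0)
}

#' Inversion-recovery delay schedule
#'
#' The 11-delay inversion-recovery schedule (ms) used for R1 measurement, with
#' the three delays recorded in duplicate repeated in place.
#' @return numeric vector of delays in ms (length 14, duplicates included).
#' @export
r1_delay_schedule <- function() {
  c(10, 30, 30, 50, 70, 90, 90, 130, 240, 410, 410, 610, 860, 1100)
}

#' CPMG delay schedule
#'
#' The 10-delay CPMG schedule (ms) used for R2 measurement, duplicated delays
#' repeated in place.
#' @return numeric vector of delays in ms (length 13, duplicates included).
#' @export
cpmg_delay_schedule <- function() {
  c(10, 10, 30, 50, 50, 70, 90, 110, 110, 130, 150, 170, 190)
}

#' HSQC temperature schedule for amide temperature coefficients
#'
#' Default temperature series: 15 to 36 degC in 3 degC steps (8 points).
#' @param unit "C" (default) or "K".
#' @return numeric vector of 8 temperatures.
#' @export
temp_schedule <- function(unit = c("C", "K")) {
  unit <- match.arg(unit)
  t_c <- seq(15, 36, by = 3)
  if (unit == "K") t_c + 273.15 else t_c
}
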