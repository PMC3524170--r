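## Domain containers. All tabular types are plain data.frames carrying a
## subclass and validated on construction; residue identity is the pair
## (residue_number, residue_type) and tables are allowed to have gaps
## (prolines and unobserved termini simply have no rows).

new_typed_df <- function(df, class) {
  structure(df, class = c(class, "data.frame"))
}

assert_residue_cols <- function(df, what) {
  if (!all(c("residue_number", "residue_type") %in% names(df)))
    stop(what, ": columns residue_number and residue_type are required", call. = FALSE)
  if (any(df$residue_number < 1 | df$residue_number != round(df$residue_number)))
    stop(what, ": residue_number must be a positive integer", call. = FALSE)
  bad <- !(toupper(df$residue_type) %in% AA1)
  if (any(bad))
    stop(what, ": unknown residue_type ", paste(unique(df$residue_type[bad]), collapse = ","),
         call. = FALSE)
  invisible(df)
}

#' Protein sequence record
#'
#' @param residues character vector of one-letter codes (case-insensitive).
#' @param id record identifier.
#' @param numbering_offset sequence position of the first residue (default 1).
#' @return object of class `sequence_record` with fields `id`, `residues`
#'   (uppercase one-letter codes) and `numbering_offset`.
#' @export
sequence_record <- function(residues, id = "seq", numbering_offset = 1L) {
  residues <- toupper(as.character(residues))
  if (length(residues) < 1L) stop("sequence must have length >= 1", call. = FALSE)
  bad <- !(residues %in% AA1)
  if (any(bad))
    stop("non-amino-acid characters in sequence: ",
         paste(unique(residues[bad]), collapse = ","), call. = FALSE)
  structure(list(id = id, residues = residues,
                 numbering_offset = as.integer(numbering_offset)),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<sequence_record> %s: %d residues (numbering %d-%d)\n", x$id,
              length(x$residues), x$numbering_offset,
              x$numbering_offset + length(x$residues) - 1L))
  invisible(x)
}

#' Residue numbers covered by a sequence record
#' @param seq a `sequence_record`.
#' @return integer vector of residue numbers.
#' @export
residue_numbers <- function(seq) {
  seq$numbering_offset + seq_along(seq$residues) - 1L
}

#' Peak-intensity decay curves (long format)
#'
#' One row per (residue, delay) observation of an inversion-recovery or CPMG
#' peak-height decay. Duplicate delays are legitimate (replicate recordings).
#'
#' @param df data.frame with columns `residue_number`, `residue_type`,
#'   `delay_ms`, `intensity` and optionally `intensity_error`.
#' @param experiment "inversion_recovery" or "cpmg".
#' @return `decay_table` data.frame with attribute `experiment`.
#' @export
decay_table <- function(df, experiment = c("inversion_recovery", "cpmg")) {
  experiment <- match.arg(experiment)
  assert_residue_cols(df, "decay_table")
  stopifnot(all(c("delay_ms", "intensity") %in% names(df)))
  if (any(df$delay_ms < 0)) stop("delays must be >= 0", call. = FALSE)
  counts <- table(df$residue_number)
  if (any(counts < 3))
    stop("each residue needs >= 3 decay points; offending residue(s): ",
         paste(names(counts)[counts < 3], collapse = ","), call. = FALSE)
  out <- new_typed_df(df, "decay_table")
  attr(out, "experiment") <- experiment
  out
}

#' Split a decay table into per-residue curves
#' @param decays a `decay_table`.
#' @return named list (by residue number) of single-residue `decay_table`s.
#' @export
split_decays <- function(decays) {
  experiment <- attr(decays, "experiment")
  out <- split(as.data.frame(decays), decays$residue_number)
  lapply(out, decay_table, experiment = experiment)
}

#' Heteronuclear NOE measurement table
#'
#' @param df data.frame with columns `residue_number`, `residue_type`,
#'   `intensity_sat`, `intensity_eq`, `noise_rms_sat`, `noise_rms_eq`:
#'   peak intensities with and without proton saturation and the RMS
#'   background noise of the two spectra.
#' @return `noe_table` data.frame.
#' @export
noe_table <- function(df) {
  assert_residue_cols(df, "noe_table")
  stopifnot(all(c("intensity_sat", "intensity_eq",
                  "noise_rms_sat", "noise_rms_eq") %in% names(df)))
  if (any(df$intensity_eq == 0))
    stop("intensity_eq must be nonzero", call. = FALSE)
  if (any(df$noise_rms_sat < 0 | df$noise_rms_eq < 0))
    stop("noise RMS values must be >= 0", call. = FALSE)
  new_typed_df(df, "noe_table")
}

#' Backbone chemical-shift table
#'
#' @param df data.frame with `residue_number`, `residue_type` and any of the
#'   ppm columns `hn`, `n`, `ca`, `cb`, `ha` (missing atoms are `NA`).
#' @param condition_label text label for the sample condition (e.g. "0M").
#' @return `shift_table` data.frame with attribute `condition_label`.
#' @export
shift_table <- function(df, condition_label = "") {
  assert_residue_cols(df, "shift_table")
  atom_cols <- intersect(c("hn", "n", "ca", "cb", "ha"), names(df))
  if (length(atom_cols) == 0)
    stop("shift_table: at least one atom column (hn, n, ca, cb, ha) required",
         call. = FALSE)
  for (col in atom_cols)
    if (any(is.infinite(df[[col]]), na.rm = TRUE))
      stop("non-finite ppm value in column ", col, call. = FALSE)
  if (anyDuplicated(df$residue_number))
    stop("duplicate residue in shift_table", call. = FALSE)
  out <- new_typed_df(df, "shift_table")
  attr(out, "condition_label") <- condition_label
  out
}

#' Optical denaturation curve
#'
#' @param denaturant_M denaturant concentrations (mol/L, >= 0).
#' @param signal spectroscopic signal (CD ellipticity or fluorescence
#'   intensity, arbitrary units), same length.
#' @param signal_type one of "cd_218nm", "fluorescence_331nm", "other".
#' @return `denaturation_table` data.frame sorted by concentration.
#' @export
denaturation_table <- function(denaturant_M, signal,
                               signal_type = c("fluorescence_331nm", "cd_218nm", "other")) {
  signal_type <- match.arg(signal_type)
  stopifnot(length(denaturant_M) == length(signal))
  if (any(denaturant_M < 0)) stop("denaturant concentrations must be >= 0", call. = FALSE)
  ord <- order(denaturant_M)
  denaturant_M <- denaturant_M[ord]; signal <- signal[ord]
  if (any(duplicated(denaturant_M)))
    stop("denaturant concentrations must be distinct", call. = FALSE)
  out <- new_typed_df(
    data.frame(denaturant_M = denaturant_M, signal = signal),
    "denaturation_table")
  attr(out, "signal_type") <- signal_type
  out
}

#' Amide-shift-versus-temperature series (long format)
#'
#' One row per (residue, temperature) amide-proton shift. Temperatures given
#' in Celsius are converted to Kelvin once here.
#'
#' @param df data.frame with `residue_number`, `residue_type`, `temperature`,
#'   `hn_shift_ppm`.
#' @param unit temperature unit of the input, "K" or "C".
#' @return `temperature_table` data.frame with column `temperature_K`.
#' @export
temperature_table <- function(df, unit = c("K", "C")) {
  unit <- match.arg(unit)
  assert_residue_cols(df, "temperature_table")
  stopifnot(all(c("temperature", "hn_shift_ppm") %in% names(df)))
  df$temperature_K <- if (unit == "C") df$temperature + 273.15 else df$temperature
  df$temperature <- NULL
  counts <- table(df$residue_number)
  if (any(counts < 3))
    stop("each residue needs >= 3 temperature points", call. = FALSE)
  for (grp in split(df$temperature_K, df$residue_number))
    if (any(duplicated(grp)))
      stop("temperatures must be distinct within a residue", call. = FALSE)
  new_typed_df(df, "temperature_table")
}

#' 3J(HN-Ha) coupling table
#'
#' @param df data.frame with `residue_number`, `residue_type`, `j_hz`.
#' @return `coupling_table` data.frame.
#' @export
coupling_table <- function(df) {
  assert_residue_cols(df, "coupling_table")
  stopifnot("j_hz" %in% names(df))
  if (any(df$j_hz <= 0 | df$j_hz >= 15))
    stop("couplings must lie in (0, 15) Hz", call. = FALSE)
  new_typed_df(df, "coupling_table")
}

#' HSQC cross-peak intensity table (wide format)
#'
#' @param df data.frame with `residue_number`, `residue_type` and one numeric
#'   column per condition label; absent peaks are `NA`, never zero.
#' @return `peak_table` data.frame.
#' @export
peak_table <- function(df) {
  assert_residue_cols(df, "peak_table")
  cond <- setdiff(names(df), c("residue_number", "residue_type"))
  if (length(cond) == 0) stop("peak_table: no condition columns", call. = FALSE)
  for (col in cond)
    if (any(df[[col]] < 0, na.rm = TRUE))
      stop("peak heights must be >= 0 (absent peaks are NA)", call. = FALSE)
  new_typed_df(df, "peak_table")
}
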