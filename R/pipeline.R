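## Orchestration: chain the per-condition stages (rates -> NOE -> spectral
## densities -> regression -> correlation times -> exchange -> propensity)
## and merge everything into one wide per-residue table, with mean +/- SD
## summaries over named residue ranges.

## Merge per-stage tables on residue number alone: inputs may disagree on (or
## omit) residue types, so types are reconciled by first non-missing value.
merge_on_residue <- function(tables) {
  tables <- Filter(Negate(is.null), tables)
  if (length(tables) == 0) return(NULL)
  types <- do.call(rbind, lapply(tables, function(tb)
    tb[, c("residue_number", "residue_type")]))
  types <- types[!is.na(types$residue_type), , drop = FALSE]
  types <- types[!duplicated(types$residue_number), , drop = FALSE]
  tables <- lapply(tables, function(tb) tb[, setdiff(names(tb), "residue_type"),
                                           drop = FALSE])
  out <- Reduce(function(a, b) merge(a, b, by = "residue_number",
                                     all = TRUE, sort = FALSE), tables)
  out$residue_type <- types$residue_type[match(out$residue_number,
                                               types$residue_number)]
  out <- out[order(out$residue_number),
             c("residue_number", "residue_type",
               setdiff(names(out), c("residue_number", "residue_type")))]
  rownames(out) <- NULL
  out
}

#' Run the full per-condition analysis pipeline
#'
#' For each named condition, fits R1/R2 decays, computes NOEs, assembles
#' relaxation triples, maps reduced spectral densities, regresses J(omegaN)
#' and J(omegaH) on J(0), extracts correlation times at both frequencies,
#' screens exchange, and attaches any propensity inputs supplied (shifts,
#' couplings, temperature series, peak intensities). A sequence yields an
#' AABUF profile shared across conditions.
#'
#' @param conditions named list; each element a list with components
#'   `r1_decays`, `r2_decays` ([decay_table()]s), `noe` ([noe_table()]), and
#'   optionally `shifts`, `couplings`, `tempseries`, and precomputed
#'   `triples` (replacing the three raw inputs).
#' @param field_mhz proton frequency, MHz.
#' @param sequence optional [sequence_record()] for the AABUF profile.
#' @param peaks optional [peak_table()] of HSQC intensities across conditions.
#' @param exchange_threshold_sd SD threshold for exchange flagging.
#' @param aabuf_window AABUF moving-average window.
#' @return object of class `pipeline_report`: per-condition results
#'   (`rates_r1`, `rates_r2`, `noe`, `triples`, `spectral`, `regressions`,
#'   `correlation_times`, `exchange`, plus propensity calls), `aabuf`,
#'   `normalized_peaks`, and `merged` -- one wide row per residue present in
#'   any input.
#' @export
run_pipeline <- function(conditions, field_mhz = 600.51, sequence = NULL,
                         peaks = NULL, exchange_threshold_sd = 1,
                         aabuf_window = 9) {
  stopifnot(length(conditions) > 0, !is.null(names(conditions)))
  fc <- make_field_constants(field_mhz)
  per_cond <- lapply(names(conditions), function(label) {
    inp <- conditions[[label]]
    res <- list(label = label)
    run_stage <- function(stage, expr) {
      tryCatch(expr, error = function(e)
        stop("condition '", label, "', stage '", stage, "': ",
             conditionMessage(e), call. = FALSE))
    }
    if (!is.null(inp$triples)) {
      res$triples <- inp$triples
    } else if (!is.null(inp$r1_decays) && !is.null(inp$r2_decays) && !is.null(inp$noe)) {
      res$rates_r1 <- run_stage("fit_r1", fit_decay_table(inp$r1_decays))
      res$rates_r2 <- run_stage("fit_r2", fit_decay_table(inp$r2_decays))
      res$noe <- run_stage("noe", heteronuclear_noe(inp$noe))
      res$triples <- run_stage("triples",
        relaxation_triples(res$rates_r1, res$rates_r2, res$noe, field_mhz))
    }
    if (!is.null(res$triples)) {
      res$spectral <- run_stage("jsd", map_spectral_density(res$triples, fc))
      res$regressions <- list(
        JwN = run_stage("regress", regress_J(res$spectral, "JwN")),
        JwH = run_stage("regress", regress_J(res$spectral, "JwH")))
      res$correlation_times <- list(
        omega_N = run_stage("tau", correlation_times(res$regressions$JwN,
                                                     fc$omega_N * 1e-9)),
        omega_H = run_stage("tau", correlation_times(res$regressions$JwH,
                                                     fc$omega_H * 1e-9)))
      res$exchange <- run_stage("exchange",
        exchange_metrics(res$triples, threshold_sd = exchange_threshold_sd))
    }
    if (!is.null(inp$shifts))
      res$secondary_shifts <- run_stage("shifts", secondary_shifts(inp$shifts))
    if (!is.null(inp$couplings)) {
      cls <- run_stage("couplings", classify_coupling(inp$couplings$j_hz))
      res$coupling_classes <- data.frame(
        residue_number = inp$couplings$residue_number,
        residue_type = inp$couplings$residue_type,
        j_hz = inp$couplings$j_hz, j_class = cls, stringsAsFactors = FALSE)
      res$structure_fractions <- summarize_structure_fractions(cls)
    }
    if (!is.null(inp$tempseries))
      res$temp_coefficients <- run_stage("tempcoeff", temp_coefficients(inp$tempseries))
    res
  })
  names(per_cond) <- names(conditions)

  aabuf <- if (!is.null(sequence)) aabuf_profile(sequence, window = aabuf_window)
  norm_peaks <- if (!is.null(peaks)) normalize_intensities(peaks)

  merged_parts <- list()
  for (label in names(per_cond)) {
    res <- per_cond[[label]]
    tag <- function(df, cols) {
      if (is.null(df)) return(NULL)
      keep <- df[, c("residue_number", "residue_type", cols), drop = FALSE]
      names(keep)[-(1:2)] <- paste0(cols, ".", label)
      keep
    }
    merged_parts <- c(merged_parts, list(
      tag(as.data.frame(res$triples),
          c("R1", "R1_err", "R2", "R2_err", "NOE", "NOE_err")),
      tag(as.data.frame(res$spectral),
          c("J0", "J0_err", "JwN", "JwN_err", "JwH", "JwH_err")),
      tag(res$exchange, c("r2_over_r1", "flagged")),
      tag(res$secondary_shifts, "dca_minus_dcb"),
      tag(res$coupling_classes, c("j_hz", "j_class")),
      tag(res$temp_coefficients, c("slope_ppb_per_K", "hbond_class"))))
  }
  if (!is.null(aabuf))
    merged_parts <- c(merged_parts, list(aabuf))
  merged <- merge_on_residue(merged_parts)

  structure(list(conditions = per_cond, aabuf = aabuf,
                 normalized_peaks = norm_peaks, field_mhz = field_mhz,
                 merged = merged),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d condition(s): %s | merged table: %s residues\n",
              length(x$conditions), paste(names(x$conditions), collapse = ", "),
              if (is.null(x$merged)) 0 else nrow(x$merged)))
  invisible(x)
}

#' Mean +/- SD summaries over named residue ranges
#'
#' For each named range and each requested metric column, reports the mean
#' and SD over residues inside the range with the metric observed, plus the
#' count of residues excluded as missing. An empty range (no residue with
#' data) yields a warning row with `NA` statistics.
#'
#' @param per_residue data.frame with `residue_number` and metric columns
#'   (e.g. the `merged` table of [run_pipeline()], or a
#'   [relaxation_triples()]).
#' @param ranges data.frame with `name`, `start`, `end`.
#' @param metrics character vector of metric column names (default: all
#'   numeric columns except `residue_number`).
#' @return data.frame with one row per (range, metric): `range`, `start`,
#'   `end`, `metric`, `mean`, `sd`, `n`, `n_missing`.
#' @export
summarize_ranges <- function(per_residue, ranges,
                             metrics = NULL) {
  df <- as.data.frame(per_residue)
  if (is.null(metrics))
    metrics <- setdiff(names(df)[vapply(df, is.numeric, TRUE)], "residue_number")
  rows <- list()
  for (r in seq_len(nrow(ranges))) {
    inside <- df$residue_number >= ranges$start[r] & df$residue_number <= ranges$end[r]
    for (m in metrics) {
      vals <- df[[m]][inside]
      n_missing <- sum(is.na(vals))
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0)
        warning("range '", ranges$name[r], "': no observed values for ", m,
                call. = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        range = ranges$name[r], start = ranges$start[r], end = ranges$end[r],
        metric = m,
        mean = if (length(vals)) mean(vals) else NA_real_,
        sd = if (length(vals) > 1) stats::sd(vals) else if (length(vals) == 1) 0 else NA_real_,
        n = length(vals), n_missing = n_missing,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
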