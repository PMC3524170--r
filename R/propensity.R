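## Residue-level structural-propensity calls: secondary chemical shifts,
## 3J(HN-Ha) classification, amide temperature coefficients, hydrophobic
## burial (AABUF) profiling, normalized HSQC intensities, and sequential NOE
## connectivity tabulation.

#' Secondary chemical shifts (delta-Ca minus delta-Cb)
#'
#' Per residue, `(Ca_obs - Ca_rc) - (Cb_obs - Cb_rc)` against a random-coil
#' reference table. Contiguous positive runs suggest helical propensity,
#' negative runs strand (reported as values, not asserted as structure).
#' Glycine has no Cb: its value is delta-Ca alone, flagged in `gly_ca_only`.
#'
#' @param shifts a [shift_table()] with `ca` and/or `cb` columns.
#' @param rc random-coil reference, default [random_coil_shifts()].
#' @param smooth_window optional odd window for a centered moving average
#'   (truncated at the chain ends); `NULL` for none.
#' @return data.frame: `residue_number`, `residue_type`, `dca_minus_dcb`
#'   (ppm; `NA` where unobserved), `gly_ca_only`, and `smoothed` when
#'   requested.
#' @export
secondary_shifts <- function(shifts, rc = random_coil_shifts(), smooth_window = NULL) {
  df <- as.data.frame(shifts)
  if (!any(c("ca", "cb") %in% names(df)))
    stop("shift table has neither ca nor cb", call. = FALSE)
  if (!("ca" %in% names(df))) df$ca <- NA_real_
  if (!("cb" %in% names(df))) df$cb <- NA_real_
  idx <- match(toupper(df$residue_type), rc$aa)
  if (any(is.na(idx)))
    stop("residue type(s) absent from the random-coil table: ",
         paste(unique(df$residue_type[is.na(idx)]), collapse = ","), call. = FALSE)
  dca <- df$ca - rc$ca[idx]
  dcb <- df$cb - rc$cb[idx]
  is_gly <- toupper(df$residue_type) == "G"
  value <- ifelse(is_gly, dca, dca - dcb)
  out <- data.frame(residue_number = df$residue_number,
                    residue_type = df$residue_type,
                    dca_minus_dcb = value,
                    gly_ca_only = is_gly,
                    stringsAsFactors = FALSE)
  if (!is.null(smooth_window)) {
    if (smooth_window %% 2 == 0) stop("smoothing window must be odd", call. = FALSE)
    out$smoothed <- truncated_window_mean(out$dca_minus_dcb, smooth_window)
  }
  out
}

## Centered moving average with a window truncated (shrunk) at the edges;
## NAs are skipped within the window.
truncated_window_mean <- function(x, window) {
  half <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1L, i - half):min(n, i + half)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, 0)
}

#' Classify 3J(HN-Ha) couplings by backbone conformation
#'
#' Three-way partition of (0, 15) Hz: helical below `helical_max`
#' (alpha-helix or polyproline-II band, 4.0-5.5 Hz), random coil between
#' `helical_max` and `coil_max` inclusive, strand above `coil_max` (> 8 Hz).
#'
#' @param j_hz coupling constant(s) in Hz, in (0, 15).
#' @param helical_max,coil_max class boundaries in Hz (defaults 5.5, 8.0).
#' @return character vector: "helical", "coil" or "strand".
#' @export
classify_coupling <- function(j_hz, helical_max = 5.5, coil_max = 8.0) {
  stopifnot(helical_max < coil_max)
  if (any(j_hz <= 0 | j_hz >= 15))
    stop("couplings must lie in (0, 15) Hz", call. = FALSE)
  ifelse(j_hz < helical_max, "helical",
         ifelse(j_hz <= coil_max, "coil", "strand"))
}

#' Secondary-structure fractions from coupling classes
#'
#' @param classes character vector of classes from [classify_coupling()].
#' @return named numeric vector of percentages (`helical`, `strand`, `coil`)
#'   over classified residues, summing to 100 up to rounding.
#' @export
summarize_structure_fractions <- function(classes) {
  if (length(classes) == 0) stop("no classified couplings", call. = FALSE)
  stopifnot(all(classes %in% c("helical", "coil", "strand")))
  n <- length(classes)
  c(helical = 100 * sum(classes == "helical") / n,
    strand = 100 * sum(classes == "strand") / n,
    coil = 100 * sum(classes == "coil") / n)
}

#' Amide-proton temperature coefficients
#'
#' Fits a straight line to each residue's amide-proton shift versus
#' temperature and reports the slope as a temperature coefficient in ppb/K.
#' A residue whose coefficient is more positive than the cutoff (default
#' -4.5 ppb/K, strict inequality) is classed `protected` (hydrogen bonded),
#' otherwise `exposed`. Residues with fewer than 3 points are skipped with a
#' warning.
#'
#' @param series a [temperature_table()].
#' @param cutoff_ppb_K protection cutoff (default -4.5).
#' @return data.frame: `residue_number`, `residue_type`, `slope_ppb_per_K`,
#'   `intercept_ppm`, `r_squared`, `hbond_class`.
#' @export
temp_coefficients <- function(series, cutoff_ppb_K = -4.5) {
  df <- as.data.frame(series)
  rows <- lapply(split(df, df$residue_number), function(g) {
    if (nrow(g) < 3) {
      warning("residue ", g$residue_number[1], ": fewer than 3 temperature points, skipped",
              call. = FALSE)
      return(NULL)
    }
    fit <- stats::lm(hn_shift_ppm ~ temperature_K, data = g)
    slope_ppb <- stats::coef(fit)[["temperature_K"]] * 1000
    r2 <- suppressWarnings(summary(fit)$r.squared)  # perfect fits warn
    data.frame(residue_number = g$residue_number[1],
               residue_type = g$residue_type[1],
               slope_ppb_per_K = slope_ppb,
               intercept_ppm = stats::coef(fit)[["(Intercept)"]],
               r_squared = r2,
               hbond_class = if (slope_ppb > cutoff_ppb_K) "protected" else "exposed",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Average-area-buried-upon-folding profile
#'
#' Per-residue hydrophobic burial from the embedded mean-area-buried scale,
#' smoothed by a centered moving average of odd width (default 9 residues).
#' At the chain ends the window shrinks to the available neighbors, so every
#' residue has a value.
#'
#' @param seq a [sequence_record()].
#' @param window odd moving-average width (default 9); 1 disables smoothing.
#' @param scale named per-residue area scale (default [aabuf_scale()]).
#' @return data.frame: `residue_number`, `residue_type`, `raw_A2`,
#'   `windowed_A2`.
#' @export
aabuf_profile <- function(seq, window = 9, scale = aabuf_scale()) {
  if (window %% 2 == 0 || window < 1)
    stop("window must be a positive odd integer", call. = FALSE)
  raw <- unname(scale[seq$residues])
  data.frame(residue_number = residue_numbers(seq),
             residue_type = seq$residues,
             raw_A2 = raw,
             windowed_A2 = truncated_window_mean(raw, window),
             stringsAsFactors = FALSE)
}

#' Normalize HSQC cross-peak intensities per condition
#'
#' Within each condition column, divides observed intensities by that
#' condition's median observed intensity. Missing peaks stay missing; a
#' condition with no observed peak is dropped with a warning.
#'
#' @param peaks a [peak_table()].
#' @return `peak_table` with normalized condition columns.
#' @export
normalize_intensities <- function(peaks) {
  df <- as.data.frame(peaks)
  cond <- setdiff(names(df), c("residue_number", "residue_type"))
  drop <- character()
  for (col in cond) {
    obs <- df[[col]][!is.na(df[[col]])]
    if (length(obs) == 0) {
      warning("condition '", col, "' has no observed peaks; dropped", call. = FALSE)
      drop <- c(drop, col)
      next
    }
    df[[col]] <- df[[col]] / stats::median(obs)
  }
  df <- df[, setdiff(names(df), drop), drop = FALSE]
  peak_table(df)
}

#' Sequential amide-amide NOE connectivities
#'
#' Filters assigned cross-peak residue pairs to sequential `d_NN(i, i+1)`
#' contacts and reports maximal contiguous runs (the stretches helical
#' conformations produce).
#'
#' @param pairs data.frame with columns `i`, `j` (residue numbers of the two
#'   amide protons).
#' @param condition_label text label carried through to the output.
#' @return list with `pairs` (the sequential subset, i < j) and `runs`
#'   (data.frame `start`, `end`: residues covered by consecutive
#'   connectivities).
#' @export
sequential_connectivities <- function(pairs, condition_label = "") {
  if (nrow(pairs) == 0) {
    return(list(pairs = data.frame(i = integer(), j = integer()),
                runs = data.frame(start = integer(), end = integer()),
                condition_label = condition_label))
  }
  lo <- pmin(pairs$i, pairs$j); hi <- pmax(pairs$i, pairs$j)
  keep <- (hi - lo) == 1L
  seq_pairs <- unique(data.frame(i = lo[keep], j = hi[keep]))
  seq_pairs <- seq_pairs[order(seq_pairs$i), , drop = FALSE]
  runs <- data.frame(start = integer(), end = integer())
  if (nrow(seq_pairs) > 0) {
    start <- seq_pairs$i[1]; end <- seq_pairs$j[1]
    if (nrow(seq_pairs) > 1) {
      for (r in 2:nrow(seq_pairs)) {
        if (seq_pairs$i[r] <= end) {
          end <- max(end, seq_pairs$j[r])
        } else {
          runs <- rbind(runs, data.frame(start = start, end = end))
          start <- seq_pairs$i[r]; end <- seq_pairs$j[r]
        }
      }
    }
    runs <- rbind(runs, data.frame(start = start, end = end))
  }
  rownames(seq_pairs) <- NULL
  list(pairs = seq_pairs, runs = runs, condition_label = condition_label)
}
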