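## Per-residue 15N relaxation-rate extraction. Peak heights along a delay
## series are fitted to I(t) = A + B * exp(-R * t): A + B is the intensity at
## t = 0 and A the steady-state intensity at t = infinity. CPMG (R2) decays
## go to zero, so their offset is fixed at zero by default; inversion-recovery
## (R1) fits keep A free.

#' Fit a single-exponential decay to peak heights
#'
#' Least squares of `I(t) = A + B * exp(-R * t)` on one residue's decay
#' curve (delays in ms, rate reported in 1/s). Starting values come from
#' log-linear regression on the offset-subtracted intensities, so monotone
#' decays need no random starts. Points with explicit intensity errors are
#' weighted `1/err^2`; otherwise errors fall back to duplicate-delay pooled
#' SD, then to the post-hoc residual SD.
#'
#' @param decay single-residue [decay_table()] with >= 3 distinct delays.
#' @param fix_offset_to_zero force `A = 0` (two-parameter fit). Defaults to
#'   `TRUE` for CPMG curves and `FALSE` for inversion recovery.
#' @return object of class `rate_estimate`: `residue_number`, `residue_type`,
#'   `rate` and `rate_error` (1/s, error from the fit covariance),
#'   `amplitude_A`, `amplitude_B`, `rss`, `n_points`.
#' @export
fit_exponential <- function(decay,
                            fix_offset_to_zero = identical(attr(decay, "experiment"), "cpmg")) {
  df <- as.data.frame(decay)
  if (length(unique(df$residue_number)) != 1L)
    stop("fit_exponential expects a single residue; use split_decays()", call. = FALSE)
  if (length(unique(df$delay_ms)) < 3L)
    stop("need >= 3 distinct delays", call. = FALSE)
  t_s <- df$delay_ms / 1000
  I <- df$intensity
  if (diff(range(I)) <= 1e-12 * max(abs(I), 1))
    stop("non-decaying curve: intensities are constant", call. = FALSE)

  weights <- NULL
  if ("intensity_error" %in% names(df) && all(is.finite(df$intensity_error)) &&
      all(df$intensity_error > 0))
    weights <- 1 / df$intensity_error^2

  A0 <- if (fix_offset_to_zero) 0 else I[which.max(t_s)]
  resid0 <- I - A0
  pos <- resid0 > 0 & is.finite(log(abs(resid0)))
  if (sum(pos) >= 2) {
    ll <- stats::lm(log(resid0[pos]) ~ t_s[pos])
    R0 <- max(-stats::coef(ll)[[2]], 0.01)
    B0 <- exp(stats::coef(ll)[[1]])
  } else {
    R0 <- 1; B0 <- I[which.min(t_s)] - A0
  }

  dat <- data.frame(t_s = t_s, I = I)
  args <- list(
    if (fix_offset_to_zero) I ~ B * exp(-R * t_s) else I ~ A + B * exp(-R * t_s),
    data = dat,
    start = if (fix_offset_to_zero) list(B = B0, R = R0)
            else list(A = A0, B = B0, R = R0),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!is.null(weights)) args$weights <- weights
  fit <- tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e)
    stop("exponential fit failed for residue ", df$residue_number[1], ": ",
         conditionMessage(e), call. = FALSE))

  cf <- stats::coef(fit)
  if (cf[["R"]] <= 0)
    stop("non-decaying curve: fitted rate <= 0 for residue ",
         df$residue_number[1], call. = FALSE)
  rate_error <- sqrt(stats::vcov(fit)["R", "R"])
  structure(
    list(residue_number = df$residue_number[1],
         residue_type = df$residue_type[1],
         rate = cf[["R"]], rate_error = rate_error,
         amplitude_A = if (fix_offset_to_zero) 0 else cf[["A"]],
         amplitude_B = cf[["B"]],
         rss = sum(stats::residuals(fit)^2), n_points = nrow(df),
         fit = fit),
    class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> residue %d%s: R = %.4g +/- %.2g 1/s (n = %d)\n",
              x$residue_number,
              if (is.na(x$residue_type)) "" else paste0(" (", x$residue_type, ")"),
              x$rate, x$rate_error, x$n_points))
  invisible(x)
}

#' Pooled intensity error from duplicate delays
#'
#' Delays recorded more than once give a direct estimate of the intensity
#' noise: the pooled standard deviation over all replicate groups,
#' `sqrt(sum_g SS_g / sum_g (n_g - 1))`, applied as a uniform per-point error.
#'
#' @param decay single-residue [decay_table()].
#' @return pooled SD (scalar), or `NA` when no delay is duplicated (caller
#'   falls back to fit-residual errors).
#' @export
duplicate_delay_error <- function(decay) {
  df <- as.data.frame(decay)
  groups <- split(df$intensity, df$delay_ms)
  groups <- groups[lengths(groups) >= 2]
  if (length(groups) == 0) return(NA_real_)
  ss <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  dof <- sum(lengths(groups) - 1L)
  sqrt(ss / dof)
}

#' Heteronuclear 1H-15N NOE with noise-propagated error
#'
#' `NOE = I_sat / I_eq` from peak intensities with and without proton
#' saturation; the error propagates the RMS background noise of the two
#' spectra: `|NOE| * sqrt((rms_sat/I_sat)^2 + (rms_eq/I_eq)^2)`. Negative
#' NOEs are physically meaningful (highly flexible residues); a negative
#' `I_eq` is flagged with a warning (likely phase problem) but still
#' computed.
#'
#' @param noe a [noe_table()] (one or more residues).
#' @return data.frame with `residue_number`, `residue_type`, `noe`,
#'   `noe_error`.
#' @export
heteronuclear_noe <- function(noe) {
  df <- as.data.frame(noe)
  if (any(df$intensity_eq == 0))
    stop("I_eq is zero: NOE undefined", call. = FALSE)
  if (any(df$intensity_eq < 0))
    warning("negative I_eq for residue(s) ",
            paste(df$residue_number[df$intensity_eq < 0], collapse = ","),
            " (phase problem?)", call. = FALSE)
  ratio <- df$intensity_sat / df$intensity_eq
  err <- abs(ratio) * sqrt((df$noise_rms_sat / df$intensity_sat)^2 +
                           (df$noise_rms_eq / df$intensity_eq)^2)
  data.frame(residue_number = df$residue_number,
             residue_type = df$residue_type,
             noe = ratio, noe_error = err,
             stringsAsFactors = FALSE)
}

#' Assemble per-residue relaxation triples
#'
#' Joins fitted R1 and R2 rate tables with NOE values into the pipeline's
#' central record: one row per residue with (R1, R2, NOE) and their errors at
#' a stated field. Residues missing any of the three are dropped.
#'
#' @param r1,r2 data.frames with `residue_number`, `residue_type`, `rate`,
#'   `rate_error` (e.g. from [fit_decay_table()]).
#' @param noe data.frame from [heteronuclear_noe()].
#' @param field_mhz proton frequency of the measurement, MHz.
#' @return `relaxation_triples` data.frame with columns `residue_number`,
#'   `residue_type`, `R1`, `R1_err`, `R2`, `R2_err`, `NOE`, `NOE_err` and
#'   attribute `field_mhz`.
#' @export
relaxation_triples <- function(r1, r2, noe, field_mhz) {
  stopifnot(field_mhz > 0)
  common <- Reduce(intersect, list(r1$residue_number, r2$residue_number,
                                   noe$residue_number))
  i1 <- match(common, r1$residue_number)
  i2 <- match(common, r2$residue_number)
  i3 <- match(common, noe$residue_number)
  out <- data.frame(
    residue_number = common,
    residue_type = r1$residue_type[i1],
    R1 = r1$rate[i1], R1_err = r1$rate_error[i1],
    R2 = r2$rate[i2], R2_err = r2$rate_error[i2],
    NOE = noe$noe[i3], NOE_err = noe$noe_error[i3],
    stringsAsFactors = FALSE)
  if (any(out$R1 <= 0 | out$R2 <= 0))
    stop("relaxation rates must be positive", call. = FALSE)
  out <- new_typed_df(out, "relaxation_triples")
  attr(out, "field_mhz") <- field_mhz
  out
}

#' Fit every residue in a decay table
#'
#' Maps [fit_exponential()] over the residues of a decay table. When no
#' explicit per-point errors are present, duplicate-delay pooled SDs are
#' attached as uniform weights first (error hierarchy: explicit > pooled
#' duplicate SD > fit residuals).
#'
#' @param decays a [decay_table()].
#' @param ... passed to [fit_exponential()].
#' @return data.frame with one row per residue: `residue_number`,
#'   `residue_type`, `rate`, `rate_error`, `amplitude_A`, `amplitude_B`,
#'   `rss`, `n_points`.
#' @export
fit_decay_table <- function(decays, ...) {
  curves <- split_decays(decays)
  rows <- lapply(curves, function(cv) {
    if (!("intensity_error" %in% names(cv))) {
      pooled <- duplicate_delay_error(cv)
      if (is.finite(pooled) && pooled > 0) cv$intensity_error <- pooled
    }
    est <- fit_exponential(cv, ...)
    data.frame(residue_number = est$residue_number,
               residue_type = est$residue_type,
               rate = est$rate, rate_error = est$rate_error,
               amplitude_A = est$amplitude_A, amplitude_B = est$amplitude_B,
               rss = est$rss, n_points = est$n_points,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
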