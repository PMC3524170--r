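## Two-state chemical-denaturation thermodynamics. The observed optical
## signal is modelled as
##   Y(D) = (s_n + s_d * K) / (1 + K),  K = exp(-(g1 - m1 * D) / (R * T))
## with flat native/denatured baselines s_n, s_d, free-energy change g1
## (kcal/mol), transition slope m1 (kcal/mol/M) and R = 1.987 cal/K/mol.
## The transition midpoint is g1/m1.

two_state_K <- function(g1, m1, D, temperature_K) {
  exp(-(g1 - m1 * D) / (R_GAS_KCAL * temperature_K))
}

#' Two-state signal model
#'
#' Forward evaluation of the two-state denaturation signal at given
#' concentrations.
#'
#' @param s_n,s_d native and denatured baseline signals (arbitrary units).
#' @param g1 free-energy change at zero denaturant, kcal/mol.
#' @param m1 transition slope, kcal/mol/M (> 0 for a denaturation).
#' @param D denaturant concentration(s), M.
#' @param temperature_K temperature in K.
#' @return numeric vector of signals.
#' @export
two_state_signal <- function(s_n, s_d, g1, m1, D, temperature_K) {
  K <- two_state_K(g1, m1, D, temperature_K)
  (s_n + s_d * K) / (1 + K)
}

#' Fraction unfolded under a two-state fit
#'
#' `K/(1+K)` with `K = exp(-(g1 - m1*D)/(R*T))`: 0.5 at the midpoint
#' `D = g1/m1`, monotone non-decreasing in `D` for `m1 > 0`.
#'
#' @param fit a `two_state_fit` (or any list with `g1`, `m1`,
#'   `temperature_K`).
#' @param D denaturant concentration(s), M.
#' @return fraction unfolded in `[0, 1]`.
#' @export
fraction_unfolded <- function(fit, D) {
  stopifnot(fit$temperature_K > 0)
  K <- two_state_K(fit$g1, fit$m1, D, fit$temperature_K)
  K / (1 + K)
}

#' Fit the two-state denaturation model to an optical melting curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the two-state model to
#' signal-versus-denaturant data. Baselines are flat by default; set
#' `sloping_baselines = TRUE` to give each baseline a linear slope in `D`.
#' Starting values are data-driven (tercile means for the baselines,
#' half-signal crossing for the midpoint, central finite-difference slope for
#' `m1`) and the fit is retried from five deterministically jittered starts on
#' failure.
#'
#' @param curve a [denaturation_table()] with at least 6 points spanning both
#'   baselines and the transition.
#' @param temperature_K temperature of the melt, K.
#' @param sloping_baselines logical; fit linear baseline slopes (default
#'   `FALSE`).
#' @return object of class `two_state_fit`: estimates `s_n`, `s_d`, `g1`,
#'   `m1` (plus baseline slopes when requested), `temperature_K`, `midpoint`
#'   (g1/m1) with `midpoint_err` (delta method), standard `errors`, the 4x4
#'   `covariance` of (s_n, s_d, g1, m1), `residuals` and the underlying `nls`
#'   fit.
#' @export
fit_two_state <- function(curve, temperature_K, sloping_baselines = FALSE) {
  stopifnot(temperature_K > 0)
  df <- as.data.frame(curve)
  if (nrow(df) < 6) stop("need >= 6 points to fit a two-state model", call. = FALSE)
  D <- df$denaturant_M; Y <- df$signal
  if (diff(range(Y)) <= 1e-10 * max(abs(Y), 1))
    stop("no transition detected", call. = FALSE)

  n3 <- max(2L, floor(length(Y) / 3))
  s_n0 <- mean(Y[seq_len(n3)])
  s_d0 <- mean(Y[seq(length(Y) - n3 + 1L, length(Y))])
  if (abs(s_d0 - s_n0) <= 1e-8 * max(abs(Y), 1))
    stop("no transition detected", call. = FALSE)
  mid0 <- D[which.min(abs(Y - (s_n0 + s_d0) / 2))]
  if (mid0 <= min(D)) mid0 <- min(D) + 0.25 * diff(range(D))
  ## dY/dD at the midpoint is (s_d - s_n) * m1 / (4RT): invert the central
  ## finite-difference slope for a starting m1.
  i_mid <- which.min(abs(D - mid0))
  i_lo <- max(1L, i_mid - 1L); i_hi <- min(length(D), i_mid + 1L)
  slope0 <- (Y[i_hi] - Y[i_lo]) / (D[i_hi] - D[i_lo])
  m1_0 <- abs(4 * R_GAS_KCAL * temperature_K * slope0 / (s_d0 - s_n0))
  if (!is.finite(m1_0) || m1_0 < 0.1) m1_0 <- 1
  start <- list(s_n = s_n0, s_d = s_d0, g1 = m1_0 * mid0, m1 = m1_0)

  model <- if (sloping_baselines) {
    start$b_n <- 0; start$b_d <- 0
    Y ~ ((s_n + b_n * D) + (s_d + b_d * D) *
           exp(-(g1 - m1 * D) / (R_GAS_KCAL * temperature_K))) /
        (1 + exp(-(g1 - m1 * D) / (R_GAS_KCAL * temperature_K)))
  } else {
    Y ~ (s_n + s_d * exp(-(g1 - m1 * D) / (R_GAS_KCAL * temperature_K))) /
        (1 + exp(-(g1 - m1 * D) / (R_GAS_KCAL * temperature_K)))
  }

  jitter_factors <- c(1, 0.5, 2, 0.25, 4, 1.5)  # deterministic restarts
  fit <- NULL; last_err <- NULL
  for (f in jitter_factors) {
    st <- start; st$m1 <- start$m1 * f; st$g1 <- st$m1 * mid0
    fit <- tryCatch(
      minpack.lm::nlsLM(model, data = data.frame(D = D, Y = Y), start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) { last_err <<- e; NULL })
    if (!is.null(fit) && stats::coef(fit)[["m1"]] > 0) break
    if (!is.null(fit) && stats::coef(fit)[["m1"]] <= 0) fit <- NULL
  }
  if (is.null(fit))
    stop("two-state fit did not converge: ", conditionMessage(last_err),
         call. = FALSE)

  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA_real_, length(cf), length(cf)))
  core <- c("s_n", "s_d", "g1", "m1")
  covariance <- vc[core, core, drop = FALSE]
  midpoint <- cf[["g1"]] / cf[["m1"]]
  ## delta method on g1/m1
  gr <- c(1 / cf[["m1"]], -cf[["g1"]] / cf[["m1"]]^2)
  vsub <- vc[c("g1", "m1"), c("g1", "m1")]
  midpoint_err <- sqrt(max(0, drop(t(gr) %*% vsub %*% gr)))
  if (midpoint < min(D) || midpoint > max(D))
    warning("fitted midpoint ", signif(midpoint, 4),
            " M lies outside the fitted concentration range", call. = FALSE)
  structure(
    list(s_n = cf[["s_n"]], s_d = cf[["s_d"]], g1 = cf[["g1"]], m1 = cf[["m1"]],
         b_n = if (sloping_baselines) cf[["b_n"]] else 0,
         b_d = if (sloping_baselines) cf[["b_d"]] else 0,
         temperature_K = temperature_K,
         midpoint = midpoint, midpoint_err = midpoint_err,
         errors = sqrt(diag(vc)), covariance = covariance,
         residuals = stats::residuals(fit), fit = fit),
    class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat(sprintf(
    "<two_state_fit> g1 %.3f kcal/mol | m1 %.3f kcal/mol/M | midpoint %.3f +/- %.3f M (T %.1f K)\n",
    x$g1, x$m1, x$midpoint, x$midpoint_err, x$temperature_K))
  invisible(x)
}

#' GdmCl concentration from a refractive-index increment
#'
#' Converts the refractive-index difference between a GdmCl sample and its
#' buffer into molar concentration using the cubic calibration polynomial of
#' Nozaki (1972) Methods Enzymol. 26:43:
#' `C = 57.147 dn + 38.68 dn^2 - 91.60 dn^3`.
#'
#' @param delta_n refractive-index increment, in `[0, 0.12]`.
#' @return GdmCl concentration in M (monotone over the domain, < 8 M).
#' @export
gdmcl_from_refractive_index <- function(delta_n) {
  if (any(delta_n < 0 | delta_n > 0.12))
    stop("delta_n outside the calibrated range [0, 0.12]", call. = FALSE)
  57.147 * delta_n + 38.68 * delta_n^2 - 91.60 * delta_n^3
}

#' Normalize a melting curve to apparent fraction unfolded
#'
#' Maps the signal to `(Y - s_n)/(s_d - s_n)` using fitted (or explicit)
#' baselines. Noise can push values slightly outside `[0, 1]`; they are not
#' clipped.
#'
#' @param curve a [denaturation_table()].
#' @param fit a `two_state_fit`, or `NULL` if baselines given directly.
#' @param s_n,s_d explicit baselines (ignored when `fit` is supplied).
#' @return a [denaturation_table()] with normalized signal.
#' @export
normalize_signal <- function(curve, fit = NULL, s_n = NULL, s_d = NULL) {
  if (!is.null(fit)) { s_n <- fit$s_n; s_d <- fit$s_d }
  if (is.null(s_n) || is.null(s_d))
    stop("supply a fit or explicit baselines", call. = FALSE)
  if (abs(s_d - s_n) <= 1e-12 * max(abs(c(s_n, s_d)), 1))
    stop("degenerate baselines: s_n == s_d", call. = FALSE)
  df <- as.data.frame(curve)
  denaturation_table(df$denaturant_M, (df$signal - s_n) / (s_d - s_n),
                     signal_type = attr(curve, "signal_type"))
}
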