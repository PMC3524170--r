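## Reduced spectral density mapping and correlation-time extraction.
##
## The mapping expresses J(0), J(omegaN) and J(omegaH) in terms of R1, R2 and
## the heteronuclear NOE (Farrow/Lefevre reduced forms, single effective high
## frequency 0.87*omegaH):
##   sigma_NH = R1 * (NOE - 1) * gammaN/gammaH
##   J(omegaH) = 4 * sigma_NH / (5 * d2)
##   J(omegaN) = (R1 - (7/4) * d2 * J(omegaH)) / ((3/4) * d2 + c2)
##   J(0)      = (R2 - ((3/8) d2 + c2/2) J(omegaN) - (13/8) d2 J(omegaH)) /
##               (d2/2 + (2/3) c2)
## J(0)/J(omegaN) are reported in ns/rad, J(omegaH) in ps/rad. The mapping is
## linear in (R1, R2, sigma), so it has an exact inverse
## (back_calculate_rates) and first-order error propagation is exact in the
## input errors.

#' 1H-15N cross-relaxation rate
#'
#' `sigma_NH = R1 * (NOE - 1) * gammaN/gammaH`. With the negative
#' gyromagnetic ratio, NOE < 1 always yields a positive sigma.
#'
#' @param triples a [relaxation_triples()] data.frame.
#' @return numeric vector of sigma_NH in 1/s.
#' @export
cross_relaxation <- function(triples) {
  triples$R1 * (triples$NOE - 1) * GAMMA_RATIO_NH
}

map_coefficients <- function(constants) {
  d2 <- constants$d2; c2 <- constants$c2
  list(d2 = d2, c2 = c2,
       denN = 0.75 * d2 + c2,            # J(omegaN) denominator
       den0 = 0.5 * d2 + (2 / 3) * c2,   # J(0) denominator
       kN = 0.375 * d2 + 0.5 * c2,       # J(omegaN) weight in R2
       kH0 = 1.625 * d2,                 # J(omegaH) weight in R2 (13/8)
       kHN = 1.75 * d2)                  # J(omegaH) weight in R1 (7/4)
}

#' Reduced spectral density mapping
#'
#' Maps per-residue (R1, R2, NOE) triples to J(0), J(omegaN) and J(omegaH)
#' with first-order error propagation from the rate and NOE errors. Negative
#' J values (possible under noise) are flagged in the `nonphysical` column,
#' never rejected.
#'
#' @param triples a [relaxation_triples()] data.frame.
#' @param constants a [make_field_constants()] object (defaults to the
#'   triples' field).
#' @return `spectral_triples` data.frame: `residue_number`, `residue_type`,
#'   `J0`, `J0_err` (ns/rad), `JwN`, `JwN_err` (ns/rad), `JwH`, `JwH_err`
#'   (ps/rad), `nonphysical`; attribute `field_mhz`.
#' @export
map_spectral_density <- function(triples,
                                 constants = make_field_constants(attr(triples, "field_mhz"))) {
  k <- map_coefficients(constants)
  R1 <- triples$R1; R2 <- triples$R2; NOE <- triples$NOE
  g <- constants$gamma_ratio

  sigma <- R1 * (NOE - 1) * g
  JwH <- 4 * sigma / (5 * k$d2)                     # s/rad
  JwN <- (R1 - k$kHN * JwH) / k$denN
  J0 <- (R2 - k$kN * JwN - k$kH0 * JwH) / k$den0

  ## Jacobian wrt the independent observables (R1, R2, NOE)
  dJwH_dR1 <- 4 * g * (NOE - 1) / (5 * k$d2)
  dJwH_dNOE <- 4 * g * R1 / (5 * k$d2)
  dJwN_dR1 <- (1 - k$kHN * dJwH_dR1) / k$denN
  dJwN_dNOE <- -k$kHN * dJwH_dNOE / k$denN
  dJ0_dR1 <- (-k$kN * dJwN_dR1 - k$kH0 * dJwH_dR1) / k$den0
  dJ0_dNOE <- (-k$kN * dJwN_dNOE - k$kH0 * dJwH_dNOE) / k$den0
  dJ0_dR2 <- 1 / k$den0

  e1 <- triples$R1_err; e2 <- triples$R2_err; eN <- triples$NOE_err
  JwH_err <- sqrt((dJwH_dR1 * e1)^2 + (dJwH_dNOE * eN)^2)
  JwN_err <- sqrt((dJwN_dR1 * e1)^2 + (dJwN_dNOE * eN)^2)
  J0_err <- sqrt((dJ0_dR1 * e1)^2 + (dJ0_dR2 * e2)^2 + (dJ0_dNOE * eN)^2)

  out <- data.frame(
    residue_number = triples$residue_number,
    residue_type = triples$residue_type,
    J0 = J0 * 1e9, J0_err = J0_err * 1e9,
    JwN = JwN * 1e9, JwN_err = JwN_err * 1e9,
    JwH = JwH * 1e12, JwH_err = JwH_err * 1e12,
    nonphysical = (J0 < 0) | (JwN < 0) | (JwH < 0),
    stringsAsFactors = FALSE)
  out <- new_typed_df(out, "spectral_triples")
  attr(out, "field_mhz") <- constants$field_mhz
  out
}

#' Back-calculate relaxation rates from spectral densities
#'
#' Exact linear inverse of [map_spectral_density()]: rebuilds (R1, R2, NOE)
#' from (J(0), J(omegaN), J(omegaH)) under the same constants. With all-zero
#' J the NOE is 1 by convention (zero cross-relaxation on zero R1).
#'
#' @param spectral a `spectral_triples` data.frame (J0/JwN in ns/rad, JwH in
#'   ps/rad).
#' @param constants a [make_field_constants()] object.
#' @param errors optional data.frame/list with `R1_err`, `R2_err`, `NOE_err`
#'   to attach (the inverse does not propagate errors).
#' @return a [relaxation_triples()]-shaped data.frame.
#' @export
back_calculate_rates <- function(spectral,
                                 constants = make_field_constants(attr(spectral, "field_mhz")),
                                 errors = NULL) {
  k <- map_coefficients(constants)
  J0 <- spectral$J0 * 1e-9; JwN <- spectral$JwN * 1e-9; JwH <- spectral$JwH * 1e-12
  R1 <- k$denN * JwN + k$kHN * JwH
  R2 <- k$den0 * J0 + k$kN * JwN + k$kH0 * JwH
  sigma <- 1.25 * k$d2 * JwH
  NOE <- ifelse(R1 == 0 & sigma == 0, 1, 1 + sigma / (R1 * constants$gamma_ratio))
  out <- data.frame(
    residue_number = spectral$residue_number,
    residue_type = spectral$residue_type,
    R1 = R1, R1_err = if (is.null(errors)) 0 else errors$R1_err,
    R2 = R2, R2_err = if (is.null(errors)) 0 else errors$R2_err,
    NOE = NOE, NOE_err = if (is.null(errors)) 0 else errors$NOE_err,
    stringsAsFactors = FALSE)
  out <- new_typed_df(out, "relaxation_triples")
  attr(out, "field_mhz") <- constants$field_mhz
  out
}

#' Regress a spectral density on J(0)
#'
#' Ordinary least squares of `J(target) = alpha * J(0) + beta` over residues
#' with both values present. Both sides are taken in ns/rad (J(omegaH) is
#' converted from ps/rad), so `alpha` is dimensionless and `beta` in ns/rad.
#'
#' @param spectral a `spectral_triples` data.frame.
#' @param target "JwN" or "JwH".
#' @return object of class `spectral_regression`: `target`, `alpha`, `beta`,
#'   `r_squared`, `n`, and the underlying `lm`.
#' @export
regress_J <- function(spectral, target = c("JwN", "JwH")) {
  target <- match.arg(target)
  y <- if (target == "JwN") spectral$JwN else spectral$JwH * 1e-3  # ps -> ns
  x <- spectral$J0
  keep <- is.finite(x) & is.finite(y)
  if (sum(keep) < 3)
    stop("need >= 3 residues with both J values for the regression", call. = FALSE)
  fit <- stats::lm(y ~ x, data = data.frame(x = x[keep], y = y[keep]))
  cf <- stats::coef(fit)
  structure(
    list(target = target, alpha = cf[["x"]], beta = cf[["(Intercept)"]],
         r_squared = suppressWarnings(summary(fit)$r.squared),  # exact lines warn
         n = sum(keep), fit = fit),
    class = "spectral_regression")
}

#' @export
print.spectral_regression <- function(x, ...) {
  cat(sprintf("<spectral_regression> J(%s) = %.4f * J(0) + %.4f ns/rad (R^2 %.3f, n %d)\n",
              if (x$target == "JwN") "omegaN" else "omegaH",
              x$alpha, x$beta, x$r_squared, x$n))
  invisible(x)
}

#' Correlation times from the J-J regression coefficients
#'
#' Solves the cubic
#' `2*alpha*omega^2*tau^3 + 5*beta*omega^2*tau^2 + 2*(alpha - 1)*tau +
#' 5*beta = 0` for the correlation time tau. Working units are chosen so the
#' roots emerge in ns directly: omega in rad/ns, beta in ns/rad. Real positive
#' roots are labelled by timescale: chemical exchange (>= 100 ns, i.e. the
#' ms-to-us regime as seen by this equation), overall tumbling (1-100 ns) and
#' internal motion (< 1 ns); complex or non-positive roots are nonphysical.
#' With `alpha = 0` the leading coefficient vanishes and the remaining
#' quadratic is solved (two roots, one reported absent).
#'
#' @param reg a `spectral_regression` (or any list with `alpha`, `beta` in
#'   ns/rad).
#' @param omega_rad_per_ns angular frequency in rad/ns (e.g.
#'   `constants$omega_N * 1e-9`).
#' @param tumbling_bounds lower/upper bound (ns) separating internal motion,
#'   overall tumbling and chemical exchange.
#' @return object of class `correlation_time_set`: `omega_rad_per_ns`,
#'   `roots` (complex, length 3; an absent root is `NA`), `real_positive_ns`
#'   (sorted decreasing), `labels` (per root: "chemical_exchange",
#'   "overall_tumbling", "internal_motion", "nonphysical", "absent").
#' @export
correlation_times <- function(reg, omega_rad_per_ns,
                              tumbling_bounds = c(1, 100)) {
  alpha <- reg$alpha; beta <- reg$beta
  stopifnot(is.finite(alpha), is.finite(beta), omega_rad_per_ns > 0)
  w2 <- omega_rad_per_ns^2
  coefs <- c(5 * beta, 2 * (alpha - 1), 5 * beta * w2, 2 * alpha * w2)
  if (alpha == 0) {
    roots <- c(solve_poly(coefs[1:3]), NA_complex_)
  } else {
    roots <- solve_poly(coefs)
  }
  is_real <- !is.na(roots) & abs(Im(roots)) <= 1e-8 * pmax(1, Mod(roots))
  re <- Re(roots)
  labels <- ifelse(is.na(roots), "absent",
            ifelse(!is_real | re <= 0, "nonphysical",
            ifelse(re >= tumbling_bounds[2], "chemical_exchange",
            ifelse(re >= tumbling_bounds[1], "overall_tumbling",
                   "internal_motion"))))
  pos <- sort(re[is_real & re > 0], decreasing = TRUE)
  structure(
    list(omega_rad_per_ns = omega_rad_per_ns, alpha = alpha, beta = beta,
         roots = roots, real_positive_ns = pos, labels = labels),
    class = "correlation_time_set")
}

## Root finding for a polynomial given in increasing-order coefficients,
## with exact handling of a zero constant term (factor out tau = 0 so the
## root is not left to numerical noise).
solve_poly <- function(coefs) {
  while (length(coefs) > 1 && coefs[length(coefs)] == 0)
    coefs <- coefs[-length(coefs)]  # drop zero leading terms
  nzero <- 0L
  while (length(coefs) > 1 && coefs[1] == 0) {
    coefs <- coefs[-1]; nzero <- nzero + 1L
  }
  roots <- if (length(coefs) > 1) polyroot(coefs) else complex(0)
  c(rep(as.complex(0), nzero), roots)
}

#' @export
print.correlation_time_set <- function(x, ...) {
  fmt <- function(z, lb) {
    if (is.na(z)) return("absent")
    if (lb == "nonphysical" && abs(Im(z)) > 1e-8 * max(1, Mod(z)))
      return(sprintf("%.3g%+.3gi (IM)", Re(z), Im(z)))
    sprintf("%.4g ns [%s]", Re(z), lb)
  }
  cat(sprintf("<correlation_time_set> alpha %.4g beta %.4g omega %.4g rad/ns\n",
              x$alpha, x$beta, x$omega_rad_per_ns))
  for (i in seq_along(x$roots))
    cat("  root", i, ":", fmt(x$roots[i], x$labels[i]), "\n")
  invisible(x)
}

#' Conformational-exchange screening metrics
#'
#' Computes `R2 * R1` and `R2 / R1` per residue; a high `R2/R1` ratio marks
#' likely conformational exchange. A residue is flagged when its ratio
#' exceeds the condition mean by more than `threshold_sd` standard deviations
#' (default 1).
#'
#' @param triples a [relaxation_triples()] data.frame.
#' @param threshold_sd flagging threshold in SD units.
#' @return data.frame: `residue_number`, `residue_type`, `r2_times_r1`
#'   (1/s^2), `r2_over_r1`, `flagged`.
#' @export
exchange_metrics <- function(triples, threshold_sd = 1) {
  if (nrow(triples) == 0) stop("empty triples", call. = FALSE)
  ratio <- triples$R2 / triples$R1
  cutoff <- mean(ratio) + threshold_sd * stats::sd(ratio)
  if (!is.finite(cutoff)) cutoff <- Inf  # single residue: nothing to compare
  data.frame(residue_number = triples$residue_number,
             residue_type = triples$residue_type,
             r2_times_r1 = triples$R2 * triples$R1,
             r2_over_r1 = ratio,
             flagged = ratio > cutoff,
             stringsAsFactors = FALSE)
}
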