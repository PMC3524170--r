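## Seeded synthetic-data generators. Each generator emulates one experiment
## of the pipeline with the statistical structure its analysis stage assumes,
## so every stage is testable with no measured data. All randomness is
## Gaussian, controlled by a `seed` argument (fixed seed => bit-identical
## output) and by a noise model: "gaussian_relative" scales the SD by the
## signal magnitude, "gaussian_absolute" uses it directly.

add_noise <- function(x, noise_level, noise_model = c("gaussian_relative", "gaussian_absolute")) {
  noise_model <- match.arg(noise_model)
  stopifnot(noise_level >= 0)
  if (noise_level == 0) return(x)
  sd <- if (noise_model == "gaussian_relative") noise_level * abs(x) else noise_level
  x + stats::rnorm(length(x), 0, sd)
}

#' Simulate a single-exponential peak-height decay
#'
#' `I(t) = A + B * exp(-rate * t)` at the given delay schedule (duplicate
#' delays honored as independent recordings) plus Gaussian noise.
#'
#' @param rate_s1 decay rate, 1/s (> 0).
#' @param A,B steady-state and decaying amplitudes.
#' @param delays_ms delay schedule in ms (default [r1_delay_schedule()]).
#' @param noise_level noise magnitude (default 0.01 relative).
#' @param noise_model "gaussian_relative" or "gaussian_absolute".
#' @param seed RNG seed (`NULL` leaves the RNG state alone).
#' @param residue_number,residue_type residue identity for the curve.
#' @param experiment experiment tag for the table.
#' @return single-residue [decay_table()].
#' @export
simulate_decay <- function(rate_s1, A = 0, B = 100,
                           delays_ms = r1_delay_schedule(),
                           noise_level = 0.01,
                           noise_model = "gaussian_relative",
                           seed = NULL,
                           residue_number = 1L, residue_type = "A",
                           experiment = if (identical(delays_ms, cpmg_delay_schedule())) "cpmg" else "inversion_recovery") {
  stopifnot(rate_s1 > 0)
  if (!is.null(seed)) set.seed(seed)
  ideal <- A + B * exp(-rate_s1 * delays_ms / 1000)
  decay_table(data.frame(residue_number = residue_number,
                         residue_type = residue_type,
                         delay_ms = delays_ms,
                         intensity = add_noise(ideal, noise_level, noise_model),
                         stringsAsFactors = FALSE),
              experiment = experiment)
}

#' Simulate a two-state denaturation curve
#'
#' Forward evaluation of the two-state model on a concentration grid plus
#' noise (defaults mirror a fluorescence melt sampled on 0-6 M at 0.2 M
#' steps).
#'
#' @param s_n,s_d,g1,m1 two-state parameters (see [two_state_signal()]);
#'   `m1 > 0`.
#' @param temperature_K temperature, K.
#' @param conc_M concentration grid, M.
#' @param noise_level noise magnitude (default 0.02 relative, a plausible
#'   optical-noise floor).
#' @param noise_model,seed see [simulate_decay()].
#' @param signal_type label for the table.
#' @return a [denaturation_table()].
#' @export
simulate_denaturation <- function(s_n, s_d, g1, m1, temperature_K = 298,
                                  conc_M = seq(0, 6, by = 0.2),
                                  noise_level = 0.02,
                                  noise_model = "gaussian_relative",
                                  seed = NULL,
                                  signal_type = "fluorescence_331nm") {
  stopifnot(m1 > 0)
  if (!is.null(seed)) set.seed(seed)
  ideal <- two_state_signal(s_n, s_d, g1, m1, conc_M, temperature_K)
  denaturation_table(conc_M, add_noise(ideal, noise_level, noise_model),
                     signal_type = signal_type)
}

#' Two-timescale (model-free) spectral density
#'
#' `J(omega) = (2/5) * (S2 * tau_m / (1 + (omega tau_m)^2) +
#' (1 - S2) * tau' / (1 + (omega tau')^2))` with
#' `1/tau' = 1/tau_m + 1/tau_e`. Used only to give the spectral-density
#' stage physically structured synthetic inputs.
#'
#' @param omega angular frequency, rad/s (vectorized).
#' @param tau_m_ns overall tumbling time, ns.
#' @param S2 order parameter in `[0, 1]`.
#' @param tau_e_ps internal-motion time, ps (must be well below `tau_m`).
#' @return J(omega) in s/rad.
#' @export
model_free_J <- function(omega, tau_m_ns, S2, tau_e_ps = 50) {
  stopifnot(S2 >= 0, S2 <= 1, tau_m_ns > 0, tau_e_ps > 0)
  tau_m <- tau_m_ns * 1e-9
  tau_e <- tau_e_ps * 1e-12
  tau_p <- 1 / (1 / tau_m + 1 / tau_e)
  0.4 * (S2 * tau_m / (1 + (omega * tau_m)^2) +
         (1 - S2) * tau_p / (1 + (omega * tau_p)^2))
}

#' Simulate relaxation triples from model-free parameters
#'
#' Generates per-residue (R1, R2, NOE) from the two-timescale spectral
#' density via the full five-frequency dipolar/CSA rate expressions
#' (J evaluated at 0, omegaN, omegaH-omegaN, omegaH, omegaH+omegaN, with the
#' module's d2 and c2), then adds noise. Because the true rates use all five
#' frequencies, the reduced mapping applied to these triples is an
#' approximation (single effective high frequency) -- exactly the situation
#' it faces on measured data.
#'
#' @param params data.frame with `residue_number`, `residue_type`,
#'   `tau_m_ns`, `S2` and optionally `tau_e_ps` (default 50 ps).
#' @param field_mhz proton frequency, MHz.
#' @param noise_level relative noise on rates and NOE (default 0.02).
#' @param seed RNG seed.
#' @return a [relaxation_triples()] data.frame (errors set to the noise SD).
#' @export
simulate_relaxation_from_model <- function(params, field_mhz = 600.51,
                                           noise_level = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fc <- make_field_constants(field_mhz)
  tau_e <- if ("tau_e_ps" %in% names(params)) params$tau_e_ps else 50
  J <- function(om) mapply(function(tm, s2, te) model_free_J(om, tm, s2, te),
                           params$tau_m_ns, params$S2, tau_e)
  wN <- fc$omega_N; wH <- fc$omega_H
  J0 <- J(0); JN <- J(wN)
  Jmn <- J(wH - wN); Jh <- J(wH); Jpl <- J(wH + wN)
  d2 <- fc$d2; c2 <- fc$c2
  R1 <- (d2 / 4) * (Jmn + 3 * JN + 6 * Jpl) + c2 * JN
  R2 <- (d2 / 8) * (4 * J0 + Jmn + 3 * JN + 6 * Jh + 6 * Jpl) +
        (c2 / 6) * (4 * J0 + 3 * JN)
  sigma <- (d2 / 4) * (6 * Jpl - Jmn)
  NOE <- 1 + (sigma / R1) / fc$gamma_ratio  # gammaH/gammaN = 1/gamma_ratio
  out <- data.frame(
    residue_number = params$residue_number,
    residue_type = params$residue_type,
    R1 = add_noise(R1, noise_level), R1_err = noise_level * R1,
    R2 = add_noise(R2, noise_level), R2_err = noise_level * R2,
    NOE = add_noise(NOE, noise_level), NOE_err = noise_level * abs(NOE),
    stringsAsFactors = FALSE)
  out <- new_typed_df(out, "relaxation_triples")
  attr(out, "field_mhz") <- field_mhz
  out
}

#' Simulate a chemical-shift table with planted secondary structure
#'
#' Random-coil reference shifts plus segment offsets: helix +2.6/-0.4 ppm on
#' Ca/Cb, strand -1.4/+1.0 ppm, coil 0 (documented generator conventions of
#' typical literature magnitude), plus absolute Gaussian noise.
#'
#' @param seq a [sequence_record()].
#' @param segments data.frame with `start`, `end`, `type`
#'   ("helix"/"strand"); ranges must not overlap. Unlisted residues are coil.
#' @param noise_level absolute noise SD in ppm (default 0.02).
#' @param seed RNG seed.
#' @param condition_label label for the table.
#' @return a [shift_table()] with `ca`/`cb` columns (Gly `cb` is `NA`).
#' @export
simulate_shift_table <- function(seq, segments = NULL, noise_level = 0.02,
                                 seed = NULL, condition_label = "sim") {
  if (!is.null(seed)) set.seed(seed)
  rc <- random_coil_shifts()
  nums <- residue_numbers(seq)
  idx <- match(seq$residues, rc$aa)
  ca <- rc$ca[idx]; cb <- rc$cb[idx]
  if (!is.null(segments) && nrow(segments) > 0) {
    covered <- unlist(mapply(function(s, e) s:e, segments$start, segments$end,
                             SIMPLIFY = FALSE))
    if (anyDuplicated(covered)) stop("overlapping segments", call. = FALSE)
    for (r in seq_len(nrow(segments))) {
      span <- nums >= segments$start[r] & nums <= segments$end[r]
      if (segments$type[r] == "helix") {
        ca[span] <- ca[span] + 2.6; cb[span] <- cb[span] - 0.4
      } else if (segments$type[r] == "strand") {
        ca[span] <- ca[span] - 1.4; cb[span] <- cb[span] + 1.0
      } else stop("segment type must be helix or strand", call. = FALSE)
    }
  }
  ca <- add_noise(ca, noise_level, "gaussian_absolute")
  cb[!is.na(cb)] <- add_noise(cb[!is.na(cb)], noise_level, "gaussian_absolute")
  shift_table(data.frame(residue_number = nums, residue_type = seq$residues,
                         ca = ca, cb = cb, stringsAsFactors = FALSE),
              condition_label = condition_label)
}

#' Simulate an amide-shift-versus-temperature series
#'
#' Linear series `delta(T) = intercept + slope * (T - T_ref)` on the default
#' 8-point 15-36 degC schedule, plus absolute noise.
#'
#' @param slope_ppb_K temperature coefficient, ppb/K.
#' @param intercept_ppm shift at `t_ref_C`, ppm.
#' @param temps_C temperatures in degC (default [temp_schedule()]).
#' @param t_ref_C reference temperature for the intercept (default 15).
#' @param noise_level absolute noise SD in ppm (default 0.002).
#' @param seed RNG seed.
#' @param residue_number,residue_type residue identity.
#' @return a [temperature_table()] (internally in K).
#' @export
simulate_temperature_series <- function(slope_ppb_K, intercept_ppm = 8.3,
                                        temps_C = temp_schedule(),
                                        t_ref_C = 15,
                                        noise_level = 0.002, seed = NULL,
                                        residue_number = 1L, residue_type = "A") {
  stopifnot(length(temps_C) >= 3)
  if (!is.null(seed)) set.seed(seed)
  shifts <- intercept_ppm + (slope_ppb_K / 1000) * (temps_C - t_ref_C)
  temperature_table(
    data.frame(residue_number = residue_number, residue_type = residue_type,
               temperature = temps_C,
               hn_shift_ppm = add_noise(shifts, noise_level, "gaussian_absolute"),
               stringsAsFactors = FALSE),
    unit = "C")
}
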