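# Independent oracles and fixture builders shared across tests.

# Brute-force polynomial root finder: companion-matrix eigenvalues of the
# monic polynomial. Coefficients in increasing order. Degenerate cases are
# handled the same way a hand calculation would: drop zero leading terms,
# factor out tau = 0 for a zero constant term.
companion_roots <- function(coefs) {
  while (length(coefs) > 1 && coefs[length(coefs)] == 0)
    coefs <- coefs[-length(coefs)]
  nzero <- 0L
  while (length(coefs) > 1 && coefs[1] == 0) {
    coefs <- coefs[-1]
    nzero <- nzero + 1L
  }
  n <- length(coefs) - 1L
  roots <- if (n >= 1) {
    monic <- coefs / coefs[length(coefs)]
    comp <- matrix(0, n, n)
    if (n > 1) comp[cbind(2:n, 1:(n - 1))] <- 1
    comp[, n] <- -monic[1:n]
    eigen(comp, only.values = TRUE)$values
  } else complex(0)
  c(rep(as.complex(0), nzero), roots)
}

# Worst relative discrepancy between two complex root multisets, minimized
# over pairings (conjugate pairs make naive sorting order-unstable).
root_set_distance <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n == 0) return(0)
  perms <- if (n == 1) list(1L) else if (n == 2) list(1:2, 2:1) else
    list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  min(vapply(perms, function(p) max(Mod(a[p] - b) / pmax(1, Mod(b))), 0))
}

# The cubic in the correlation-time extraction, increasing-order coefficients.
tau_cubic_coefs <- function(alpha, beta, omega) {
  c(5 * beta, 2 * (alpha - 1), 5 * beta * omega^2, 2 * alpha * omega^2)
}

# A deterministic physical spectral-density triple set (ns/rad, ns/rad,
# ps/rad) spanning realistic magnitudes, for round-trip tests.
random_spectral_triples <- function(n, seed) {
  set.seed(seed)
  df <- data.frame(
    residue_number = seq_len(n),
    residue_type = sample(c("A", "L", "K", "S", "V"), n, replace = TRUE),
    J0 = runif(n, 0.2, 4),
    J0_err = 0, JwN_err = 0, JwH_err = 0,
    JwN = runif(n, 0.05, 0.6),
    JwH = runif(n, 1, 30),
    stringsAsFactors = FALSE)
  structure(df, class = c("spectral_triples", "data.frame"), field_mhz = 600.51)
}

# Uniform synthetic relaxation triples with hand-set values.
uniform_triples <- function(n = 20, R1 = 2, R2 = 6, NOE = 0.7, field_mhz = 600.51) {
  df <- data.frame(
    residue_number = seq_len(n), residue_type = "A",
    R1 = R1, R1_err = 0.05, R2 = R2, R2_err = 0.1,
    NOE = NOE, NOE_err = 0.02, stringsAsFactors = FALSE)
  structure(df, class = c("relaxation_triples", "data.frame"),
            field_mhz = field_mhz)
}

synthetic_fasta <- function() {
  system.file("extdata", "m_crystallin_synthetic.fasta", package = "unfoldnmr")
}
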