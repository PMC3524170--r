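test_that("every generator is bit-reproducible under a fixed seed", {
  expect_identical(simulate_decay(2.65, seed = 61),
                   simulate_decay(2.65, seed = 61))
  expect_identical(simulate_denaturation(1, 0.3, 5.396, 2.84, seed = 62),
                   simulate_denaturation(1, 0.3, 5.396, 2.84, seed = 62))
  sq <- read_sequence(synthetic_fasta())
  segs <- data.frame(start = 22, end = 28, type = "helix")
  expect_identical(simulate_shift_table(sq, segs, seed = 63),
                   simulate_shift_table(sq, segs, seed = 63))
  expect_identical(simulate_temperature_series(-5, seed = 64),
                   simulate_temperature_series(-5, seed = 64))
  params <- data.frame(residue_number = 1:10, residue_type = "A",
                       tau_m_ns = 4.67, S2 = 0.82)
  expect_identical(simulate_relaxation_from_model(params, seed = 65),
                   simulate_relaxation_from_model(params, seed = 65))
  # different seeds genuinely differ
  expect_false(identical(simulate_decay(2.65, seed = 61),
                         simulate_decay(2.65, seed = 66)))
})

test_that("zero-noise generators compose with their analysis stages as identities", {
  est <- fit_exponential(simulate_decay(2.65, noise_level = 0))
  expect_equal(est$rate, 2.65, tolerance = 1e-7)

  fit <- fit_two_state(simulate_denaturation(1, 0.3, 5.396, 2.84,
                                             noise_level = 0), 298)
  expect_equal(fit$midpoint, 1.9, tolerance = 1e-7)

  tc <- temp_coefficients(simulate_temperature_series(-6, noise_level = 0))
  expect_equal(tc$slope_ppb_per_K, -6, tolerance = 1e-9)
})

test_that("the default denaturation grid and plateaus mirror a midpoint-1.9 melt", {
  cur <- simulate_denaturation(1, 0.3, 5.396, 2.84, noise_level = 0)
  expect_equal(nrow(cur), 31)  # 0-6 M at 0.2 M
  expect_equal(range(cur$denaturant_M), c(0, 6))
  amplitude <- abs(1 - 0.3)
  pre <- cur$signal[cur$denaturant_M <= 1.1]
  post <- cur$signal[cur$denaturant_M >= 2.8]
  expect_lt(diff(range(pre)) / amplitude, 0.02)   # flat before 1.1 M
  expect_lt(diff(range(post)) / amplitude, 0.02)  # flat after 2.8 M
  mid <- cur$signal[cur$denaturant_M > 1.1 & cur$denaturant_M < 2.8]
  expect_gt(diff(range(mid)) / amplitude, 0.5)    # the transition itself
})

test_that("the model-free generator has the right limits and regression structure", {
  # S2 = 1: single Lorentzian, J(0) = (2/5) tau_m
  expect_equal(model_free_J(0, 4.67, 1), 0.4 * 4.67e-9, tolerance = 1e-12)
  # rigid uniform chain: J(0) roughly uniform across the sequence
  params <- data.frame(residue_number = 1:80, residue_type = "A",
                       tau_m_ns = 4.67, S2 = 0.82)
  tri <- simulate_relaxation_from_model(params, 600.51, noise_level = 0.02,
                                        seed = 67)
  sp <- map_spectral_density(tri)
  expect_lt(stats::sd(sp$J0) / mean(sp$J0), 0.1)
  # rigidity varying along the chain (realistic mix) correlates J(wN) with
  # J(0): alpha comes out small and positive
  set.seed(68)
  params2 <- data.frame(residue_number = 1:80, residue_type = "A",
                        tau_m_ns = 4.67, S2 = runif(80, 0.6, 0.95))
  tri2 <- simulate_relaxation_from_model(params2, 600.51, noise_level = 0.02,
                                         seed = 69)
  reg <- regress_J(map_spectral_density(tri2), "JwN")
  expect_gt(reg$alpha, 0)
  expect_lt(reg$alpha, 0.5)
})

test_that("a two-population chain yields two real positive correlation-time roots", {
  tau_fast <- 1; tau_slow <- 4
  params <- data.frame(residue_number = 1:80, residue_type = "A",
                       tau_m_ns = rep(c(tau_slow, tau_fast), 40),
                       S2 = 0.82)
  tri <- simulate_relaxation_from_model(params, 600.51, noise_level = 0.01,
                                        seed = 68)
  sp <- map_spectral_density(tri)
  reg <- regress_J(sp, "JwN")
  ct <- correlation_times(reg, make_field_constants(600.51)$omega_N * 1e-9)
  expect_gte(length(ct$real_positive_ns), 2)
  # the two dominant roots bracket the planted tumbling populations
  expect_gt(max(ct$real_positive_ns), tau_fast)
  expect_lt(min(ct$real_positive_ns), tau_slow)
})

test_that("the mapping approximation stays within 5 percent on model-free rates", {
  params <- data.frame(residue_number = 1, residue_type = "A",
                       tau_m_ns = 4.67, S2 = 0.82)
  tri <- simulate_relaxation_from_model(params, 600.51, noise_level = 0)
  sp <- map_spectral_density(tri)
  J0_direct <- model_free_J(0, 4.67, 0.82) * 1e9
  expect_lt(abs(sp$J0 - J0_direct) / J0_direct, 0.05)
})
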