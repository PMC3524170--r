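test_that("field constants carry the printed d2/c2 and the gyromagnetic ratio", {
  fc6 <- make_field_constants(600.51)
  fc8 <- make_field_constants(800.12)
  expect_equal(fc6$c2, 1.25e9)
  expect_equal(fc8$c2, 2.25e9)
  expect_equal(fc6$d2, 1.35e9)
  expect_equal(fc6$omega_N / (2 * pi) / 1e6, 0.10136 * 600.51, tolerance = 1e-12)
  expect_equal(fc6$omega_N / (2 * pi) / 1e6, 60.867, tolerance = 1e-4)
  # off-class fields scale c2 quadratically
  fc7 <- make_field_constants(700)
  expect_equal(fc7$c2, (700 / 600.51)^2 * 1.25e9)
})

test_that("cross-relaxation sign convention makes NOE < 1 give sigma > 0", {
  tri <- uniform_triples(1, R1 = 2, NOE = 1)
  expect_equal(cross_relaxation(tri), 0)
  tri2 <- uniform_triples(1, R1 = 2, NOE = 0.5)
  expect_equal(cross_relaxation(tri2), 2 * (-0.5) * (-0.10136))
  expect_equal(cross_relaxation(tri2), 0.10136)
  set.seed(51)
  noes <- runif(50, -1, 0.999)
  tri3 <- uniform_triples(50)
  tri3$NOE <- noes
  expect_true(all(cross_relaxation(tri3) > 0))
})

test_that("mapping and back-calculation are exact mutual inverses", {
  for (field in c(600.51, 800.12)) {
    fc <- make_field_constants(field)
    sp <- random_spectral_triples(200, seed = 52)
    attr(sp, "field_mhz") <- field
    tri <- back_calculate_rates(sp, fc)
    sp2 <- map_spectral_density(tri, fc)
    expect_lt(max(abs(sp2$J0 - sp$J0) / sp$J0), 1e-12)
    expect_lt(max(abs(sp2$JwN - sp$JwN) / sp$JwN), 1e-12)
    expect_lt(max(abs(sp2$JwH - sp$JwH) / sp$JwH), 1e-12)
    tri2 <- back_calculate_rates(sp2, fc)
    expect_equal(tri2$R1, tri$R1, tolerance = 1e-12)
    expect_equal(tri2$R2, tri$R2, tolerance = 1e-12)
    expect_equal(tri2$NOE, tri$NOE, tolerance = 1e-12)
  }
})

test_that("all-zero spectral densities back-calculate to zero rates and unit NOE", {
  sp <- random_spectral_triples(1, seed = 53)
  sp$J0 <- 0; sp$JwN <- 0; sp$JwH <- 0
  tri <- back_calculate_rates(sp)
  expect_equal(tri$R1, 0)
  expect_equal(tri$R2, 0)
  expect_equal(tri$NOE, 1)
})

test_that("doubling R2 moves only J(0); physical J triples give R2 > R1 ordering checks", {
  tri <- uniform_triples(1, R1 = 2, R2 = 6, NOE = 0.7)
  sp <- map_spectral_density(tri)
  tri2 <- tri; tri2$R2 <- 12
  sp2 <- map_spectral_density(tri2)
  expect_gt(sp2$J0, sp$J0)
  expect_equal(sp2$JwN, sp$JwN)
  expect_equal(sp2$JwH, sp$JwH)

  # grid check: J(0) >= J(wN) >= J(wH) triples produce R2 >= R1 * const > 0
  sp_grid <- random_spectral_triples(100, seed = 54)
  sp_grid$JwN <- pmin(sp_grid$JwN, sp_grid$J0)
  tri_grid <- back_calculate_rates(sp_grid)
  expect_true(all(tri_grid$R2 > 0))
  expect_true(all(tri_grid$R2 / tri_grid$R1 > 0.5))
})

test_that("error propagation is first-order linear in the input errors", {
  tri <- uniform_triples(5, R1 = 2, R2 = 6, NOE = 0.7)
  sp1 <- map_spectral_density(tri)
  tri2 <- tri
  tri2$R1_err <- 2 * tri$R1_err
  tri2$R2_err <- 2 * tri$R2_err
  tri2$NOE_err <- 2 * tri$NOE_err
  sp2 <- map_spectral_density(tri2)
  expect_equal(sp2$J0_err, 2 * sp1$J0_err, tolerance = 1e-12)
  expect_equal(sp2$JwN_err, 2 * sp1$JwN_err, tolerance = 1e-12)
  expect_equal(sp2$JwH_err, 2 * sp1$JwH_err, tolerance = 1e-12)
})

test_that("regress_J recovers exact lines and degenerate scatter", {
  sp <- random_spectral_triples(65, seed = 55)
  sp$JwN <- 0.14 * sp$J0 + 0.30
  reg <- regress_J(sp, "JwN")
  expect_equal(reg$alpha, 0.14, tolerance = 1e-12)
  expect_equal(reg$beta, 0.30, tolerance = 1e-12)
  expect_equal(reg$n, 65L)

  # JwH is regressed in ns/rad
  sp$JwH <- (0.002 * sp$J0 + 0.004) * 1e3  # ps/rad column
  regH <- regress_J(sp, "JwH")
  expect_equal(regH$alpha, 0.002, tolerance = 1e-12)
  expect_equal(regH$beta, 0.004, tolerance = 1e-12)

  set.seed(56)
  sp$JwN <- 0.3 + rnorm(65, 0, 0.02)  # no dependence on J0
  reg0 <- regress_J(sp, "JwN")
  expect_lt(abs(reg0$alpha), 0.05)
  expect_equal(reg0$beta, mean(sp$JwN) - reg0$alpha * mean(sp$J0), tolerance = 1e-9)

  expect_error(regress_J(sp[1:2, ], "JwN"), ">= 3 residues")
})

test_that("the correlation-time cubic reproduces the printed regression cases", {
  omega_N <- make_field_constants(600.51)$omega_N * 1e-9  # rad/ns
  ct4 <- correlation_times(list(alpha = 0.14, beta = 0.30), omega_N)
  # largest real positive root ~3.54 ns at 4 M (coefficients printed to 2 dp)
  expect_equal(max(ct4$real_positive_ns), 3.54, tolerance = 0.05)
  expect_length(ct4$roots, 3)
  expect_setequal(ct4$labels[Re(ct4$roots) > 0 & abs(Im(ct4$roots)) < 1e-8],
                  "overall_tumbling")

  ct6 <- correlation_times(list(alpha = 0.11, beta = 0.31), omega_N)
  pos <- sort(ct6$real_positive_ns, decreasing = TRUE)
  expect_equal(pos[1], 3.97, tolerance = 0.05)
  expect_equal(pos[2], 1.01, tolerance = 0.05)
})

test_that("the cubic solver matches the companion-matrix oracle across random draws", {
  set.seed(57)
  n_draws <- 1000
  alphas <- runif(n_draws, 0, 1)
  betas <- runif(n_draws, 0.01, 1)
  omegas <- runif(n_draws, 0.1, 5)
  # inject the degenerate families
  alphas[1:20] <- 0
  betas[21:40] <- 0
  worst <- 0
  for (i in seq_len(n_draws)) {
    ct <- correlation_times(list(alpha = alphas[i], beta = betas[i]), omegas[i])
    mine <- ct$roots[!is.na(ct$roots)]
    oracle <- companion_roots(tau_cubic_coefs(alphas[i], betas[i], omegas[i]))
    expect_length(mine, length(oracle))
    worst <- max(worst, root_set_distance(mine, oracle))
  }
  expect_lt(worst, 1e-9)
})

test_that("complex cubic roots come in conjugate pairs and beta = 0 factors out tau = 0", {
  set.seed(58)
  for (i in 1:100) {
    ct <- correlation_times(list(alpha = runif(1, 0, 1), beta = runif(1, -1, 1)),
                            runif(1, 0.1, 5))
    n_complex <- sum(abs(Im(ct$roots[!is.na(ct$roots)])) >
                       1e-8 * pmax(1, Mod(ct$roots[!is.na(ct$roots)])))
    expect_true(n_complex %in% c(0L, 2L))
  }
  ct0 <- correlation_times(list(alpha = 0.5, beta = 0), 2)
  expect_true(any(ct0$roots == 0))
  ctq <- correlation_times(list(alpha = 0, beta = 0.3), 2)
  expect_identical(sum(is.na(ctq$roots)), 1L)
  expect_identical(ctq$labels[is.na(ctq$roots)], "absent")
})

test_that("timescale labels partition the positive axis at the configured bounds", {
  ct <- correlation_times(list(alpha = 0.14, beta = 0.30), 0.382443)
  pos <- Re(ct$roots)[abs(Im(ct$roots)) < 1e-8 & Re(ct$roots) > 0]
  expect_true(all(ct$labels[match(pos, Re(ct$roots))] == "overall_tumbling"))
  # sub-ns roots label as internal motion
  ct2 <- correlation_times(list(alpha = 0.11, beta = 0.31),
                           make_field_constants(600.51)$omega_H * 1e-9)
  small <- Re(ct2$roots) > 0 & Re(ct2$roots) < 1 & abs(Im(ct2$roots)) < 1e-8
  expect_true(all(ct2$labels[small] == "internal_motion"))
})

test_that("exchange metrics flag only genuine R2/R1 outliers", {
  tri <- uniform_triples(20, R1 = 2, R2 = 6)
  ex <- exchange_metrics(tri)
  expect_equal(ex$r2_over_r1, rep(3, 20))
  expect_equal(ex$r2_times_r1, rep(12, 20))
  expect_false(any(ex$flagged))

  tri_eq <- uniform_triples(5, R1 = 2, R2 = 2)
  ex_eq <- exchange_metrics(tri_eq)
  expect_equal(ex_eq$r2_over_r1, rep(1, 5))
  expect_equal(ex_eq$r2_times_r1, rep(4, 5))

  tri$R2[7] <- 3 * tri$R2[7]
  ex2 <- exchange_metrics(tri)
  expect_identical(which(ex2$flagged), 7L)
})
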