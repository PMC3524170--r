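toy_shifts <- function(types = c("A", "V", "G", "K"), dca = 0, dcb = 0,
                       condition = "0M") {
  rc <- random_coil_shifts()
  idx <- match(types, rc$aa)
  shift_table(data.frame(residue_number = seq_along(types),
                         residue_type = types,
                         ca = rc$ca[idx] + dca,
                         cb = rc$cb[idx] + dcb,
                         stringsAsFactors = FALSE),
              condition_label = condition)
}

test_that("secondary shifts are zero on random-coil input and exact on offsets", {
  ss0 <- secondary_shifts(toy_shifts())
  expect_equal(ss0$dca_minus_dcb, rep(0, 4))
  expect_true(ss0$gly_ca_only[3])

  ss <- secondary_shifts(toy_shifts(dca = 2.0, dcb = -0.5))
  expect_equal(ss$dca_minus_dcb[c(1, 2, 4)], rep(2.5, 3))
  expect_equal(ss$dca_minus_dcb[3], 2.0)  # Gly: delta-Ca only

  bad <- toy_shifts()
  bad$residue_type[1] <- "X"
  class(bad) <- c("shift_table", "data.frame")
  expect_error(secondary_shifts(bad), "absent from the random-coil table")
})

test_that("a planted helical segment yields a positive run exactly there", {
  sq <- read_sequence(synthetic_fasta())
  segs <- data.frame(start = 22, end = 28, type = "helix")
  shifts <- simulate_shift_table(sq, segs, noise_level = 0)
  ss <- secondary_shifts(shifts)
  vals <- ss$dca_minus_dcb
  in_seg <- ss$residue_number >= 22 & ss$residue_number <= 28
  gly <- ss$gly_ca_only
  expect_equal(vals[in_seg & !gly], rep(3.0, sum(in_seg & !gly)),
               tolerance = 1e-9)                  # +2.6 - (-0.4)
  expect_equal(vals[in_seg & gly], rep(2.6, sum(in_seg & gly)),
               tolerance = 1e-9)
  expect_true(all(abs(vals[!in_seg]) < 1e-9))
  expect_error(simulate_shift_table(sq, data.frame(start = c(5, 8),
                                                   end = c(10, 12),
                                                   type = "helix")),
               "overlapping")
})

test_that("coupling classes partition (0, 15) Hz and summarize to percentages", {
  expect_identical(classify_coupling(4.8), "helical")
  expect_identical(classify_coupling(5.5), "coil")   # boundary goes to coil
  expect_identical(classify_coupling(8.0), "coil")
  expect_identical(classify_coupling(8.01), "strand")
  grid <- seq(0.01, 14.99, by = 0.01)
  cls <- classify_coupling(grid)
  expect_true(all(cls %in% c("helical", "coil", "strand")))
  # custom thresholds repartition without gaps or overlaps
  cls2 <- classify_coupling(grid, helical_max = 5.0, coil_max = 8.5)
  expect_equal(sum(cls2 == "helical"), sum(grid < 5.0))

  expect_equal(summarize_structure_fractions(classify_coupling(c(4.2, 9.0, 6.5))),
               c(helical = 100 / 3, strand = 100 / 3, coil = 100 / 3))
  fr <- summarize_structure_fractions(rep("strand", 10))
  expect_equal(unname(fr), c(0, 100, 0))
  # 77 couplings split 2/32/43 (helical/strand/coil)
  fr77 <- summarize_structure_fractions(c(rep("helical", 2), rep("strand", 32),
                                          rep("coil", 43)))
  expect_equal(unname(round(fr77, 1)), c(2.6, 41.6, 55.8))
  expect_equal(sum(fr77), 100)
  expect_error(summarize_structure_fractions(character()), "no classified")
})

test_that("temperature coefficients come from exact line fits with a strict cutoff", {
  ts_flat <- simulate_temperature_series(0, noise_level = 0, residue_number = 1)
  tc <- temp_coefficients(ts_flat)
  expect_equal(tc$slope_ppb_per_K, 0)
  expect_identical(tc$hbond_class, "protected")

  ts6 <- simulate_temperature_series(-6, noise_level = 0, residue_number = 2)
  tc6 <- temp_coefficients(ts6)
  expect_equal(tc6$slope_ppb_per_K, -6, tolerance = 1e-9)
  expect_identical(tc6$hbond_class, "exposed")

  # strict inequality: a slope exactly at the cutoff is exposed
  at_cutoff <- temp_coefficients(ts6, cutoff_ppb_K = tc6$slope_ppb_per_K)
  expect_identical(at_cutoff$hbond_class, "exposed")
  ts44 <- simulate_temperature_series(-4.4, noise_level = 0, residue_number = 4)
  expect_identical(temp_coefficients(ts44)$hbond_class, "protected")

  # slope invariant under adding a constant to all shifts
  df <- as.data.frame(ts6)
  df$hn_shift_ppm <- df$hn_shift_ppm + 3
  df$temperature <- df$temperature_K; df$temperature_K <- NULL
  tc_shift <- temp_coefficients(temperature_table(df, unit = "K"))
  expect_equal(tc_shift$slope_ppb_per_K, tc6$slope_ppb_per_K, tolerance = 1e-9)
})

test_that("the default temperature schedule has eight 3-degree steps", {
  expect_length(temp_schedule(), 8)
  expect_equal(unique(diff(temp_schedule())), 3)
  ts <- simulate_temperature_series(-5, noise_level = 0)
  expect_equal(sort(unique(ts$temperature_K)), temp_schedule("K"))
})

test_that("AABUF profiles smooth the burial scale with a shrinking edge window", {
  poly <- function(aa, n = 20) sequence_record(rep(aa, n), id = paste0("poly", aa))
  sc <- aabuf_scale()
  pw <- aabuf_profile(poly("W"))
  pg <- aabuf_profile(poly("G"))
  expect_equal(unique(pw$windowed_A2), unname(sc["W"]))
  expect_equal(unique(pg$windowed_A2), unname(sc["G"]))
  expect_gt(mean(pw$windowed_A2), mean(pg$windowed_A2))

  sq <- read_sequence(synthetic_fasta())
  raw <- aabuf_profile(sq, window = 1)
  expect_equal(raw$windowed_A2, raw$raw_A2)
  smoothed <- aabuf_profile(sq, window = 9)
  expect_equal(nrow(smoothed), 85)
  expect_true(all(is.finite(smoothed$windowed_A2)))
  # homopolymer: windowed mean equals raw mean under the truncated policy
  expect_equal(mean(pw$windowed_A2), mean(pw$raw_A2), tolerance = 1e-12)
  expect_error(aabuf_profile(sq, window = 8), "odd")
})

test_that("peak intensities normalize per condition by the observed median", {
  pk <- peak_table(data.frame(residue_number = 1:10, residue_type = "A",
                              m0 = rep(40, 10),
                              m4 = c(rep(80, 9), NA)))
  norm <- normalize_intensities(pk)
  expect_equal(norm$m0, rep(1, 10))
  expect_equal(norm$m4[1:9], rep(1, 9))
  expect_true(is.na(norm$m4[10]))  # missing preserved, median over observed

  pk2 <- peak_table(data.frame(residue_number = 1:4, residue_type = "A",
                               m0 = c(10, 20, 20, 40)))
  expect_equal(normalize_intensities(pk2)$m0, c(0.5, 1, 1, 2))

  pk3 <- peak_table(data.frame(residue_number = 1:3, residue_type = "A",
                               m0 = c(1, 2, 3), m6 = NA_real_))
  expect_warning(norm3 <- normalize_intensities(pk3), "no observed peaks")
  expect_false("m6" %in% names(norm3))
})

test_that("sequential NOE connectivities collapse into contiguous runs", {
  out <- sequential_connectivities(data.frame(i = c(20, 21, 40),
                                              j = c(21, 22, 50)))
  expect_equal(out$runs, data.frame(start = 20L, end = 22L))
  expect_equal(nrow(out$pairs), 2)

  empty <- sequential_connectivities(data.frame(i = integer(), j = integer()))
  expect_equal(nrow(empty$runs), 0)

  # two helical stretches: 20-25 and 68-73
  pairs <- data.frame(i = c(20:24, 68:72, 30), j = c(21:25, 69:73, 33))
  out2 <- sequential_connectivities(pairs, condition_label = "6M")
  expect_equal(out2$runs, data.frame(start = c(20L, 68L), end = c(25L, 73L)))
  expect_identical(out2$condition_label, "6M")
})
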