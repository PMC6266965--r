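test_that("default frequency grid is 31 log-spaced points containing 1 kHz", {
  g <- make_frequency_grid(5, 1, 1e6)
  expect_length(g, 31)
  expect_identical(g[16], 1000)          # exact, not approximate
  expect_equal(g[8], 10^(7/5))           # closed-form log spacing
  ratios <- g[-1] / g[-length(g)]
  expect_true(all(abs(ratios - 10^(1/5)) < 1e-12 * 10^(1/5)))
})

test_that("grid construction validates bounds and hits endpoints", {
  expect_equal(make_frequency_grid(1, 1, 10), c(1, 10))
  expect_error(make_frequency_grid(5, -1, 1e6), "positive")
  expect_error(make_frequency_grid(5, 1e6, 1), "strictly less")
  expect_error(make_frequency_grid(0, 1, 1e6), ">= 1")
  g <- make_frequency_grid(3, 10, 1e4)
  expect_identical(g[c(1, length(g))], c(10, 1e4))
})

test_that("spectrum constructor enforces invariants", {
  g <- c(1, 10, 100)
  expect_s3_class(eis_spectrum(g, c(3, 2, 1), c(-10, -20, -30)), "eis_spectrum")
  expect_error(eis_spectrum(g, c(3, 2), c(-10, -20, -30)), "match")
  expect_error(eis_spectrum(g, c(3, 0, 1), c(-10, -20, -30)), "> 0")
  expect_error(eis_spectrum(g, c(3, 2, 1), c(-10, -200, -30)), "180")
  expect_error(eis_spectrum(c(10, 1, 100), c(3, 2, 1), c(-1, -2, -3)),
               "increasing")
})

test_that("session codes order in-vitro < 1 h < week 2 < week 3", {
  expect_identical(session_time("week", 3), "week_3")
  expect_error(session_time("week"), "integer >= 2")
  expect_error(session_time("week", 1), "integer >= 2")
  codes <- c("week_3", "in_vitro", "week_2", "post_op_1h", "week_10")
  expect_identical(codes[order(session_rank(codes))],
                   c("in_vitro", "post_op_1h", "week_2", "week_3", "week_10"))
})

test_that("CSV round trip preserves every numeric field and sorts rows", {
  s <- simulate_spectrum(archetype_params("IROX", "hockey_stick", "in_vivo"),
                         meta = make_meta())
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(s, path)
  s2 <- read_spectrum_csv(path, meta = s$meta)
  expect_identical(s2$freq_hz, s$freq_hz)
  expect_identical(s2$zmag_ohm, s$zmag_ohm)
  expect_identical(s2$zphz_deg, s$zphz_deg)

  # out-of-order rows are sorted to the same spectrum
  df <- read.csv(path)
  write.csv(df[rev(seq_len(nrow(df))), ], path, row.names = FALSE)
  s3 <- read_spectrum_csv(path)
  expect_equal(s3$freq_hz, s$freq_hz)
  expect_equal(s3$zmag_ohm, s$zmag_ohm)
})

test_that("CSV reader rejects malformed files with row-level messages", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frequency_hz,zmag_ohm", "1,10"), path)
  expect_error(read_spectrum_csv(path), "zphz_deg")
  writeLines(c("frequency_hz,zmag_ohm,zphz_deg", "1,10,-5", "10,abc,-5"), path)
  expect_error(read_spectrum_csv(path), "row 2")
  writeLines(c("frequency_hz,zmag_ohm,zphz_deg", "1,10,-5", "1,20,-5"), path)
  expect_error(read_spectrum_csv(path), "duplicate frequency")
  writeLines(c("frequency_hz,zmag_ohm,zphz_deg", "1,10,-5", "10,0,-5"), path)
  expect_error(read_spectrum_csv(path), "row 2")
  writeLines(c("frequency_hz,zmag_ohm,zphz_deg", "3,30,-5", "1,10,-5",
               "2,20,-5"), path)
  expect_equal(read_spectrum_csv(path)$freq_hz, c(1, 2, 3))
})

test_that("instrument table parsing: magnitude/phase from Zreal/Zimag", {
  path <- withr::local_tempfile(fileext = ".dta")
  writeLines(c("EXPLAIN", "ZCURVE\tTABLE",
               "Pt\tFreq\tZreal\tZimag",
               "#\tHz\tohm\tohm",
               "0\t100\t3\t-4"), path)
  s <- read_instrument_dta(path)
  expect_equal(s$zmag_ohm, 5)
  expect_equal(s$zphz_deg, -53.13010235, tolerance = 1e-8)

  writeLines(c("EXPLAIN", "ZCURVE\tTABLE", "Pt\tFreq\tZreal\tZimag",
               "#\tHz\tohm\tohm"), path)
  expect_error(read_instrument_dta(path), "no data rows")
  writeLines(c("EXPLAIN", "nothing here"), path)
  expect_error(read_instrument_dta(path), "no ZCURVE")
})

test_that("instrument reader recomputes magnitude when Zmod is inconsistent", {
  path <- withr::local_tempfile(fileext = ".dta")
  writeLines(c("ZCURVE\tTABLE",
               "Pt\tFreq\tZreal\tZimag\tZmod\tZphz",
               "#\tHz\tohm\tohm\tohm\tdeg",
               "0\t100\t3\t-4\t7\t-53.13"), path)
  expect_warning(s <- read_instrument_dta(path), "recomputed")
  expect_equal(s$zmag_ohm, 5)
})

test_that("instrument round trip is bit-identical through read -> write -> read", {
  s <- simulate_spectrum(archetype_params("PT", "mixed", "in_vivo"),
                         meta = make_meta(array_type = "PT"))
  p1 <- withr::local_tempfile(fileext = ".dta")
  p2 <- withr::local_tempfile(fileext = ".dta")
  write_instrument_dta(s, p1)
  r1 <- read_instrument_dta(p1, meta = s$meta)
  write_instrument_dta(r1, p2)
  expect_identical(readLines(p1), readLines(p2))
  r2 <- read_instrument_dta(p2, meta = s$meta)
  expect_identical(r1$zmag_ohm, r2$zmag_ohm)
  expect_identical(r1$zphz_deg, r2$zphz_deg)
  expect_identical(r1$zmag_ohm, s$zmag_ohm)
})

test_that("to_complex matches polar definition and round-trips", {
  s <- eis_spectrum(c(1, 10), c(100, 100), c(0, -90))
  z <- to_complex(s)
  expect_equal(z[1], 100 + 0i)
  expect_equal(z[2], 0 - 100i, tolerance = 1e-10)

  set.seed(3)
  g <- sort(10^runif(20, 0, 6))
  s <- eis_spectrum(g, 10^runif(20, 1, 9), runif(20, -180, 180))
  back <- from_complex(g, to_complex(s))
  expect_equal(back$zmag_ohm, s$zmag_ohm, tolerance = 1e-12)
  expect_equal(back$zphz_deg, s$zphz_deg, tolerance = 1e-12)
})

test_that("cohort container round-trips through a directory", {
  cohort <- tiny_cohort()
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_setequal(names(back$spectra), names(cohort$spectra))
  k <- names(cohort$spectra)[5]
  expect_identical(back$spectra[[k]]$zmag_ohm, cohort$spectra[[k]]$zmag_ohm)
  expect_identical(back$spectra[[k]]$meta$array_type,
                   cohort$spectra[[k]]$meta$array_type)
  expect_equal(nrow(back$truth), nrow(cohort$truth))
})
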