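test_that("band features match hand-computed values", {
  s <- flat_spectrum(zmag = 1e7, phase = -50)
  ft <- extract_features(s)
  expect_equal(ft$mean_phase_lt100, -50)
  expect_equal(ft$max_abs_dphase, 0)
  expect_equal(ft$mean_zmag_lt100, 1e7)

  s2 <- eis_spectrum(c(10, 100, 1000), c(1, 1, 1), c(-10, -40, -80))
  expect_equal(extract_features(s2)$max_abs_dphase, 40)
})

test_that("band boundaries: < 100 Hz strict, 100 Hz - 50 kHz closed, > 10 kHz strict", {
  g <- default_grid
  ph <- rep(-50, 31)
  ph[g == 100] <- -1           # on the closed-band edge, outside the low band
  s <- eis_spectrum(g, rep(1e6, 31), ph)
  ft <- extract_features(s)
  expect_equal(ft$mean_phase_lt100, -50)       # 100 Hz excluded (strict)
  expect_equal(ft$max_phase_100_50k, -1)       # 100 Hz included (closed)
  expect_equal(ft$max_phase_100_10k, -1)
  # 10^4.7 Hz > 50 kHz belongs to the >50 kHz band, not the closed one
  ph2 <- rep(-50, 31); ph2[g > 5e4 & g < 1e5] <- -2
  ft2 <- extract_features(eis_spectrum(g, rep(1e6, 31), ph2))
  expect_equal(ft2$max_phase_100_50k, -50)
  expect_gt(ft2$mean_phase_gt50k, -50)
})

test_that("printed rule examples classify as stated", {
  # all four hockey-stick conditions hold
  ft <- make_features(mean_zmag_lt100 = 5e6, mean_phase_lt100 = -60,
                      max_phase_100_50k = -10, max_phase_100_10k = -10)
  expect_equal(classify_spectrum(ft, "IROX")$category, "hockey_stick")

  # iridium-oxide outlier threshold
  ft <- make_features(mean_zmag_lt100 = 3e9)
  expect_equal(classify_spectrum(ft, "IROX")$category, "outlier")
  # below it, the platinum threshold must not fire for iridium oxide
  ft <- make_features(mean_zmag_lt100 = 3e8, mean_phase_lt100 = -20)
  expect_equal(classify_spectrum(ft, "IROX")$category, "mixed")
  expect_equal(classify_spectrum(ft, "PT")$category, "outlier")

  # failing every rule set falls through to mixed
  ft <- make_features(mean_zmag_lt100 = 1e7, mean_phase_lt100 = -38,
                      max_phase_100_50k = -35, max_phase_100_10k = -35)
  expect_equal(classify_spectrum(ft, "IROX")$category, "mixed")

  # single-condition ski-slope branch
  ft <- make_features(mean_phase_lt100 = -60, max_phase_100_50k = -50,
                      max_phase_100_10k = -50, mean_phase_gt10k = -85,
                      mean_phase_gt50k = -85)
  expect_equal(classify_spectrum(ft, "IROX")$category, "ski_slope")
})

test_that("hockey-stick rule is gated to iridium oxide; Pt ski-slope flagged", {
  ft <- make_features(mean_zmag_lt100 = 5e6, mean_phase_lt100 = -60,
                      max_phase_100_50k = -10, max_phase_100_10k = -10)
  expect_equal(classify_spectrum(ft, "PT")$category, "mixed")
  ft <- make_features(mean_phase_gt10k = -85)
  lab <- classify_spectrum(ft, "PT")
  expect_equal(lab$category, "ski_slope")
  expect_match(lab$note, "low-confidence")
})

test_that("rule engine agrees with brute-force oracle on 1000 random features", {
  set.seed(19)
  for (k in 1:1000) {
    ft <- make_features(mean_zmag_lt100 = 10^runif(1, 4, 10.5),
                        mean_phase_lt100 = runif(1, -95, 5),
                        max_phase_100_50k = runif(1, -95, 5),
                        max_phase_100_10k = runif(1, -95, 5),
                        mean_phase_gt10k = runif(1, -95, 5),
                        mean_phase_gt50k = runif(1, -95, 5),
                        max_abs_dphase = runif(1, 0, 60))
    typ <- if (k %% 2) "IROX" else "PT"
    expect_identical(classify_spectrum(ft, typ)$category,
                     brute_force_classify(ft, typ))
  }
})

test_that("magnitude scaling only moves magnitude-gated rules", {
  set.seed(23)
  for (k in 1:200) {
    ft <- make_features(mean_zmag_lt100 = 10^runif(1, 4, 9),
                        mean_phase_lt100 = runif(1, -95, 5),
                        max_phase_100_50k = runif(1, -95, 5),
                        max_phase_100_10k = runif(1, -95, 5),
                        mean_phase_gt10k = runif(1, -95, 5),
                        mean_phase_gt50k = runif(1, -95, 5),
                        max_abs_dphase = runif(1, 0, 60))
    ft10 <- ft; ft10$mean_zmag_lt100 <- 10 * ft$mean_zmag_lt100
    a <- classify_spectrum(ft, "IROX")$category
    b <- classify_spectrum(ft10, "IROX")$category
    if (a != b)
      expect_true(b == "outlier" || a == "hockey_stick")
  }
})

test_that("classification requires the bands each rule needs", {
  s <- eis_spectrum(c(200, 2000), c(1e6, 1e5), c(-60, -10))  # nothing < 100 Hz
  expect_error(classify_spectrum(s, "IROX"), "< 100 Hz")
})

test_that("determinism and totality on simulated spectra", {
  lib <- archetype_library()
  for (i in seq_len(nrow(lib))) {
    r <- lib[i, ]
    s <- simulate_spectrum(archetype_params(r$array_type, r$category,
                                            r$condition))
    l1 <- classify_spectrum(s, r$array_type)
    l2 <- classify_spectrum(s, r$array_type)
    expect_identical(l1$category, l2$category)
    expect_true(l1$category %in% c("hockey_stick", "ski_slope", "mixed",
                                   "outlier"))
  }
})

test_that("cohort classification is total and matches scripted truth when noiseless", {
  cohort <- tiny_cohort()
  labels <- classify_cohort(cohort)
  expect_equal(nrow(labels), length(cohort$spectra))
  expect_equal(nrow(attr(labels, "errors")), 0)
  m <- merge(labels, cohort$truth,
             by = c("array_id", "channel", "session"))
  expect_equal(nrow(m), nrow(labels))
  expect_true(all(m$category.x == m$category.y))

  empty <- eis_cohort(list())
  expect_equal(nrow(classify_cohort(empty)), 0)
})

test_that("manual overrides set provenance and report the fraction", {
  cohort <- tiny_cohort()
  labels <- classify_cohort(cohort)
  same <- apply_overrides(labels, NULL)
  expect_equal(attr(same, "override_fraction"), 0)
  expect_identical(same$category, labels$category)

  led <- data.frame(array_id = labels$array_id[1], channel = labels$channel[1],
                    session = labels$session[1], new_category = "outlier",
                    note = "visual: open circuit")
  out <- apply_overrides(labels, led)
  expect_equal(out$category[1], "outlier")
  expect_equal(out$provenance[1], "manual")
  expect_identical(out$category[-1], labels$category[-1])
  expect_equal(attr(out, "override_fraction"), 1 / nrow(labels))

  led$array_id <- "nonexistent"
  expect_error(apply_overrides(labels, led), "unknown key")
})
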