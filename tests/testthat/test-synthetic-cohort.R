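test_that("archetype library carries the published group means", {
  lib <- archetype_library()
  hs <- lib[lib$array_type == "IROX" & lib$category == "hockey_stick" &
            lib$condition == "in_vivo", ]
  expect_equal(hs$n, 0.64)
  expect_equal(hs$R_S, 138e3)
  expect_equal(hs$Q, 30e-8)
  expect_equal(hs$R_E, 6.2e10)
  pm <- lib[lib$array_type == "PT" & lib$category == "mixed" &
            lib$condition == "in_vivo", ]
  expect_equal(pm$n, 0.55)
  expect_equal(pm$R_S, 25e3)
  # no in-vitro outliers were observed; the library has none
  expect_false(any(lib$category == "outlier" & lib$condition == "in_vitro"))
  # every chosen element is marked as such
  expect_true(all(lib$q_provenance %in% c("table", "chosen")))
})

test_that("label closure: every archetype classifies as its own category", {
  lib <- archetype_library()
  for (i in seq_len(nrow(lib))) {
    r <- lib[i, ]
    s <- simulate_spectrum(archetype_params(r$array_type, r$category,
                                            r$condition))
    expect_identical(classify_spectrum(s, r$array_type)$category, r$category,
                     label = sprintf("%s %s %s", r$array_type, r$category,
                                     r$condition))
  }
})

test_that("fit closure: noiseless Randles-only archetypes recover Q, n, R_S", {
  lib <- archetype_library()
  for (i in seq_len(nrow(lib))) {
    r <- lib[i, ]
    p <- archetype_params(r$array_type, r$category, r$condition,
                          extended = FALSE)
    fit <- fit_randles(simulate_spectrum(p))
    expect_equal(fit$params$Q, p$Q, tolerance = 0.005)
    expect_equal(fit$params$n, p$n, tolerance = 0.005)
    expect_equal(fit$params$R_S, p$R_S, tolerance = 0.005)
  }
})

test_that("noise model: zero noise is the identity, same seed reproduces", {
  s <- simulate_spectrum(archetype_params("PT", "mixed", "in_vivo"))
  expect_identical(apply_noise(s, noise_model(0, 0)), s)
  nm <- noise_model(0.05, 3)
  set.seed(9); a <- apply_noise(s, nm)
  set.seed(9); b <- apply_noise(s, nm)
  expect_identical(a$zmag_ohm, b$zmag_ohm)
  expect_identical(a$zphz_deg, b$zphz_deg)
})

test_that("noise law matches the half-normal median in log10 magnitude", {
  s <- flat_spectrum(zmag = 1e6, phase = -45,
                     grid = make_frequency_grid(5, 1, 100))
  set.seed(13)
  nm <- noise_model(sigma_logmag = 0.05, sigma_phase = 0)
  devs <- replicate(1000, abs(log10(apply_noise(s, nm)$zmag_ohm[1]) - 6))
  # median of |N(0, sigma)| is sigma * qnorm(0.75)
  expect_equal(median(devs), 0.05 * qnorm(0.75), tolerance = 0.08)
})

test_that("channel series: noiseless equals archetype simulation; seeded runs repeat", {
  script <- data.frame(session = c("in_vitro", "week_2"),
                       category = c("hockey_stick", "mixed"))
  meta_fn <- function(ses) make_meta(session = ses)
  out <- simulate_channel_series(script, meta_fn)
  ref <- simulate_spectrum(archetype_params("IROX", "hockey_stick", "in_vitro"),
                           meta = make_meta())
  expect_identical(out[[1]]$zmag_ohm, ref$zmag_ohm)

  nm <- noise_model(0.05, 3)
  a <- simulate_channel_series(script, meta_fn, nm, seed = 4)
  b <- simulate_channel_series(script, meta_fn, nm, seed = 4)
  expect_identical(a[[2]]$zmag_ohm, b[[2]]$zmag_ohm)
})

test_that("default cohort mirrors the study structure", {
  cfg <- cohort_config()
  expect_length(cfg$arrays, 11)
  types <- vapply(cfg$arrays, `[[`, "", "array_type")
  expect_equal(sum(types == "IROX"), 5)
  expect_equal(sum(types == "PT"), 6)
  # whole-array failure: the ski-failure preset stops at week 8
  sc <- trajectory_preset("irox_ski_failure")
  expect_false(any(sc$session %in% paste0("week_", 9:12)))
  expect_true(all(sc$category[sc$session == "week_8"] == "ski_slope"))
  # in-vitro sessions never carry outliers (none existed in vitro)
  for (arr in cfg$arrays)
    expect_false(any(arr$script$category[arr$script$session == "in_vitro"]
                     == "outlier"))
})

test_that("one-spectrum config produces a one-spectrum dataset", {
  cfg <- cohort_config(n_irox = 1, n_pt = 0, channels = 1, weeks = 2)
  cfg$arrays[[1]]$script <-
    data.frame(channel = 1, session = "in_vitro", category = "hockey_stick")
  d <- simulate_cohort(cfg, seed = 1)
  expect_length(d$spectra, 1)
  expect_equal(d$truth$category, "hockey_stick")
})

test_that("simulate_cohort is deterministic for a fixed seed", {
  nm <- noise_model(0.05, 3)
  a <- tiny_cohort(noise = nm, seed = 7)
  b <- tiny_cohort(noise = nm, seed = 7)
  k <- names(a$spectra)[3]
  expect_identical(a$spectra[[k]]$zmag_ohm, b$spectra[[k]]$zmag_ohm)
})
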