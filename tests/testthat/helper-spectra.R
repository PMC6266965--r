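# shared fixtures, built in code

default_grid <- make_frequency_grid(5, 1, 1e6)

make_meta <- function(array_id = "a1", channel = 1, array_type = "IROX",
                      session = "in_vitro") {
  session_meta(array_id, channel, array_type, session)
}

# constant-phase flat spectrum
flat_spectrum <- function(zmag = 1e7, phase = -50, grid = default_grid,
                          meta = NULL) {
  eis_spectrum(grid, rep(zmag, length(grid)), rep(phase, length(grid)),
               meta = meta)
}

# a tiny two-array cohort with known categories
tiny_cohort <- function(noise = noise_model(), seed = 1) {
  cfg <- cohort_config(n_irox = 1, n_pt = 1, channels = 1:4, weeks = 2:3,
                       noise = noise)
  simulate_cohort(cfg, seed = seed)
}

# features object with explicit fields, for rule-engine tests
make_features <- function(mean_zmag_lt100 = 1e6, mean_phase_lt100 = -60,
                          max_phase_100_50k = -10, max_phase_100_10k = -10,
                          mean_phase_gt10k = -10, mean_phase_gt50k = -5,
                          max_abs_dphase = 10) {
  structure(list(mean_zmag_lt100 = mean_zmag_lt100,
                 mean_phase_lt100 = mean_phase_lt100,
                 max_phase_100_50k = max_phase_100_50k,
                 max_phase_100_10k = max_phase_100_10k,
                 mean_phase_gt10k = mean_phase_gt10k,
                 mean_phase_gt50k = mean_phase_gt50k,
                 max_abs_dphase = max_abs_dphase),
            class = "spectrum_features")
}

# independently coded brute-force evaluation of the printed inequalities,
# used as the oracle for the rule engine
brute_force_classify <- function(ft, array_type) {
  out_thr <- c(IROX = 2e9, PT = 1e8)[[array_type]]
  if (ft$mean_zmag_lt100 > out_thr) return("outlier")
  if (array_type == "IROX") {
    c1 <- ft$mean_zmag_lt100 < 8e6
    c2 <- (-80 < ft$mean_phase_lt100) && (ft$mean_phase_lt100 < -40)
    c3 <- ft$max_phase_100_50k > -30
    c4 <- abs(ft$max_phase_100_10k - ft$mean_phase_lt100) > 25
    if (c1 && c2 && c3 && c4) return("hockey_stick")
  }
  s1 <- ft$mean_phase_gt10k < -80
  s2 <- (ft$mean_phase_lt100 > -35) && (ft$mean_phase_gt50k < -70) &&
    (ft$max_abs_dphase > 25)
  if (s1 || s2) return("ski_slope")
  "mixed"
}
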