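#' Measurement noise model
#'
#' Multiplicative log-normal noise on magnitude and additive Gaussian noise on
#' phase, independent across points and between magnitude and phase.  The
#' magnitude perturbation is `|Z| * 10^e` with `e ~ N(0, sigma_logmag)` (so
#' `sigma_logmag` is in decades and positivity is preserved); the phase
#' perturbation is `phi + N(0, sigma_phase)` degrees, clamped to
#' \[-180, 180\].
#'
#' @param sigma_logmag Standard deviation of the log10-magnitude noise
#'   (decades, >= 0).
#' @param sigma_phase Standard deviation of the phase noise (degrees, >= 0).
#' @return Named list of class `"noise_model"`.
#' @export
noise_model <- function(sigma_logmag = 0, sigma_phase = 0) {
  if (sigma_logmag < 0 || sigma_phase < 0)
    stop("noise standard deviations must be >= 0", call. = FALSE)
  structure(list(sigma_logmag = sigma_logmag, sigma_phase = sigma_phase),
            class = "noise_model")
}

#' Apply measurement noise to a spectrum
#'
#' Uses the current RNG state; seed via `set.seed()` or the `seed` arguments
#' of the simulators for reproducibility.
#'
#' @param s An [eis_spectrum()].
#' @param noise A [noise_model()].
#' @return A noisy [eis_spectrum()].
#' @export
apply_noise <- function(s, noise) {
  stopifnot(inherits(s, "eis_spectrum"), inherits(noise, "noise_model"))
  if (noise$sigma_logmag == 0 && noise$sigma_phase == 0) return(s)
  k <- length(s$freq_hz)
  mag <- s$zmag_ohm * 10^rnorm(k, 0, noise$sigma_logmag)
  ph <- pmin(pmax(s$zphz_deg + rnorm(k, 0, noise$sigma_phase), -180), 180)
  eis_spectrum(s$freq_hz, mag, ph, meta = s$meta)
}

# internal: condition implied by a session code
session_condition <- function(session) {
  ifelse(session == "in_vitro", "in_vitro", "in_vivo")
}

#' Simulate one channel's longitudinal spectrum series
#'
#' @param script Data frame with columns `session` and `category`; one row per
#'   measured session of the channel, in any order.
#' @param meta_fn Function `(session) -> session_meta` supplying metadata.
#' @param noise A [noise_model()].
#' @param grid Frequency grid.
#' @param seed Optional integer; when given, seeds the RNG for the series.
#' @return List of [eis_spectrum()] in session order.
#' @export
simulate_channel_series <- function(script, meta_fn, noise = noise_model(),
                                    grid = make_frequency_grid(),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  script <- script[order(session_rank(script$session)), , drop = FALSE]
  lapply(seq_len(nrow(script)), function(i) {
    ses <- script$session[i]
    meta <- meta_fn(ses)
    p <- archetype_params(meta$array_type, script$category[i],
                          session_condition(ses))
    apply_noise(simulate_spectrum(p, grid, meta = meta), noise)
  })
}

# ---- trajectory scripts -----------------------------------------------------

# A trajectory script assigns, for one array, a category to every
# (channel, session) pair that is measured; unmeasured sessions are simply
# absent.  Scripts are built from per-channel category timelines.

script_from_timeline <- function(channels, sessions, assign_fn) {
  rows <- list()
  for (ch in channels) for (ses in sessions) {
    cat <- assign_fn(ch, ses)
    if (!is.na(cat))
      rows[[length(rows) + 1L]] <- data.frame(channel = ch, session = ses,
                                              category = cat,
                                              stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Named longitudinal trajectory presets
#'
#' Scripted per-array category timelines reproducing the failure narratives of
#' the study: whole-array transitions to ski-slope followed by loss of the
#' array, early hockey-stick to mixed conversion, late whole-array outlier
#' conversion for platinum, and stable arrays.  Sessions are the in-vitro
#' baseline, the ~1 h post-op check and weeks 2..12; channels 1..16.
#'
#' @param preset Preset name, see Details.
#' @param channels Channel numbers.
#' @param weeks Week numbers of the weekly sessions.
#' @return Data frame with columns `channel`, `session`, `category` (measured
#'   sessions only).
#'
#' @details Presets (categories refer to scripted ground truth):
#' \describe{
#'   \item{`irox_ski_failure`}{15/16 hockey-stick in vitro (one mixed); one
#'     channel becomes an outlier at implantation; all sites ski-slope at week
#'     8; array unmeasured from week 9 (failure).}
#'   \item{`irox_mixed_transition`}{hockey-stick baseline; 15 sites switch to
#'     mixed at week 3 and remain mixed; array fails after week 10.}
#'   \item{`irox_varied`}{hockey-stick baseline; two mixed at week 2; three
#'     outliers and five mixed during weeks 5-9; all hockey-stick from week
#'     10.}
#'   \item{`irox_ski_baseline`}{three channels ski-slope from the in-vitro
#'     baseline onward, the rest hockey-stick converting to mixed at week 6.}
#'   \item{`pt_outlier_failure`}{all mixed until week 7; every site an outlier
#'     from week 8.}
#'   \item{`pt_stable`}{all mixed at every session.}
#'   \item{`pt_late_outliers`}{mixed, with two channels becoming outliers from
#'     week 9.}
#' }
#' @export
trajectory_preset <- function(preset, channels = 1:16, weeks = 2:12) {
  sessions <- c("in_vitro", "post_op_1h", paste0("week_", weeks))
  wk <- function(ses) if (grepl("^week_", ses))
    as.integer(sub("week_", "", ses)) else NA_integer_
  assign_fn <- switch(preset,
    irox_ski_failure = function(ch, ses) {
      w <- wk(ses)
      if (!is.na(w) && w >= 9) return(NA_character_)  # array failed
      if (!is.na(w) && w == 8) return("ski_slope")
      if (ch == 16) return("mixed")
      if (ch == 15 && ses != "in_vitro") return("outlier")
      "hockey_stick"
    },
    irox_mixed_transition = function(ch, ses) {
      w <- wk(ses)
      if (!is.na(w) && w >= 11) return(NA_character_)
      if (ch == 16) return("mixed")
      if (!is.na(w) && w >= 3) return("mixed")
      "hockey_stick"
    },
    irox_varied = function(ch, ses) {
      w <- wk(ses)
      if (is.na(w)) return("hockey_stick")
      if (w >= 10) return("hockey_stick")
      if (w >= 5) {
        if (ch <= 3) return("outlier")
        if (ch <= 8) return("mixed")
        return("hockey_stick")
      }
      if (ch <= 2) return("mixed")
      "hockey_stick"
    },
    irox_ski_baseline = function(ch, ses) {
      w <- wk(ses)
      if (ch <= 3) return("ski_slope")
      if (!is.na(w) && w >= 6) return("mixed")
      "hockey_stick"
    },
    pt_outlier_failure = function(ch, ses) {
      w <- wk(ses)
      if (!is.na(w) && w >= 8) return("outlier")
      "mixed"
    },
    pt_stable = function(ch, ses) "mixed",
    pt_late_outliers = function(ch, ses) {
      w <- wk(ses)
      if (ch <= 2 && !is.na(w) && w >= 9) return("outlier")
      "mixed"
    },
    stop("unknown trajectory preset: ", preset, call. = FALSE))
  script_from_timeline(channels, sessions, assign_fn)
}

#' Default cohort configuration
#'
#' Mirrors the study design: five iridium-oxide and six platinum 16-channel
#' arrays, measured in vitro, ~1 h post-op and weekly over weeks 2-12, with
#' scripted category trajectories including whole-array failures.
#'
#' @param n_irox,n_pt Number of arrays per cohort.
#' @param channels Channel numbers per array.
#' @param weeks Week numbers of the weekly sessions.
#' @param noise A [noise_model()]; the default is noiseless.
#' @return List of class `"cohort_config"` with one entry per array:
#'   `array_id`, `array_type`, `script`.
#' @export
cohort_config <- function(n_irox = 5, n_pt = 6, channels = 1:16,
                          weeks = 2:12, noise = noise_model()) {
  irox_presets <- c("irox_ski_failure", "irox_mixed_transition",
                    "irox_varied", "irox_ski_baseline", "irox_varied")
  pt_presets <- c("pt_outlier_failure", "pt_stable", "pt_late_outliers",
                  "pt_outlier_failure", "pt_stable", "pt_late_outliers")
  arrays <- list()
  for (i in seq_len(n_irox)) {
    preset <- irox_presets[(i - 1L) %% length(irox_presets) + 1L]
    arrays[[length(arrays) + 1L]] <-
      list(array_id = sprintf("irox%02d", i), array_type = "IROX",
           preset = preset,
           script = trajectory_preset(preset, channels, weeks))
  }
  for (i in seq_len(n_pt)) {
    preset <- pt_presets[(i - 1L) %% length(pt_presets) + 1L]
    arrays[[length(arrays) + 1L]] <-
      list(array_id = sprintf("pt%02d", i), array_type = "PT",
           preset = preset,
           script = trajectory_preset(preset, channels, weeks))
  }
  structure(list(arrays = arrays, channels = channels, weeks = weeks,
                 noise = noise), class = "cohort_config")
}

#' Simulate a labelled synthetic cohort
#'
#' Simulates every scripted (array, channel, session) spectrum from the
#' archetype library, applies measurement noise and attaches the scripted
#' categories as ground-truth labels.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; all randomness flows from it.
#' @param grid Frequency grid.
#' @return An [eis_cohort()] with `truth` labels.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1,
                            grid = make_frequency_grid()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  spectra <- list(); truth <- list()
  for (arr in config$arrays) {
    sc <- arr$script
    sc <- sc[order(sc$channel, session_rank(sc$session)), , drop = FALSE]
    blocks <- lapply(seq_len(nrow(sc)), function(i) {
      meta <- session_meta(arr$array_id, sc$channel[i], arr$array_type,
                           sc$session[i])
      p <- archetype_params(arr$array_type, sc$category[i],
                            session_condition(sc$session[i]))
      apply_noise(simulate_spectrum(p, grid, meta = meta), config$noise)
    })
    spectra <- c(spectra, blocks)
    truth[[length(truth) + 1L]] <-
      data.frame(array_id = arr$array_id, channel = sc$channel,
                 session = sc$session, category = sc$category,
                 stringsAsFactors = FALSE)
  }
  eis_cohort(spectra, truth = do.call(rbind, truth))
}
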