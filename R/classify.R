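#' Category labels
#'
#' The four spectrum categories and the columns of a label table.
#' @keywords internal
#' @name categories
NULL

CATEGORIES <- c("hockey_stick", "ski_slope", "mixed", "outlier")

#' Band statistics used by the rule-based classifier
#'
#' Computes the scalar features the classification rules test.  Band means are
#' arithmetic means over grid points satisfying the band predicate; maxima are
#' maxima over points in the band; `max_abs_dphase` is the maximum absolute
#' difference between phases at successive grid frequencies.  The low band is
#' `f < 100 Hz` (strict); the maximum bands are the closed intervals
#' 100 Hz - 50 kHz and 100 Hz - 10 kHz; the high bands are `f > 10 kHz` and
#' `f > 50 kHz` (strict).  A feature whose band contains no grid point is
#' `NA`.
#'
#' @param s An [eis_spectrum()].
#' @return Named list of class `"spectrum_features"` with elements
#'   `mean_zmag_lt100`, `mean_phase_lt100`, `max_phase_100_50k`,
#'   `max_phase_100_10k`, `mean_phase_gt10k`, `mean_phase_gt50k`,
#'   `max_abs_dphase`.
#' @export
extract_features <- function(s) {
  stopifnot(inherits(s, "eis_spectrum"))
  f <- s$freq_hz; m <- s$zmag_ohm; ph <- s$zphz_deg
  if (!length(f)) stop("empty spectrum", call. = FALSE)
  band <- function(x, sel, fun) if (any(sel)) fun(x[sel]) else NA_real_
  structure(list(
    mean_zmag_lt100  = band(m, f < 100, mean),
    mean_phase_lt100 = band(ph, f < 100, mean),
    max_phase_100_50k = band(ph, f >= 100 & f <= 5e4, max),
    max_phase_100_10k = band(ph, f >= 100 & f <= 1e4, max),
    mean_phase_gt10k = band(ph, f > 1e4, mean),
    mean_phase_gt50k = band(ph, f > 5e4, mean),
    max_abs_dphase   = if (length(ph) > 1) max(abs(diff(ph))) else 0
  ), class = "spectrum_features")
}

#' Classification rule thresholds
#'
#' All thresholds of the rule engine, with the published defaults, exposed as
#' configuration so sensitivity analyses need no code edits.  Comparisons are
#' strict, exactly as printed.
#'
#' @param outlier_zmag_pt Outlier threshold on `mean(|Z| < 100 Hz)` for
#'   platinum arrays, ohm.
#' @param outlier_zmag_irox Same for iridium-oxide arrays, ohm.
#' @param hs_zmag Hockey-stick condition 1: `mean(|Z| < 100 Hz)` upper bound.
#' @param hs_phase_lo,hs_phase_hi Hockey-stick condition 2: open interval for
#'   `mean(phase < 100 Hz)`, degrees.
#' @param hs_max_50k Hockey-stick condition 3: lower bound for
#'   `max(phase, 100 Hz - 50 kHz)`, degrees.
#' @param hs_delta Hockey-stick condition 4: lower bound for
#'   `|max(phase, 100 Hz - 10 kHz) - mean(phase < 100 Hz)|`, degrees.
#' @param ski_gt10k Ski-slope single-condition branch: upper bound for
#'   `mean(phase > 10 kHz)`, degrees.
#' @param ski_phase_lo Ski-slope branch 2 condition 1: lower bound for
#'   `mean(phase < 100 Hz)`, degrees.
#' @param ski_gt50k Ski-slope branch 2 condition 2: upper bound for
#'   `mean(phase > 50 kHz)`, degrees.
#' @param ski_dphase Ski-slope branch 2 condition 3: lower bound for
#'   `max(|delta phase|)`, degrees.
#' @return Named list of class `"eis_rules"`.
#' @export
eis_rules <- function(outlier_zmag_pt = 1e8, outlier_zmag_irox = 2e9,
                      hs_zmag = 8e6, hs_phase_lo = -80, hs_phase_hi = -40,
                      hs_max_50k = -30, hs_delta = 25,
                      ski_gt10k = -80, ski_phase_lo = -35, ski_gt50k = -70,
                      ski_dphase = 25) {
  structure(as.list(environment()), class = "eis_rules")
}

need_feature <- function(f, nm, band) {
  v <- f[[nm]]
  if (is.na(v))
    stop(sprintf("cannot classify: no grid frequencies in band %s", band),
         call. = FALSE)
  v
}

#' Classify one spectrum's features into a category
#'
#' Applies the published rules in fixed precedence: outlier first, then (for
#' iridium-oxide arrays only) hockey-stick, then ski-slope, with mixed as the
#' default.  The ski-slope rule is written for iridium-oxide arrays; when it
#' fires for a platinum array the label is flagged low-confidence in `note`.
#'
#' @param f A [extract_features()] result (or an [eis_spectrum()], which is
#'   reduced first).
#' @param array_type `"IROX"` or `"PT"`.
#' @param rules An [eis_rules()] configuration.
#' @return List of class `"category_label"`: `category`, `provenance`
#'   (`"auto"`), `note`.
#' @export
classify_spectrum <- function(f, array_type = c("IROX", "PT"),
                              rules = eis_rules()) {
  array_type <- match.arg(array_type)
  if (inherits(f, "eis_spectrum")) f <- extract_features(f)
  stopifnot(inherits(f, "spectrum_features"))
  label <- function(category, note = "")
    structure(list(category = category, provenance = "auto", note = note),
              class = "category_label")

  mz_lo <- need_feature(f, "mean_zmag_lt100", "< 100 Hz")
  thr_out <- if (array_type == "PT") rules$outlier_zmag_pt else rules$outlier_zmag_irox
  if (mz_lo > thr_out) return(label("outlier"))

  if (array_type == "IROX") {
    ph_lo <- need_feature(f, "mean_phase_lt100", "< 100 Hz")
    mx50 <- need_feature(f, "max_phase_100_50k", "100 Hz - 50 kHz")
    mx10 <- need_feature(f, "max_phase_100_10k", "100 Hz - 10 kHz")
    if (mz_lo < rules$hs_zmag &&
        ph_lo > rules$hs_phase_lo && ph_lo < rules$hs_phase_hi &&
        mx50 > rules$hs_max_50k &&
        abs(mx10 - ph_lo) > rules$hs_delta)
      return(label("hockey_stick"))
  }

  gt10k <- need_feature(f, "mean_phase_gt10k", "> 10 kHz")
  ph_lo <- need_feature(f, "mean_phase_lt100", "< 100 Hz")
  gt50k <- need_feature(f, "mean_phase_gt50k", "> 50 kHz")
  if (gt10k < rules$ski_gt10k ||
      (ph_lo > rules$ski_phase_lo && gt50k < rules$ski_gt50k &&
       f$max_abs_dphase > rules$ski_dphase)) {
    note <- if (array_type == "PT")
      "low-confidence: ski-slope rule defined for iridium-oxide arrays" else ""
    return(label("ski_slope", note))
  }
  label("mixed")
}

#' Classify every spectrum in a cohort
#'
#' Applies [classify_spectrum()] to each spectrum.  Per-spectrum
#' classification errors do not abort the run; they are collected in the
#' `"errors"` attribute of the result and the affected rows are omitted.
#'
#' @param cohort An [eis_cohort()].
#' @param rules An [eis_rules()] configuration.
#' @return Data frame with columns `array_id`, `channel`, `session`,
#'   `category`, `provenance`, `note`; attribute `"errors"` is a data frame of
#'   keys that failed with their messages.
#' @export
classify_cohort <- function(cohort, rules = eis_rules()) {
  stopifnot(inherits(cohort, "eis_cohort"))
  rows <- list(); errs <- list()
  for (s in cohort$spectra) {
    res <- tryCatch(classify_spectrum(s, s$meta$array_type, rules),
                    error = function(e) e)
    if (inherits(res, "error")) {
      errs[[length(errs) + 1L]] <-
        data.frame(key = spectrum_key(s$meta), message = conditionMessage(res),
                   stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <-
        data.frame(array_id = s$meta$array_id, channel = s$meta$channel,
                   session = s$meta$session, category = res$category,
                   provenance = res$provenance, note = res$note,
                   stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(array_id = character(), channel = integer(),
               session = character(), category = character(),
               provenance = character(), note = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "errors") <- if (length(errs)) do.call(rbind, errs) else
    data.frame(key = character(), message = character(),
               stringsAsFactors = FALSE)
  out
}

#' Apply a manual-override ledger to a label table
#'
#' Mirrors the supervised correction workflow: automatic labels are reviewed
#' and a small fraction is corrected by hand.  Overridden rows get provenance
#' `"manual"` and the ledger's note; the override fraction is attached as the
#' `"override_fraction"` attribute.
#'
#' @param labels Label data frame from [classify_cohort()].
#' @param ledger Data frame with columns `array_id`, `channel`, `session`,
#'   `new_category` and optionally `note`.
#' @return The corrected label data frame.
#' @export
apply_overrides <- function(labels, ledger) {
  if (is.null(ledger) || nrow(ledger) == 0L) {
    attr(labels, "override_fraction") <- 0
    return(labels)
  }
  need <- c("array_id", "channel", "session", "new_category")
  if (!all(need %in% names(ledger)))
    stop("override ledger must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  bad <- !ledger$new_category %in% CATEGORIES
  if (any(bad))
    stop("unknown category in override ledger: ",
         paste(unique(ledger$new_category[bad]), collapse = ", "),
         call. = FALSE)
  lk <- label_keys(labels)
  ok <- label_keys(ledger)
  missing <- setdiff(ok, lk)
  if (length(missing))
    stop("override ledger references unknown key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  idx <- match(ok, lk)
  labels$category[idx] <- ledger$new_category
  labels$provenance[idx] <- "manual"
  if ("note" %in% names(ledger)) labels$note[idx] <- ledger$note
  attr(labels, "override_fraction") <- length(unique(idx)) / nrow(labels)
  labels
}
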