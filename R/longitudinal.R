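#' Impedance magnitude at 1 kHz
#'
#' Returns the raw sample when 1 kHz lies on the grid; otherwise interpolates
#' the magnitude log-log linearly between the bracketing grid points (spectra
#' are near power-law locally, so log-log interpolation avoids the bias of
#' linear interpolation on a coarse log grid).
#'
#' @param s An [eis_spectrum()].
#' @return Magnitude in ohm.
#' @export
impedance_at_1khz <- function(s) {
  stopifnot(inherits(s, "eis_spectrum"))
  f <- s$freq_hz
  hit <- which(f == 1e3)
  if (length(hit)) return(s$zmag_ohm[hit[1]])
  if (min(f) > 1e3 || max(f) < 1e3)
    stop("grid does not bracket 1 kHz", call. = FALSE)
  10^approx(log10(f), log10(s$zmag_ohm), xout = 3)$y
}

#' Frequency of the phase maximum
#'
#' The grid frequency at which the phase spectrum attains its maximum; ties
#' are broken toward the lowest frequency.  For intact low-impedance sites the
#' peak migrates to lower frequency as the access resistance grows.
#'
#' @param s An [eis_spectrum()].
#' @return Frequency in Hz.
#' @export
f_peak <- function(s) {
  stopifnot(inherits(s, "eis_spectrum"))
  s$freq_hz[which.max(s$zphz_deg)]
}

#' Category population table over sessions
#'
#' Counts channels per category per session.  Roster entries with no label at
#' a session (e.g. after whole-array failure, when spectra are no longer
#' collected) are counted in the `unmeasured` column, so each session's counts
#' sum to the roster size.
#'
#' @param labels Label data frame (see [classify_cohort()]).
#' @param roster Data frame of all `(array_id, channel)` pairs in the cohort.
#' @param sessions Character vector of session codes defining the column
#'   order; defaults to the sessions present in `labels`, ordered by
#'   [session_rank()].
#' @return Matrix `sessions x (categories + unmeasured)` of counts, with the
#'   roster size in attribute `"roster_size"`.
#' @export
population_table <- function(labels, roster, sessions = NULL) {
  if (is.null(sessions)) {
    sessions <- unique(labels$session)
    sessions <- sessions[order(session_rank(sessions))]
  }
  rk <- paste(roster$array_id, roster$channel, sep = "/")
  if (anyDuplicated(rk))
    stop("duplicate (array, channel) pairs in roster", call. = FALSE)
  cats <- c(CATEGORIES, "unmeasured")
  out <- matrix(0L, nrow = length(sessions), ncol = length(cats),
                dimnames = list(sessions, cats))
  for (ses in sessions) {
    lab <- labels[labels$session == ses, , drop = FALSE]
    lab <- lab[paste(lab$array_id, lab$channel, sep = "/") %in% rk, ,
               drop = FALSE]
    tab <- table(factor(lab$category, levels = CATEGORIES))
    out[ses, CATEGORIES] <- as.integer(tab)
    out[ses, "unmeasured"] <- length(rk) - nrow(lab)
  }
  attr(out, "roster_size") <- length(rk)
  out
}

#' Aggregate a per-channel metric by category and session
#'
#' Computes count, mean and standard error of the mean (SEM = sd/sqrt(count),
#' sample sd) per (category, session) cell.  Following the study's reporting
#' rule, mean and SEM are emitted only when more than three channels are
#' present in the cell; otherwise they are `NA`.
#'
#' @param values Data frame with columns `category`, `session` and `value`
#'   (one row per channel measurement).
#' @return Data frame with columns `category`, `session`, `count`, `mean`,
#'   `sem`, ordered by category then [session_rank()].
#' @export
aggregate_metric <- function(values) {
  need <- c("category", "session", "value")
  if (!all(need %in% names(values)))
    stop("`values` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!nrow(values))
    return(data.frame(category = character(), session = character(),
                      count = integer(), mean = numeric(), sem = numeric(),
                      stringsAsFactors = FALSE))
  key <- interaction(values$category, values$session, drop = TRUE)
  parts <- split(values, key)
  rows <- lapply(parts, function(d) {
    n <- nrow(d)
    emit <- n > 3
    data.frame(category = d$category[1], session = d$session[1], count = n,
               mean = if (emit) mean(d$value) else NA_real_,
               sem = if (emit) sd(d$value) / sqrt(n) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$category, session_rank(out$session)), ]
  rownames(out) <- NULL
  out
}

#' Per-channel longitudinal trajectories
#'
#' Combines labels with the 1 kHz magnitude and phase-peak frequency of every
#' spectrum into a long table ordered by session.
#'
#' @param cohort An [eis_cohort()].
#' @param labels Label data frame covering the cohort.
#' @return Data frame: `array_id`, `channel`, `array_type`, `session`,
#'   `category`, `z1k_ohm`, `f_peak_hz`.  `z1k_ohm` is `NA` when the grid does
#'   not bracket 1 kHz.
#' @export
channel_trajectories <- function(cohort, labels) {
  stopifnot(inherits(cohort, "eis_cohort"))
  lk <- label_keys(labels)
  rows <- lapply(cohort$spectra, function(s) {
    key <- spectrum_key(s$meta)
    i <- match(key, lk)
    z1k <- tryCatch(impedance_at_1khz(s), error = function(e) NA_real_)
    data.frame(array_id = s$meta$array_id, channel = s$meta$channel,
               array_type = s$meta$array_type, session = s$meta$session,
               category = if (is.na(i)) NA_character_ else labels$category[i],
               z1k_ohm = z1k, f_peak_hz = f_peak(s), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$array_id, out$channel, session_rank(out$session)), ]
  rownames(out) <- NULL
  out
}

#' Scale an areal CPE admittance to an electrode of given area
#'
#' Multiplies an admittance per unit area (S s^n mm^-2) by an electrode area
#' given in um^2 (converted to mm^2).
#'
#' @param q_areal Areal CPE admittance, S s^n mm^-2.
#' @param area_um2 Electrode area, um^2.
#' @return CPE admittance in S s^n.
#' @examples
#' scale_areal_admittance(27e-6, 4000)  # ~1.1e-7
#' @export
scale_areal_admittance <- function(q_areal, area_um2) {
  if (q_areal <= 0 || area_um2 <= 0)
    stop("inputs must be positive", call. = FALSE)
  q_areal * area_um2 * 1e-6
}

#' Scale an access resistance by the ratio of electrode areas
#'
#' Access resistance is inversely proportional to electrode area, so a value
#' reported for a reference area is divided by `area_new / area_ref`.
#'
#' @param r Access resistance, ohm, for the reference electrode.
#' @param area_ref Reference electrode area (any unit).
#' @param area_new Target electrode area (same unit).
#' @return Scaled access resistance, ohm.
#' @examples
#' scale_access_resistance(7380, 900, 4000)  # ~1660 ohm
#' @export
scale_access_resistance <- function(r, area_ref, area_new) {
  if (r <= 0 || area_ref <= 0 || area_new <= 0)
    stop("inputs must be positive", call. = FALSE)
  r / (area_new / area_ref)
}

#' Convert a CPE magnitude from s ohm^-1/n units to S s^n
#'
#' Values reported in the alternative unit system (s ohm^-1/n) are converted
#' by raising to the power `n`.
#'
#' @param q_alt CPE magnitude in s ohm^-1/n units (> 0).
#' @param n CPE exponent in (0, 1\].
#' @return CPE magnitude in S s^n.
#' @examples
#' convert_q_units(0.89e-9, 0.86)  # ~1.6e-8
#' @export
convert_q_units <- function(q_alt, n) {
  if (q_alt <= 0) stop("`q_alt` must be > 0", call. = FALSE)
  if (n <= 0 || n > 1) stop("`n` must lie in (0, 1]", call. = FALSE)
  q_alt^n
}
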