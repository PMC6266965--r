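#' Session identifiers
#'
#' Measurement sessions are categorical: an in-vitro (pre-implant) baseline, a
#' ~1 h post-operative check, then weekly sessions starting at week 2.  They
#' are encoded as character codes `"in_vitro"`, `"post_op_1h"`, `"week_<w>"`
#' and ordered by [session_rank()].
#'
#' @param kind One of `"in_vitro"`, `"post_op_1h"`, `"week"`.
#' @param week Integer week number (>= 2); required when `kind == "week"`.
#' @return A session code (character scalar).
#' @examples
#' session_time("week", 3)          # "week_3"
#' session_rank("post_op_1h")       # 1
#' @export
session_time <- function(kind = c("in_vitro", "post_op_1h", "week"), week = NULL) {
  kind <- match.arg(kind)
  if (kind == "week") {
    if (is.null(week) || length(week) != 1L || is.na(week) ||
        week != as.integer(week) || week < 2)
      stop("`week` must be an integer >= 2 when kind = \"week\"", call. = FALSE)
    return(paste0("week_", as.integer(week)))
  }
  if (!is.null(week))
    stop("`week` is only meaningful for kind = \"week\"", call. = FALSE)
  kind
}

#' @rdname session_time
#' @param session Character vector of session codes.
#' @return `session_rank()`: numeric ordering key (in-vitro = -1, 1 h = 0,
#'   week w = w), so that in_vitro < post_op_1h < week_2 < week_3 < ...
#' @export
session_rank <- function(session) {
  out <- rep(NA_real_, length(session))
  out[session == "in_vitro"] <- -1
  out[session == "post_op_1h"] <- 0
  wk <- grepl("^week_[0-9]+$", session)
  out[wk] <- as.numeric(sub("^week_", "", session[wk]))
  if (anyNA(out))
    stop("invalid session code(s): ",
         paste(unique(session[is.na(out)]), collapse = ", "), call. = FALSE)
  out
}

#' Session metadata for one channel measurement
#'
#' @param array_id Array identifier (character scalar).
#' @param channel Channel number, integer in 1..16.
#' @param array_type `"IROX"` (iridium oxide tips) or `"PT"` (platinum tips).
#' @param session Session code, see [session_time()].
#' @return A list of class `"session_meta"`.
#' @export
session_meta <- function(array_id, channel, array_type = c("IROX", "PT"),
                         session = "in_vitro") {
  array_type <- match.arg(array_type)
  if (length(channel) != 1L || is.na(channel) || channel != as.integer(channel) ||
      channel < 1 || channel > 16)
    stop("`channel` must be an integer in 1..16", call. = FALSE)
  session_rank(session)  # validates
  structure(list(array_id = as.character(array_id),
                 channel = as.integer(channel),
                 array_type = array_type, session = session),
            class = "session_meta")
}

#' One channel-session impedance spectrum
#'
#' Bundles a frequency grid with impedance magnitude (ohm) and phase (degrees,
#' negative = capacitive, stored as given and never wrapped) plus session
#' metadata.
#'
#' @param freq_hz Frequencies in Hz, strictly increasing, all > 0.
#' @param zmag_ohm Impedance magnitudes in ohm, all > 0, same length as grid.
#' @param zphz_deg Phases in degrees, within \[-180, 180\].
#' @param meta A [session_meta()] object (or NULL for anonymous spectra).
#' @return A list of class `"eis_spectrum"`.
#' @export
eis_spectrum <- function(freq_hz, zmag_ohm, zphz_deg, meta = NULL) {
  validate_grid(freq_hz)
  n <- length(freq_hz)
  if (length(zmag_ohm) != n || length(zphz_deg) != n)
    stop("`zmag_ohm` and `zphz_deg` must match the grid length", call. = FALSE)
  if (anyNA(zmag_ohm) || any(zmag_ohm <= 0))
    stop("all impedance magnitudes must be > 0", call. = FALSE)
  if (anyNA(zphz_deg) || any(zphz_deg < -180 | zphz_deg > 180))
    stop("all phases must lie in [-180, 180] degrees", call. = FALSE)
  if (!is.null(meta) && !inherits(meta, "session_meta"))
    stop("`meta` must be a session_meta object or NULL", call. = FALSE)
  structure(list(freq_hz = as.numeric(freq_hz), zmag_ohm = as.numeric(zmag_ohm),
                 zphz_deg = as.numeric(zphz_deg), meta = meta),
            class = "eis_spectrum")
}

#' @export
print.eis_spectrum <- function(x, ...) {
  rng <- range(x$freq_hz)
  cat(sprintf("<eis_spectrum> %d frequencies, %.3g-%.3g Hz\n",
              length(x$freq_hz), rng[1], rng[2]))
  if (!is.null(x$meta))
    cat(sprintf("  array %s channel %d (%s), session %s\n", x$meta$array_id,
                x$meta$channel, x$meta$array_type, x$meta$session))
  cat(sprintf("  |Z|: %.3g-%.3g ohm; phase: %.1f to %.1f deg\n",
              min(x$zmag_ohm), max(x$zmag_ohm), min(x$zphz_deg), max(x$zphz_deg)))
  invisible(x)
}

#' Convert a spectrum to complex impedances
#'
#' Element k is `zmag[k] * exp(1i * pi/180 * phase[k])`.
#'
#' @param spectrum An [eis_spectrum()].
#' @return Complex vector of impedances (ohm), one per grid frequency.
#' @export
to_complex <- function(spectrum) {
  stopifnot(inherits(spectrum, "eis_spectrum"))
  spectrum$zmag_ohm * exp(1i * spectrum$zphz_deg * pi / 180)
}

#' Build a spectrum from complex impedances
#'
#' Inverse of [to_complex()]: polar decomposition of a complex impedance
#' vector on a grid.
#'
#' @param freq_hz Frequency grid in Hz.
#' @param z Complex impedance vector.
#' @inheritParams eis_spectrum
#' @return An [eis_spectrum()].
#' @export
from_complex <- function(freq_hz, z, meta = NULL) {
  eis_spectrum(freq_hz, Mod(z), Arg(z) * 180 / pi, meta = meta)
}
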