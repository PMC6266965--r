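#' Read a spectrum from the package CSV dialect
#'
#' The CSV dialect is fixed: comma separator, `.` decimal, and a header with
#' the columns `frequency_hz`, `zmag_ohm`, `zphz_deg` (extra columns are
#' ignored).  Rows may appear in any order; they are sorted by frequency.
#'
#' @param source Path to a CSV file, or a connection.
#' @param meta Optional [session_meta()] attached to the returned spectrum.
#' @return An [eis_spectrum()].
#' @export
read_spectrum_csv <- function(source, meta = NULL) {
  df <- read.csv(source, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("frequency_hz", "zmag_ohm", "zphz_deg")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("spectrum CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  num <- lapply(need, function(cl) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]) | is.na(df[[cl]]))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at data row %d", cl, bad[1]),
           call. = FALSE)
    v
  })
  names(num) <- need
  dup <- which(duplicated(num$frequency_hz))
  if (length(dup))
    stop(sprintf("duplicate frequency %g at data row %d",
                 num$frequency_hz[dup[1]], dup[1]), call. = FALSE)
  ord <- order(num$frequency_hz)
  zero <- which(num$zmag_ohm <= 0)
  if (length(zero))
    stop(sprintf("non-positive magnitude at data row %d", zero[1]), call. = FALSE)
  eis_spectrum(num$frequency_hz[ord], num$zmag_ohm[ord], num$zphz_deg[ord],
               meta = meta)
}

#' Write a spectrum in the package CSV dialect
#'
#' @param spectrum An [eis_spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "eis_spectrum"))
  df <- data.frame(frequency_hz = format(spectrum$freq_hz, digits = 17),
                   zmag_ohm = format(spectrum$zmag_ohm, digits = 17),
                   zphz_deg = format(spectrum$zphz_deg, digits = 17))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an instrument-style tab-delimited export (ZCURVE table)
#'
#' Parses the text export dialect of potentiostat EIS runs: a tab-delimited
#' file containing a `ZCURVE` table whose header row includes the columns
#' `Freq`, `Zreal`, `Zimag` and, usually, `Zmod`, `Zphz`.  A units row after
#' the header is skipped if present.  Magnitude and phase are taken from
#' `Zmod`/`Zphz` when both are present, otherwise computed from
#' `Zreal`/`Zimag`.  If `Zmod` disagrees with `sqrt(Zreal^2 + Zimag^2)` by
#' more than 1%, a warning is issued and the magnitude is recomputed.
#'
#' @param source Path to the export file, or a connection.
#' @param meta Optional [session_meta()].
#' @return An [eis_spectrum()].
#' @export
read_instrument_dta <- function(source, meta = NULL) {
  lines <- readLines(source, warn = FALSE)
  start <- grep("^ZCURVE\\b", lines)
  if (length(start) == 0L)
    stop("no ZCURVE table found in instrument file", call. = FALSE)
  if (length(start) > 1L)
    stop("multiple ZCURVE tables found in instrument file", call. = FALSE)
  body <- lines[(start + 1L):length(lines)]
  if (!length(body))
    stop("ZCURVE table has no header row", call. = FALSE)
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  header <- trimws(header)
  if (!all(c("Freq", "Zreal", "Zimag") %in% header))
    stop("ZCURVE header must contain Freq, Zreal and Zimag columns",
         call. = FALSE)
  rows <- body[-1]
  parsed <- lapply(rows, function(ln) strsplit(ln, "\t", fixed = TRUE)[[1]])
  is_data <- vapply(parsed, function(p) {
    length(p) >= length(header) &&
      !is.na(suppressWarnings(as.numeric(p[match("Freq", header)])))
  }, logical(1))
  # a non-numeric row directly after the header is a units row; anything
  # non-numeric later terminates the table
  first_data <- which(is_data)[1]
  if (is.na(first_data))
    stop("ZCURVE table contains no data rows", call. = FALSE)
  run <- is_data
  if (first_data > 2L)
    stop("ZCURVE table contains no data rows", call. = FALSE)
  end <- which(!is_data & seq_along(is_data) > first_data)
  last_data <- if (length(end)) end[1] - 1L else length(rows)
  keep <- parsed[first_data:last_data]
  col <- function(nm) {
    idx <- match(nm, header)
    if (is.na(idx)) return(NULL)
    vapply(keep, function(p) suppressWarnings(as.numeric(p[idx])), numeric(1))
  }
  freq <- col("Freq"); zre <- col("Zreal"); zim <- col("Zimag")
  if (anyNA(freq) || anyNA(zre) || anyNA(zim))
    stop("non-numeric cell inside ZCURVE data rows", call. = FALSE)
  zmod <- col("Zmod"); zphz <- col("Zphz")
  mag_rc <- sqrt(zre^2 + zim^2)
  if (!is.null(zmod) && !is.null(zphz) && !anyNA(zmod) && !anyNA(zphz)) {
    bad <- abs(zmod - mag_rc) > 0.01 * mag_rc
    if (any(bad)) {
      warning("Zmod inconsistent with sqrt(Zreal^2 + Zimag^2) beyond 1%; ",
              "magnitude recomputed", call. = FALSE)
      zmod[bad] <- mag_rc[bad]
    }
    mag <- zmod; ph <- zphz
  } else {
    mag <- mag_rc
    ph <- atan2(zim, zre) * 180 / pi
  }
  ord <- order(freq)
  eis_spectrum(freq[ord], mag[ord], ph[ord], meta = meta)
}

#' Write a spectrum in the instrument-style tab-delimited dialect
#'
#' Produces a ZCURVE table that [read_instrument_dta()] reads back with every
#' numeric field preserved to full precision.
#'
#' @param spectrum An [eis_spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_instrument_dta <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "eis_spectrum"))
  z <- to_complex(spectrum)
  hdr <- c("EXPLAIN", "TAG\tEISPOT", "ZCURVE\tTABLE",
           paste(c("Pt", "Freq", "Zreal", "Zimag", "Zmod", "Zphz"),
                 collapse = "\t"),
           paste(c("#", "Hz", "ohm", "ohm", "ohm", "deg"), collapse = "\t"))
  fmt <- function(x) format(x, digits = 17, scientific = TRUE)
  rows <- paste(seq_along(z) - 1L, fmt(spectrum$freq_hz), fmt(Re(z)),
                fmt(Im(z)), fmt(spectrum$zmag_ohm), fmt(spectrum$zphz_deg),
                sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}
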