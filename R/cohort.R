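#' Cohort dataset: spectra keyed by (array, channel, session)
#'
#' A cohort is a collection of [eis_spectrum()] objects keyed by
#' `array_id/channel/session`, with optional ground-truth category labels
#' (used by the synthetic simulator).
#'
#' @param spectra List of [eis_spectrum()] objects, each carrying metadata.
#' @param truth Optional data frame with columns `array_id`, `channel`,
#'   `session`, `category` giving ground-truth labels for (a subset of) the
#'   spectra.
#' @return A list of class `"eis_cohort"` with elements `spectra` (named list)
#'   and `truth`.
#' @export
eis_cohort <- function(spectra = list(), truth = NULL) {
  keys <- vapply(spectra, function(s) {
    if (is.null(s$meta))
      stop("every cohort spectrum must carry session metadata", call. = FALSE)
    spectrum_key(s$meta)
  }, character(1))
  if (anyDuplicated(keys))
    stop("duplicate (array, channel, session) keys in cohort", call. = FALSE)
  names(spectra) <- keys
  if (!is.null(truth)) {
    need <- c("array_id", "channel", "session", "category")
    if (!all(need %in% names(truth)))
      stop("`truth` must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    tk <- label_keys(truth)
    if (!all(tk %in% keys))
      stop("truth labels reference keys absent from the cohort", call. = FALSE)
  }
  structure(list(spectra = spectra, truth = truth), class = "eis_cohort")
}

#' @export
print.eis_cohort <- function(x, ...) {
  meta <- cohort_index(x)
  cat(sprintf("<eis_cohort> %d spectra: %d arrays, %d sessions%s\n",
              length(x$spectra), length(unique(meta$array_id)),
              length(unique(meta$session)),
              if (!is.null(x$truth)) ", with truth labels" else ""))
  invisible(x)
}

spectrum_key <- function(meta) {
  paste(meta$array_id, meta$channel, meta$session, sep = "/")
}

label_keys <- function(df) {
  paste(df$array_id, df$channel, df$session, sep = "/")
}

#' Index of a cohort's spectra
#'
#' @param cohort An [eis_cohort()].
#' @return Data frame with one row per spectrum: `array_id`, `channel`,
#'   `array_type`, `session`, `key`.
#' @export
cohort_index <- function(cohort) {
  stopifnot(inherits(cohort, "eis_cohort"))
  if (!length(cohort$spectra))
    return(data.frame(array_id = character(), channel = integer(),
                      array_type = character(), session = character(),
                      key = character(), stringsAsFactors = FALSE))
  rows <- lapply(cohort$spectra, function(s) {
    data.frame(array_id = s$meta$array_id, channel = s$meta$channel,
               array_type = s$meta$array_type, session = s$meta$session,
               key = spectrum_key(s$meta), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a cohort to a directory
#'
#' One sub-directory per array, one file per channel-session, plus a JSON
#' manifest (`manifest.json`) mapping files to their metadata and, when
#' present, a `truth_labels.csv`.
#'
#' @param cohort An [eis_cohort()].
#' @param dir Output directory (created if needed).
#' @param format `"csv"` (package dialect) or `"dta"` (instrument dialect).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "dta")) {
  stopifnot(inherits(cohort, "eis_cohort"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "csv") ".csv" else ".dta"
  files <- lapply(cohort$spectra, function(s) {
    m <- s$meta
    sub <- file.path(dir, m$array_id)
    dir.create(sub, showWarnings = FALSE)
    fn <- file.path(m$array_id,
                    sprintf("ch%02d_%s%s", m$channel, m$session, ext))
    if (format == "csv") write_spectrum_csv(s, file.path(dir, fn))
    else write_instrument_dta(s, file.path(dir, fn))
    list(file = fn, array_id = m$array_id, channel = m$channel,
         array_type = m$array_type, session = m$session)
  })
  manifest <- list(package = "eismea", format = format,
                   files = unname(files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(cohort$truth))
    write.csv(cohort$truth, file.path(dir, "truth_labels.csv"),
              row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory containing `manifest.json`.
#' @return An [eis_cohort()].
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf))
    stop("no manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  spectra <- lapply(manifest$files, function(f) {
    meta <- session_meta(f$array_id, f$channel, f$array_type, f$session)
    path <- file.path(dir, f$file)
    if (identical(manifest$format, "dta")) read_instrument_dta(path, meta)
    else read_spectrum_csv(path, meta)
  })
  truth <- NULL
  tf <- file.path(dir, "truth_labels.csv")
  if (file.exists(tf))
    truth <- read.csv(tf, stringsAsFactors = FALSE)
  eis_cohort(spectra, truth = truth)
}
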