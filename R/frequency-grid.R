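#' Build a log-spaced measurement frequency grid
#'
#' Constructs the log-uniform frequency grid used throughout the package.  The
#' default measurement protocol sweeps 1 Hz to 1 MHz at 5 points per decade,
#' giving 31 frequencies with 1 kHz falling exactly on the grid.
#'
#' @param points_per_decade Integer >= 1, number of grid points per decade.
#' @param fmin,fmax Frequency bounds in Hz, both positive, `fmin < fmax`.
#'
#' @return Numeric vector of strictly increasing frequencies in Hz, inclusive
#'   of both endpoints.
#'
#' @details The grid is computed as `10^(log10(fmin) + k / points_per_decade)`.
#'   Exponents that land within 1e-9 of an integer are snapped so that decade
#'   frequencies (1 kHz in particular) are represented exactly.  `fmax` must
#'   lie on the implied lattice (within 1e-8 of a grid exponent); the last
#'   point is snapped to `fmax` exactly.
#'
#' @examples
#' g <- make_frequency_grid(5, 1, 1e6)
#' length(g)      # 31
#' g[16]          # exactly 1000
#' @export
make_frequency_grid <- function(points_per_decade = 5, fmin = 1, fmax = 1e6) {
  if (!is.numeric(fmin) || !is.numeric(fmax) || length(fmin) != 1L ||
      length(fmax) != 1L || is.na(fmin) || is.na(fmax) || fmin <= 0 || fmax <= 0)
    stop("`fmin` and `fmax` must be positive finite scalars", call. = FALSE)
  if (fmin >= fmax)
    stop("`fmin` must be strictly less than `fmax`", call. = FALSE)
  if (!is.numeric(points_per_decade) || length(points_per_decade) != 1L ||
      is.na(points_per_decade) || points_per_decade < 1)
    stop("`points_per_decade` must be >= 1", call. = FALSE)
  span <- log10(fmax) - log10(fmin)
  k_max <- round(points_per_decade * span)
  if (abs(k_max / points_per_decade - span) > 1e-8)
    stop("`fmax` does not lie on the log lattice implied by `fmin` and ",
         "`points_per_decade`", call. = FALSE)
  e <- log10(fmin) + (0:k_max) / points_per_decade
  near_int <- abs(e - round(e)) < 1e-9
  e[near_int] <- round(e[near_int])
  f <- 10^e
  f[length(f)] <- fmax
  f[1] <- fmin
  f
}

#' Validate a frequency grid
#'
#' @param freq_hz Numeric vector of frequencies in Hz.
#' @return The validated grid, invisibly.
#' @keywords internal
validate_grid <- function(freq_hz) {
  if (!is.numeric(freq_hz) || length(freq_hz) < 1L || anyNA(freq_hz))
    stop("frequency grid must be a non-empty numeric vector without NA",
         call. = FALSE)
  if (any(freq_hz <= 0))
    stop("all grid frequencies must be > 0", call. = FALSE)
  if (is.unsorted(freq_hz, strictly = TRUE))
    stop("grid frequencies must be strictly increasing", call. = FALSE)
  invisible(freq_hz)
}
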