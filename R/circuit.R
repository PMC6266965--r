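#' Randles circuit parameters
#'
#' The Randles model used here is the access (solution) resistance `R_S` in
#' series with the parallel combination of the charge-transfer resistance
#' `R_E` and a constant phase element (CPE) of admittance magnitude `Q` and
#' exponent `n`:
#' \deqn{Z(w) = R_S + \frac{R_E}{1 + R_E Q (jw)^n}.}
#'
#' @param R_E Charge-transfer resistance, ohm (> 0).
#' @param Q CPE admittance magnitude, S s^n (> 0).
#' @param n CPE exponent in \[0, 1\] (1 = ideal capacitor, 0 = resistor).
#' @param R_S Access/solution resistance, ohm (> 0).
#' @return Named list of class `"randles_params"`.
#' @export
randles_params <- function(R_E, Q, n, R_S) {
  if (any(!is.finite(c(R_E, Q, R_S))) || R_E <= 0 || Q <= 0 || R_S <= 0)
    stop("R_E, Q and R_S must be positive and finite", call. = FALSE)
  if (!is.finite(n) || n < 0 || n > 1)
    stop("`n` must lie in [0, 1]", call. = FALSE)
  structure(list(R_E = R_E, Q = Q, n = n, R_S = R_S),
            class = "randles_params")
}

#' Extended circuit parameters (parasitic shunt + dielectric coupling)
#'
#' Adds two optional degradation pathways to [randles_params()]: a parasitic
#' shunt resistance `R_p` (encapsulation damage / lead break; produces the
#' flat low-frequency plateau of ski-slope spectra) and a dielectric coupling
#' capacitance `C_d` (insulation degradation; produces the high-frequency
#' roll-off).  Both are placed in parallel with the whole Randles branch.
#' With `R_p = Inf` and `C_d = 0` the model reduces exactly to the Randles
#' circuit.
#'
#' @param base A [randles_params()] object.
#' @param R_p Parasitic shunt resistance, ohm; `Inf` when absent.
#' @param C_d Dielectric coupling capacitance, F; `0` when absent.
#' @return Named list of class `"extended_params"`.
#' @export
extended_params <- function(base, R_p = Inf, C_d = 0) {
  stopifnot(inherits(base, "randles_params"))
  if (is.na(R_p) || R_p <= 0) stop("`R_p` must be > 0 (or Inf)", call. = FALSE)
  if (!is.finite(C_d) || C_d < 0) stop("`C_d` must be >= 0", call. = FALSE)
  structure(list(base = base, R_p = R_p, C_d = C_d),
            class = "extended_params")
}

#' Constant-phase-element impedance
#'
#' `Z_CPE(w) = 1 / (Q (jw)^n)` with the principal complex branch,
#' `j^n = exp(j n pi / 2)`, so the phase is exactly `-n * 90` degrees.
#'
#' @param w Frequency argument (> 0).  The package convention maps grid
#'   frequencies in Hz directly onto `w` (see [simulate_spectrum()]).
#' @param Q CPE admittance magnitude, S s^n.
#' @param n CPE exponent in \[0, 1\].
#' @return Complex impedance(s), ohm.
#' @export
z_cpe <- function(w, Q, n) {
  if (any(!is.finite(w)) || any(w <= 0))
    stop("`w` must be positive and finite", call. = FALSE)
  if (Q <= 0) stop("`Q` must be > 0", call. = FALSE)
  if (n < 0 || n > 1) stop("`n` must lie in [0, 1]", call. = FALSE)
  1 / (Q * (1i * w)^n)
}

#' Randles circuit impedance
#'
#' Evaluates `Z(w) = R_S + R_E / (1 + R_E Q (jw)^n)`.
#'
#' @param w Frequency argument(s) (> 0).
#' @param p A [randles_params()] object.
#' @return Complex impedance(s), ohm.
#' @export
z_randles <- function(w, p) {
  stopifnot(inherits(p, "randles_params"))
  if (any(!is.finite(w)) || any(w <= 0))
    stop("`w` must be positive and finite", call. = FALSE)
  p$R_S + p$R_E / (1 + p$R_E * p$Q * (1i * w)^p$n)
}

#' Extended circuit impedance
#'
#' Parallel combination of the Randles branch with the parasitic shunt and
#' the dielectric capacitance:
#' `Z = 1 / (1/Z_randles + 1/R_p + jw C_d)`.  Reduces exactly to
#' [z_randles()] when `R_p = Inf` and `C_d = 0`.
#'
#' @param w Frequency argument(s) (> 0).
#' @param p An [extended_params()] object (a bare [randles_params()] is
#'   promoted with no extra elements).
#' @return Complex impedance(s), ohm.
#' @export
z_extended <- function(w, p) {
  if (inherits(p, "randles_params")) p <- extended_params(p)
  stopifnot(inherits(p, "extended_params"))
  zr <- z_randles(w, p$base)
  if (is.infinite(p$R_p) && p$C_d == 0) return(zr)
  1 / (1 / zr + 1 / p$R_p + 1i * w * p$C_d)
}

#' Simulate a noiseless spectrum from circuit parameters
#'
#' Evaluates the extended circuit at each grid frequency and converts to
#' magnitude/phase form.
#'
#' @param p An [extended_params()] or [randles_params()] object.
#' @param grid Frequency grid in Hz (default: the 31-point 1 Hz - 1 MHz grid).
#' @param meta Optional [session_meta()].
#' @param angular If `TRUE`, the CPE argument is taken as angular frequency
#'   (`w = 2 pi f`); the package default maps ordinary frequency directly
#'   (`w = f`), the convention under which the packaged archetype parameters
#'   reproduce their category morphologies.
#' @return An [eis_spectrum()].
#' @export
simulate_spectrum <- function(p, grid = make_frequency_grid(), meta = NULL,
                              angular = FALSE) {
  validate_grid(grid)
  w <- if (angular) 2 * pi * grid else grid
  from_complex(grid, z_extended(w, p), meta = meta)
}
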