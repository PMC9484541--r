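#' Arrhenius thermal damage integral
#'
#' Accumulates first-order thermal damage over a temperature history
#' sampled at a fixed step: \eqn{\Omega = \sum_t \zeta\,
#' e^{-E_a/(R\,T(t))}\,\Delta t}, with the temperature converted to kelvin
#' inside the exponent only. \eqn{\Omega} is dimensionless, non-negative,
#' and additive over consecutive time partitions.
#'
#' @param temp_c Temperature history at a point, degrees C (vector).
#' @param dt Sampling step, s.
#' @param params An [arrhenius_params()] object.
#' @return The damage integral \eqn{\Omega} (scalar).
#' @export
#' @examples
#' p <- arrhenius_params()
#' arrhenius_integral(rep(80, 100), 0.1, p)
arrhenius_integral <- function(temp_c, dt, params = arrhenius_params()) {
  sum(arrhenius_rate(temp_c, params)) * dt
}

# instantaneous damage rate zeta * exp(-Ea/(R T)), vectorised over
# temperatures in Celsius (works on matrices too)
arrhenius_rate <- function(temp_c, params) {
  params$zeta * exp(-params$ea / (params$r_gas * (temp_c + 273.15)))
}

#' Thermal injury probability from accumulated damage
#'
#' \eqn{P_{TI} = 1 - e^{-\Omega}}; damage \eqn{\Omega = \ln 2} corresponds
#' exactly to the 0.5 injury threshold.
#'
#' @param omega Damage integral(s).
#' @return Injury probability in `[0, 1)`.
#' @export
ti_probability <- function(omega) {
  1 - exp(-omega)
}
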