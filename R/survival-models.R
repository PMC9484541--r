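#' Peleg-Fermi survival probability
#'
#' The Fermi-type (logistic) dose-response curve for cell survival under
#' pulsed electric fields:
#' \deqn{S(E, N) = \frac{1}{1 + \exp\!\big((E - E_c(N)) / A_c(N)\big)}}
#' where \eqn{E_c(N)} is the field strength at which half the population is
#' killed after \eqn{N} pulses and \eqn{A_c(N)} sets the slope of the
#' sigmoid. `S` is a fraction in (0, 1), strictly decreasing in `efs`, and
#' equals exactly 0.5 at `efs == ec_n`.
#'
#' @param efs Electric field strength, V/cm.
#' @param ec_n Half-lethality field \eqn{E_c(N)}, V/cm.
#' @param ac_n Slope constant \eqn{A_c(N)}, V/cm; must be positive.
#' @return Survival fraction(s) in (0, 1).
#' @export
#' @examples
#' survival_probability(800, 800, 200) # 0.5
survival_probability <- function(efs, ec_n, ac_n) {
  if (any(ac_n <= 0)) {
    abort("ac_n must be positive.", class = "ebtsim_invalid_slope")
  }
  1 / (1 + exp((efs - ec_n) / ac_n))
}

#' Half-lethality field and slope constant as functions of pulse number
#'
#' Both cell-specific functions decay exponentially with pulse number:
#' \eqn{E_c(N) = E_0 e^{-k_1 N}} and \eqn{A_c(N) = A_0 e^{-k_2 N}}.
#' The rate constants may be negative (some cell lines show a slowly
#' *increasing* slope constant).
#'
#' @param e0,a0 Amplitudes at N = 0, V/cm.
#' @param k1,k2 Per-pulse decay rates.
#' @param n Pulse number (non-negative).
#' @return Field strength(s), V/cm.
#' @export
#' @examples
#' ec_of_n(1862.259, 0.014, 100) # ~459.2 V/cm
ec_of_n <- function(e0, k1, n) {
  if (any(n < 0)) abort("n must be non-negative.", class = "ebtsim_domain_error")
  e0 * exp(-k1 * n)
}

#' @rdname ec_of_n
#' @export
ac_of_n <- function(a0, k2, n) {
  if (any(n < 0)) abort("n must be non-negative.", class = "ebtsim_domain_error")
  a0 * exp(-k2 * n)
}

#' Half-lethality (IRE effective-field) threshold
#'
#' Evaluates \eqn{E_c(N)} for each coefficient row and appends it as column
#' `ec_n`. \eqn{E_c(N)} at the clinical default of 100 pulses is the
#' effective-field threshold handed to the injury simulator: tissue below it
#' is assigned zero electrical-injury probability.
#'
#' @param coeffs A coefficient tibble with columns `e0` and `k1`
#'   (e.g. from [pf_coefficients()] or [fit_peleg_fermi()]).
#' @param n Pulse number at which to evaluate the threshold (default 100).
#' @return `coeffs` with an added `ec_n` column, V/cm.
#' @export
ec_threshold <- function(coeffs, n = 100) {
  if (n < 1) abort("n must be >= 1.", class = "ebtsim_domain_error")
  dplyr::mutate(tibble::as_tibble(coeffs),
                ec_n = ec_of_n(.data$e0, .data$k1, n))
}

#' Survival surface over a field-strength by pulse-number grid
#'
#' Evaluates the Peleg-Fermi survival fraction on the outer product of
#' `efs` and `pulse_numbers` using one coefficient row.
#'
#' @param coeffs A one-row coefficient tibble (columns `e0`, `k1`, `a0`,
#'   `k2`).
#' @param efs Vector of field strengths, V/cm.
#' @param pulse_numbers Vector of pulse numbers.
#' @return A tibble of class `ep_surface` with columns `efs_v_cm`,
#'   `pulse_number`, `survival` (fraction).
#' @export
survival_surface <- function(coeffs, efs, pulse_numbers) {
  stopifnot(nrow(coeffs) == 1, length(efs) >= 1, length(pulse_numbers) >= 1)
  grid <- tidyr::expand_grid(efs_v_cm = efs, pulse_number = pulse_numbers)
  out <- dplyr::mutate(
    grid,
    survival = survival_probability(
      .data$efs_v_cm,
      ec_of_n(coeffs$e0, coeffs$k1, .data$pulse_number),
      ac_of_n(coeffs$a0, coeffs$k2, .data$pulse_number)
    )
  )
  class(out) <- c("ep_surface", class(out))
  out
}

# modified (double-exponential) pulse-number dependence
ec_of_n_modified <- function(e1, k1, e2, k2, n) {
  e1 * exp(-k1 * n) + e2 * exp(-k2 * n)
}
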